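class,f1,precision,recall,fpr
C1,0.930,0.929,0.931,0.07
C2,0.907,0.919,0.896,0.015
C3,0.848,0.870,0.827,0.018
C4,0.944,0.944,0.944,0.02
C5,0.915,0.956,0.915,0.011
C6,0.905,0.905,0.905,0.009
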