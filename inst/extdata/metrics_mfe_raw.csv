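class,f1,precision,recall,fpr
C1,0.903,0.901,0.906,0.05
C2,0.863,0.874,0.852,0.019
C3,0.814,0.751,0.889,0.033
C4,0.914,0.925,0.903,0.018
C5,0.892,0.905,0.878,0.018
C6,0.868,0.921,0.821,0.05
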