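class,C1,C2,C3,C4,C5,C6
C1,1111,17,22,31,9,10
C2,19,431,16,7,5,3
C3,15,1,334,1,9,0
C4,13,9,15,682,1,0
C5,22,12,14,1,549,2
C6,14,0,4,3,4,215
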