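class,C1,C2,C3,C4,C5,C6
C1,1087,36,42,21,10,4
C2,27,409,18,23,1,2
C3,22,3,320,1,13,1
C4,18,8,23,650,14,7
C5,32,12,18,8,527,3
C6,21,0,5,0,17,197
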