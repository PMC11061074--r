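electrode,row,col
Fz,0,1
Cz,0,3
Pz,0,5
Oz,0,7
Fp1,1,2
Fp2,1,5
AF3,2,2
AF4,2,5
F7,3,0
F3,3,2
F4,3,5
F8,3,7
FC5,4,1
FC1,4,3
FC2,4,4
FC6,4,6
T7,5,0
C3,5,2
C4,5,5
T8,5,7
CP5,6,1
CP1,6,3
CP2,6,4
CP6,6,6
P7,7,0
P3,7,2
P4,7,5
P8,7,7
PO3,8,2
O1,8,3
O2,8,4
PO4,8,5
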