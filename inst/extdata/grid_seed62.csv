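electrode,row,col
FPZ,0,0
FZ,0,1
FCZ,0,2
CZ,0,3
CPZ,0,4
PZ,0,5
POZ,0,6
OZ,0,7
FP1,1,1
AF3,1,2
AF4,1,5
FP2,1,6
F7,2,0
F5,2,1
F3,2,2
F1,2,3
F2,2,4
F4,2,5
F6,2,6
F8,2,7
FT7,3,0
FC5,3,1
FC3,3,2
FC1,3,3
FC2,3,4
FC4,3,5
FC6,3,6
FT8,3,7
T7,4,0
C5,4,1
C3,4,2
C1,4,3
C2,4,4
C4,4,5
C6,4,6
T8,4,7
TP7,5,0
CP5,5,1
CP3,5,2
CP1,5,3
CP2,5,4
CP4,5,5
CP6,5,6
TP8,5,7
P7,6,0
P5,6,1
P3,6,2
P1,6,3
P2,6,4
P4,6,5
P6,6,6
P8,6,7
PO7,7,1
PO5,7,2
PO3,7,3
PO4,7,4
PO6,7,5
PO8,7,6
CB1,8,2
O1,8,3
O2,8,4
CB2,8,5
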