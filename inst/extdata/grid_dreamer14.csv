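electrode,row,col
AF3,1,2
AF4,1,5
F7,2,0
F3,2,2
F4,2,5
F8,2,7
FC5,3,1
FC6,3,6
T7,4,0
T8,4,7
P7,6,0
P8,6,7
O1,8,3
O2,8,4
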