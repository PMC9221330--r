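# Per-subject subjective difficulty ratings (1-10) for six flight behaviors,
# 14 simulator subjects. Column order follows the published table.
subject,stall,somersault,takeoff,turn_and_hover,level_flight,roll
1,10,8,6,6,4,3
2,7,6,8,5,3,4
3,8,9,5,6,4,4
4,9,8,3,5,3,3
5,8,5,2,3,2,2
6,8,4,1,4,1,3
7,6,8,1,5,2,2
8,3,7,2,3,3,6
9,8,9,5,6,5,5
10,7,8,3,6,4,4
11,8,7,3,5,4,3
12,5,7,2,6,5,2
13,7,9,3,7,5,3
14,8,8,4,5,4,3
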