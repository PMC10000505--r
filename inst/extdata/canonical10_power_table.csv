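# Normalized per-channel radiated power fractions [%] of the HCQ-optimal
# steering solution for a 10-element single-ring canonical helmet array,
# per operating frequency.
channel,f250MHz,f375MHz,f500MHz
1,6,4,5
2,0,0,0
3,2,1,3
4,7,8,2
5,16,5,2
6,3,1,2
7,1,6,3
8,1,3,4
9,5,1,4
10,4,1,2
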