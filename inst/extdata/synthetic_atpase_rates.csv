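actin,rate
0,0.2374
1.25,1.656
2.5,2.3474
5,3.3195
10,4.2102
15,4.5349
20,5.008
30,5.022
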