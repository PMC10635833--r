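pressure_kPa,displacement_um
0,0.0
10,1.1
20,2.3
30,3.6
40,5.0
50,6.5
60,8.1
70,9.8
80,11.6
90,13.5
100,15.5
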