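section,neutral_area,jaw,dorsum_pos,dorsum_shape,apex,lip_aperture,len_protrusion,len_larynx
1,1.3,0,0.0842,0,0,0,0,-0.15
2,1.6,0,0.203,-2e-04,0,0,0,-0.15
3,2,0,0.4171,-9e-04,0,0,0,-0.15
4,2.4,0,0.7301,-0.0043,0,0,0,-0.15
5,2.7,0,1.0892,-0.0167,0,0,0,-0.15
6,3,0,1.3847,-0.0556,0,0,0,-0.15
7,3.1,0,1.5,-0.1572,0,0,0,-0.15
8,3.2,0,1.3845,-0.3789,0,0,0,-0.15
9,3.2,0,1.0885,-0.7785,0,0,0,-0.15
10,3.1,0.25,0.7268,-1.3629,0,0,0,0
11,3,0.325,0.4039,-2.0332,0,0,0,0
12,3,0.4,0.1594,-2.5847,0,0,0,0
13,3,0.475,-0.0393,-2.8,0,0,0,0
14,3,0.55,-0.268,-2.5847,0,0,0,0
15,2.9,0.625,-0.6027,-2.0332,0,0,0,0
16,2.9,0.7,-1.0686,-1.3629,0,0,0,0
17,2.9,0.775,-1.597,-0.7785,-4e-04,0,0,0
18,2.8,0.85,-2.0308,-0.3789,-0.0036,0,0,0
19,2.8,0.925,-2.2,-0.1572,-0.023,0,0,0
20,2.8,1,-2.0309,-0.0556,-0.1076,0,0,0
21,2.7,1,-1.5975,-0.0167,-0.37,0,0,0
22,2.7,1,-1.0709,-0.0043,-0.9339,0,0,0
23,2.6,1,-0.6117,-9e-04,-1.7313,0,0,0
24,2.6,1,-0.2977,-2e-04,-2.3573,0,0,0
25,2.5,1,-0.1235,0,-2.3573,0,0,0
26,2.4,1,-0.0437,0,-1.7313,0,0,0
27,2.2,0,-0.0131,0,-0.9339,2.4444,0.35,0
28,2,0,-0.0034,0,-0.37,2.2222,0.35,0
29,1.8,0,-7e-04,0,-0.1076,2,0.35,0
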