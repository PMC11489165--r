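dose,litter_id,response
0,L001,7.2185301
0,L002,8.5902779
0,L003,6.736584
0,L004,8.0339198
0,L005,8.1887867
0,L006,9.7154286
0,L007,8.703862
0,L008,7.5299935
0,L009,9.2334303
0,L010,7.3669631
0,L011,8.5461362
0,L012,6.5785055
0,L013,10.216215
0,L014,5.7587943
0,L015,7.3474038
0,L016,7.4107471
0,L017,6.5073547
0,L018,7.7896736
0,L019,6.5488345
0,L020,5.1303447
0,L021,7.4542907
5,L022,8.3967794
5,L023,6.9203026
5,L024,5.4608948
5,L025,8.4567138
5,L026,5.5190965
5,L027,8.0047094
5,L028,7.1270723
5,L029,8.0049811
5,L030,8.0541124
5,L031,8.7125654
20,L032,6.578718
20,L033,7.6000587
20,L034,4.1288274
20,L035,7.8789701
20,L036,5.3929867
20,L037,6.4354637
20,L038,7.4694489
20,L039,4.4705334
20,L040,6.8030553
20,L041,6.8490039
50,L042,5.3214366
50,L043,2.8929024
50,L044,4.1811388
50,L045,3.6791155
50,L046,4.9598812
50,L047,5.1256539
50,L048,3.9818666
50,L049,4.3238006
50,L050,3.4134193
50,L051,3.646566
100,L052,2.7125732
100,L053,3.2113884
100,L054,2.1719142
100,L055,3.3221083
100,L056,2.325826
100,L057,2.9594605
100,L058,3.5822979
100,L059,3.6135879
100,L060,2.6314094
100,L061,2.7204649
125,L062,1.7563221
125,L063,2.0455728
125,L064,2.374923
125,L065,2.525369
125,L066,2.5075431
125,L067,2.0268454
125,L068,2.3921264
125,L069,2.2962483
125,L070,2.2884518
125,L071,3.132142
250,L072,1.5406813
250,L073,1.4046425
250,L074,1.1008032
250,L075,0.7797227
250,L076,0.9102382
250,L077,1.1868646
250,L078,0.86790031
250,L079,1.148901
250,L080,1.1066217
250,L081,1.6131878
500,L082,0.98139179
500,L083,0.71161658
500,L084,0.70705025
500,L085,0.5591471
500,L086,0.86440501
500,L087,0.78830102
500,L088,1.0284243
500,L089,0.90888162
625,L090,1.052505
625,L091,1.006221
625,L092,0.76867795
625,L093,0.72051205
625,L094,0.67104411
625,L095,0.81836535
625,L096,0.66175843
625,L097,0.70864036
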