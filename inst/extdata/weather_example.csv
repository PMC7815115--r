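station_id,year,month,tmin_c,tmax_c,precip_mm,lon,lat
S001,2000,1,-19.924,-9.93028,5.02954,128.706,43.4167
S001,2000,2,-19.0994,-9.10566,4.98892,128.706,43.4167
S001,2000,3,-10.1772,-0.183501,8.09638,128.706,43.4167
S001,2000,4,1.56176,11.5555,20.9884,128.706,43.4167
S001,2000,5,5.58957,15.5833,35.7276,128.706,43.4167
S001,2000,6,17.1172,27.1109,136.384,128.706,43.4167
S001,2000,7,17.5446,27.5383,122.881,128.706,43.4167
S001,2000,8,13.6552,23.649,119.413,128.706,43.4167
S001,2000,9,9.90277,19.8965,53.0579,128.706,43.4167
S001,2000,10,-0.0865233,9.90721,23.0817,128.706,43.4167
S001,2000,11,-8.34839,1.64533,14.6344,128.706,43.4167
S001,2000,12,-18.6614,-8.66771,16.8879,128.706,43.4167
S001,2001,1,-20.9068,-10.9131,4.60889,128.706,43.4167
S001,2001,2,-18.991,-8.99725,5.85165,128.706,43.4167
S001,2001,3,-10.2682,-0.274501,10.7855,128.706,43.4167
S001,2001,4,-2.74797,7.24576,20.0038,128.706,43.4167
S001,2001,5,7.16798,17.1617,47.9999,128.706,43.4167
S001,2001,6,17.4831,27.4769,89.354,128.706,43.4167
S001,2001,7,20.2789,30.2726,152.539,128.706,43.4167
S001,2001,8,16.8574,26.8511,120.698,128.706,43.4167
S001,2001,9,9.89488,19.8886,58.7348,128.706,43.4167
S001,2001,10,-2.62199,7.37174,34.8739,128.706,43.4167
S001,2001,11,-10.2864,-0.292631,18.4537,128.706,43.4167
S001,2001,12,-16.4479,-6.45415,19.6965,128.706,43.4167
S001,2002,1,-21.6183,-11.6246,4.38071,128.706,43.4167
S001,2002,2,-17.9384,-7.94467,6.2017,128.706,43.4167
S001,2002,3,-10.0981,-0.104419,13.2145,128.706,43.4167
S001,2002,4,-0.556958,9.43677,26.142,128.706,43.4167
S001,2002,5,9.53447,19.5282,39.3264,128.706,43.4167
S001,2002,6,14.343,24.3368,133.045,128.706,43.4167
S001,2002,7,19.1575,29.1512,120.181,128.706,43.4167
S001,2002,8,14.866,24.8597,104.484,128.706,43.4167
S001,2002,9,7.21979,17.2135,39.3956,128.706,43.4167
S001,2002,10,3.00436,12.9981,24.1034,128.706,43.4167
S001,2002,11,-10.7036,-0.709824,19.8719,128.706,43.4167
S001,2002,12,-17.41,-7.4163,11.402,128.706,43.4167
S002,2000,1,-22.0988,-10.4832,3.49868,126.756,43.4964
S002,2000,2,-19.6381,-8.02242,5.00873,126.756,43.4964
S002,2000,3,-9.59775,2.0179,12.8698,126.756,43.4964
S002,2000,4,-0.671201,10.9445,27.3161,126.756,43.4964
S002,2000,5,6.53206,18.1477,45.5641,126.756,43.4964
S002,2000,6,17.4179,29.0335,87.1227,126.756,43.4964
S002,2000,7,17.5246,29.1403,154.989,126.756,43.4964
S002,2000,8,14.2054,25.8211,107.854,126.756,43.4964
S002,2000,9,6.31027,17.9259,38.1284,126.756,43.4964
S002,2000,10,-4.36642,7.24923,20.9693,126.756,43.4964
S002,2000,11,-13.3552,-1.73959,18.669,126.756,43.4964
S002,2000,12,-19.2982,-7.68259,13.9215,126.756,43.4964
S002,2001,1,-20.2856,-8.66998,6.45252,126.756,43.4964
S002,2001,2,-17.0296,-5.4139,4.52062,126.756,43.4964
S002,2001,3,-11.4928,0.122845,6.15834,126.756,43.4964
S002,2001,4,-0.0471753,11.5685,26.8466,126.756,43.4964
S002,2001,5,8.2448,19.8605,44.155,126.756,43.4964
S002,2001,6,12.8529,24.4686,96.8921,126.756,43.4964
S002,2001,7,17.2747,28.8904,101.69,126.756,43.4964
S002,2001,8,12.9516,24.5672,147.368,126.756,43.4964
S002,2001,9,10.1403,21.756,45.729,126.756,43.4964
S002,2001,10,-1.10629,10.5094,28.9065,126.756,43.4964
S002,2001,11,-9.27441,2.34124,17.184,126.756,43.4964
S002,2001,12,-19.8624,-8.24674,13.2392,126.756,43.4964
S002,2002,1,-21.2596,-9.64396,3.53895,126.756,43.4964
S002,2002,2,-18.5334,-6.91771,5.82021,126.756,43.4964
S002,2002,3,-13.9672,-2.35158,10.7889,126.756,43.4964
S002,2002,4,-1.82002,9.79563,29.3599,126.756,43.4964
S002,2002,5,9.63174,21.2474,48.002,126.756,43.4964
S002,2002,6,12.6003,24.216,145.718,126.756,43.4964
S002,2002,7,17.3193,28.9349,141.305,126.756,43.4964
S002,2002,8,14.5131,26.1288,155.082,126.756,43.4964
S002,2002,9,7.3743,18.99,44.0909,126.756,43.4964
S002,2002,10,-2.5717,9.04395,34.5459,126.756,43.4964
S002,2002,11,-12.4065,-0.790838,21.2308,126.756,43.4964
S002,2002,12,-18.7084,-7.09272,14.0011,126.756,43.4964
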