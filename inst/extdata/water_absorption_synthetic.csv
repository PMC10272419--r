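wavelength_nm,mua_per_cm
1000,0.36
1010,0.32501
1020,0.29232
1030,0.26341
1040,0.23915
1050,0.22
1060,0.20147
1070,0.18299
1080,0.16926
1090,0.1637
1100,0.17
1110,0.19472
1120,0.2417
1130,0.31227
1140,0.40328
1150,0.5
1160,0.6
1170,0.7159
1180,0.839
1190,0.9541
1200,1.04
1210,1.06568
1220,1.03491
1230,0.98075
1240,0.93387
1250,0.92
1260,0.93213
1270,0.95257
1280,0.99062
1290,1.05775
1300,1.17
1310,1.35033
1320,1.61645
1330,1.98553
1340,2.47573
1350,3.1
1360,3.91728
1370,5.04499
1380,6.6
1390,8.9694
1400,12
1410,14.5
1420,17.5
1430,21
1440,24.5
1450,27.5
1460,28.2
1470,27.3
1480,25.5
1490,23
1500,20.5
1510,18.51118
1520,16.5
1530,14.00989
1540,11.66628
1550,10
1560,8.95352
1570,8.19205
1580,7.61029
1590,7.13226
1600,6.7
1610,6.29108
1620,5.9298
1630,5.63444
1640,5.41983
1650,5.3
1660,5.29779
1670,5.39788
1680,5.56032
1690,5.74332
1700,5.9
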