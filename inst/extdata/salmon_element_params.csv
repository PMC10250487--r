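element,group,median,q1,q3
Li,Alaska_Wild,34.65,28.15,42.35
Li,Iceland_Farmed,31.25,25.86,38.95
Li,Iceland_Wild,10.84,7.06,15.23
Li,Norway_Farmed,4.95,3.60,8.33
Li,Scotland_Farmed,17.79,14.15,23.40
B,Alaska_Wild,649.20,502.05,887.25
B,Iceland_Farmed,422.48,298.48,535.33
B,Iceland_Wild,0.00,0.00,29.81
B,Norway_Farmed,99.15,49.73,161.48
B,Scotland_Farmed,480.53,367.37,652.20
Al,Alaska_Wild,1703.10,805.12,1454.70
Al,Iceland_Farmed,2901.25,2354.63,4145.86
Al,Iceland_Wild,3791.98,2895.53,4735.38
Al,Norway_Farmed,874.50,357.08,1352.40
Al,Scotland_Farmed,1313.40,998.17,1621.80
V,Alaska_Wild,11.46,7.67,18.24
V,Iceland_Farmed,2.64,1.69,3.30
V,Iceland_Wild,8.09,5.01,11.42
V,Norway_Farmed,15.30,11.55,18.90
V,Scotland_Farmed,10.20,7.64,13.50
Cr,Alaska_Wild,37.20,22.54,55.50
Cr,Iceland_Farmed,30.63,19.59,46.78
Cr,Iceland_Wild,39.11,23.21,68.23
Cr,Norway_Farmed,26.55,15.00,40.50
Cr,Scotland_Farmed,26.10,17.10,49.02
Mn,Alaska_Wild,222.90,189.20,257.03
Mn,Iceland_Farmed,332.81,307.92,361.99
Mn,Iceland_Wild,301.96,257.22,353.69
Mn,Norway_Farmed,196.65,177.60,22.78
Mn,Scotland_Farmed,206.81,180.30,240.47
Fe,Alaska_Wild,9223.37,9178.14,9223.37
Fe,Iceland_Farmed,6578.47,5999.64,7243.14
Fe,Iceland_Wild,9223.37,9144.23,9223.37
Fe,Norway_Farmed,4960.80,4224.23,5937.60
Fe,Scotland_Farmed,5927.78,5226.00,7047.49
Co,Alaska_Wild,5.70,5.09,6.62
Co,Iceland_Farmed,12.88,11.33,14.24
Co,Iceland_Wild,14.49,13.22,17.54
Co,Norway_Farmed,9.90,8.40,12.00
Co,Scotland_Farmed,11.10,8.40,12.90
Ni,Alaska_Wild,57.90,36.68,120.08
Ni,Iceland_Farmed,16.29,14.51,20.10
Ni,Iceland_Wild,28.91,20.76,41.01
Ni,Norway_Farmed,13.35,11.10,20.03
Ni,Scotland_Farmed,21.97,14.40,50.13
Cu,Alaska_Wild,1437.95,1271.48,1816.20
Cu,Iceland_Farmed,1069.81,1016.46,1156.92
Cu,Iceland_Wild,1714.95,1527.61,1966.40
Cu,Norway_Farmed,780.90,644.25,902.03
Cu,Scotland_Farmed,1086.30,790.80,1257.42
Zn,Alaska_Wild,15409.20,13747.98,16683.60
Zn,Iceland_Farmed,15735.37,15042.36,16545.02
Zn,Iceland_Wild,17570.84,15968.55,19596.62
Zn,Norway_Farmed,9223.37,9079.35,9223.37
Zn,Scotland_Farmed,9223.37,8964.60,9223.37
As,Alaska_Wild,1638.90,1312.88,2089.50
As,Iceland_Farmed,3463.66,2825.34,4429.03
As,Iceland_Wild,2304.47,1619.14,3118.05
As,Norway_Farmed,1878.60,1634.63,2145.23
As,Scotland_Farmed,1347.00,1160.40,1859.75
Se,Alaska_Wild,1794.30,1602.53,2003.18
Se,Iceland_Farmed,1324.70,1251.13,1419.08
Se,Iceland_Wild,2064.51,2064.51,2515.02
Se,Norway_Farmed,831.75,719.10,949.80
Se,Scotland_Farmed,894.30,675.60,1319.56
Rb,Alaska_Wild,3129.30,2839.28,3547.80
Rb,Iceland_Farmed,4191.43,3967.07,4430.72
Rb,Iceland_Wild,4306.69,4306.69,4951.48
Rb,Norway_Farmed,2812.35,2441.92,3235.50
Rb,Scotland_Farmed,3304.91,2867.31,3743.10
Sr,Alaska_Wild,1559.40,1150.42,1916.55
Sr,Iceland_Farmed,1849.41,1510.02,2443.96
Sr,Iceland_Wild,649.88,649.88,1481.46
Sr,Norway_Farmed,1176.75,944.18,1789.13
Sr,Scotland_Farmed,968.92,702.05,1374.00
Nb,Alaska_Wild,5.99,3.08,10.70
Nb,Iceland_Farmed,2.32,1.48,4.13
Nb,Iceland_Wild,8.72,8.72,30.76
Nb,Norway_Farmed,3.90,1.50,9.83
Nb,Scotland_Farmed,6.94,2.70,18.34
Mo,Alaska_Wild,10.35,8.12,13.53
Mo,Iceland_Farmed,12.04,10.05,13.48
Mo,Iceland_Wild,11.62,9.63,13.58
Mo,Norway_Farmed,9.60,6.90,12.23
Mo,Scotland_Farmed,13.20,10.37,16.80
Cd,Alaska_Wild,7.14,5.56,9.67
Cd,Iceland_Farmed,0.00,0.00,0.42
Cd,Iceland_Wild,14.16,11.31,15.77
Cd,Norway_Farmed,0.60,0.30,1.20
Cd,Scotland_Farmed,0.47,0.30,0.90
Cs,Alaska_Wild,73.65,66.19,82.43
Cs,Iceland_Farmed,128.34,118.37,132.42
Cs,Iceland_Wild,120.59,108.61,133.65
Cs,Norway_Farmed,75.60,63.90,84.60
Cs,Scotland_Farmed,76.20,64.50,87.94
Ta,Alaska_Wild,9.15,4.31,14.07
Ta,Iceland_Farmed,8.78,6.91,10.49
Ta,Iceland_Wild,22.49,16.88,46.29
Ta,Norway_Farmed,6.00,3.38,10.65
Ta,Scotland_Farmed,12.45,4.20,22.80
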