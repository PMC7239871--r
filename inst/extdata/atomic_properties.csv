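element,r_cal,r_cov,r_emp,mass,t_boil,density,e_ea,chi,dh_fus,dh_vap,ie1,ie2,t_melt,v_mol,spec_heat,therm_cond,valence
H,53,31,25,1.008,20.28,0.00008988,72.8,2.20,0.117,0.904,1312.0,0,13.99,11.42,14.304,0.1805,1
C,67,76,70,12.011,4300,2.267,153.9,2.55,117,715,1086.5,2352.6,3800,5.29,0.709,140,4
N,56,71,65,14.007,77.36,0.0012506,0,3.04,0.72,5.57,1402.3,2856,63.15,13.54,1.040,0.02583,3
O,48,66,60,15.999,90.20,0.001429,141,3.44,0.444,6.82,1313.9,3388.3,54.36,14.0,0.918,0.02658,2
F,42,57,50,18.998,85.03,0.001696,328,3.98,0.510,6.62,1681.0,3374.2,53.53,11.20,0.824,0.0277,1
Na,190,166,180,22.990,1156,0.971,52.8,0.93,2.60,97.42,495.8,4562,370.87,23.78,1.228,142,1
Mg,145,141,150,24.305,1363,1.738,0,1.31,8.48,128,737.7,1450.7,923,14.00,1.023,156,2
Al,118,121,125,26.982,2792,2.699,42.5,1.61,10.71,294,577.5,1816.7,933.47,10.00,0.897,237,3
Si,111,111,110,28.085,3538,2.3296,133.6,1.90,50.21,359,786.5,1577.1,1687,12.06,0.705,149,4
P,98,107,100,30.974,550,1.82,72.0,2.19,0.66,12.4,1011.8,1907,317.30,17.02,0.769,0.236,5
S,88,105,100,32.06,717.8,2.067,200,2.58,1.727,45,999.6,2252,388.36,15.53,0.710,0.205,2
Cl,79,102,100,35.45,239.11,0.003214,349,3.16,6.406,20.41,1251.2,2298,171.6,17.39,0.479,0.0089,1
K,243,203,220,39.098,1032,0.862,48.4,0.82,2.321,76.9,418.8,3052,336.53,45.94,0.757,102.5,1
Ca,194,176,180,40.078,1757,1.54,2.37,1.00,8.54,154.7,589.8,1145.4,1115,26.20,0.647,201,2
Ti,176,160,140,47.867,3560,4.506,7.6,1.54,14.15,425,658.8,1309.8,1941,10.64,0.523,21.9,4
Fe,156,132,140,55.845,3134,7.874,15.7,1.83,13.81,340,762.5,1561.9,1811,7.09,0.449,80.4,3
Co,152,126,135,58.933,3200,8.86,63.7,1.88,16.06,377,760.4,1648,1768,6.67,0.421,100,2
Cu,145,132,135,63.546,2835,8.96,118.4,1.90,13.26,300.4,745.5,1957.9,1357.77,7.11,0.385,401,2
Zn,142,122,135,65.38,1180,7.134,0,1.65,7.32,123.6,906.4,1733.3,692.68,9.16,0.388,116,2
Se,103,120,115,78.971,958,4.809,195,2.55,6.69,95.48,941.0,2045,494,16.42,0.321,0.52,2
Br,94,120,115,79.904,332.0,3.1028,324.6,2.96,10.571,29.96,1139.9,2103,265.8,19.78,0.474,0.122,1
Zr,206,175,155,91.224,4682,6.52,41.1,1.33,14.0,573,640.1,1270,2128,14.02,0.278,22.6,4
Pd,169,139,140,106.42,3236,12.02,53.7,2.20,16.74,362,804.4,1870,1828.05,8.56,0.244,71.8,2
Ag,165,145,160,107.868,2435,10.501,125.6,1.93,11.28,258,731.0,2070,1234.93,10.27,0.235,429,1
Cd,161,144,155,112.414,1040,8.69,0,1.69,6.21,99.87,867.8,1631.4,594.22,13.00,0.232,96.6,2
I,115,139,140,126.904,457.4,4.933,295.2,2.66,15.52,41.57,1008.4,1845.9,386.85,25.72,0.214,0.449,1
La,195,207,195,138.905,3737,6.145,48.0,1.10,6.20,400,538.1,1067,1193,22.39,0.195,13.4,3
Ce,185,204,185,140.116,3716,6.770,50.0,1.12,5.46,398,534.4,1050,1068,20.69,0.192,11.3,3
Pt,177,136,135,195.084,4098,21.46,205.3,2.28,22.17,469,870.0,1791,2041.4,9.09,0.133,71.6,4
Au,174,136,135,196.967,3129,19.282,222.8,2.54,12.55,324,890.1,1980,1337.33,10.21,0.129,318,3
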