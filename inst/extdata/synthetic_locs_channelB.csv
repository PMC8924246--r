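x_nm,y_nm,frame,precision_nm,channel
3089.22,1321.06,1,17.57,B
3099.29,1334.53,2,20.73,B
3088.27,1283.22,3,22.39,B
3059.55,1314.69,4,20.97,B
3078.64,1328.62,5,19.39,B
3079.92,1340.35,6,19.68,B
3118.43,1293.43,7,18.16,B
3060.92,1250.09,8,20.75,B
3063.7,1353.55,9,18.58,B
3087.25,1326.22,10,18.67,B
3068.36,1313.6,11,22.37,B
3055.48,1340.19,12,19.97,B
3055.94,1323.35,13,19.87,B
3083.62,1348.32,14,19.89,B
3108.82,1321.5,15,21.03,B
3118.04,1326.8,16,18.09,B
3037.2,1280.17,17,20.53,B
3097.89,1365.18,18,18.57,B
3091,1319.14,19,17.66,B
3079.47,1351.77,20,16.95,B
3111.29,1328.8,21,19.14,B
3043.99,1299.3,22,20.65,B
3059.19,1306.66,23,19.85,B
3084.14,1288.55,24,19.35,B
118.72,1770.17,25,17.22,B
105.5,1769.02,26,21.58,B
88.36,1780.57,27,22.03,B
122.2,1770.19,28,17.04,B
117.55,1713.04,29,17.39,B
113.81,1746.03,30,18.68,B
110.83,1704.48,31,17.2,B
76.11,1787.32,32,20.24,B
113.83,1746.7,33,19.51,B
92.77,1764.51,34,23.79,B
89.05,1688.19,35,23.12,B
130.02,1733.65,36,17.98,B
100.18,1746.34,37,20.69,B
98.56,1748.97,38,21.03,B
91.06,1723.26,39,16.63,B
134.96,1723.08,40,19.59,B
114.78,1779.54,41,19.53,B
110.83,1776.34,42,22.46,B
128.53,1761.09,43,21.82,B
87.91,1733.88,44,21.19,B
85.14,1727.13,45,21.19,B
101.05,1767.04,46,21.95,B
134.78,1734.3,47,21.11,B
105.21,1738.44,48,20.74,B
3121.22,2106.55,49,17.66,B
3139,2109.61,50,21.17,B
3093.32,2131.29,51,17.19,B
3094.67,2116.44,52,21.27,B
3084.81,2096.42,53,19.88,B
3105.42,2109.09,54,21.14,B
3140.77,2095.72,55,20.21,B
3121.18,2089.78,56,22.05,B
3099.16,2087.4,57,21.05,B
3113.54,2116.87,58,20.83,B
3134.6,2077.07,59,19.97,B
3127.82,2124.03,60,18.27,B
3089.75,2107.4,61,18.35,B
3095.75,2122.77,62,20.24,B
3127.9,2038.29,63,19.48,B
3162.46,2105.1,64,16.95,B
3113.52,2092.75,65,21.3,B
3135.38,2121.71,66,22.6,B
3128.97,2084.81,67,18.44,B
3146.35,2106.25,68,18.15,B
3127.98,2055.24,69,22.01,B
467.78,1968.26,70,20.16,B
481.78,1886.38,71,20.59,B
479.16,1928.31,72,19.36,B
424.13,1943.11,73,21.75,B
451.9,1960.47,74,16.96,B
455.76,1950.98,75,21.31,B
451.58,1936.93,76,19.79,B
430.28,1926.82,77,21.14,B
458.34,1951.69,78,18.21,B
454.04,1985.65,79,21.84,B
416.9,1993.41,80,21.71,B
420.39,1930.8,81,16.13,B
461.77,1931.53,82,19.26,B
452.95,1939.43,83,18.35,B
445.7,1865,84,20.91,B
466.78,1932.95,85,17.92,B
476.25,1923.49,86,19.12,B
462.39,1907.95,87,22.29,B
425.3,1966.4,88,18.79,B
455.32,1937.53,89,17.65,B
501.9,1920.33,90,22.72,B
496.68,1966.03,91,17.78,B
438.98,1961.82,92,21.48,B
714.33,2569.31,93,17.15,B
692.53,2634.99,94,20.97,B
720.33,2634.07,95,18.89,B
696.29,2569.69,96,16.28,B
698.99,2605.32,97,18.69,B
740.56,2620.84,98,20.92,B
724.54,2600.94,99,18.42,B
719.45,2524.76,100,20.24,B
699.42,2567.88,101,17.97,B
712.06,2599.36,102,20.14,B
746.85,2557.04,103,22.51,B
722.02,2575.29,104,21.23,B
731.07,2581.99,105,17.62,B
742.72,2585.37,106,20.1,B
838.89,835.6,107,17.67,B
777.33,836.72,108,20.39,B
737.03,850.3,109,22.81,B
740.09,837.56,110,18.25,B
773.2,873.81,111,18.38,B
795.6,824.74,112,19.04,B
733.43,893.19,113,17.84,B
790.14,894.93,114,19.59,B
747.92,879.68,115,15.97,B
792.01,860.1,116,21.38,B
781.43,827.12,117,21.82,B
801.26,823.11,118,22.47,B
785.74,842.4,119,21.59,B
798.85,838.63,120,15.01,B
797.51,863.98,121,20.9,B
813.79,850.84,122,21.46,B
787,857.96,123,17.24,B
758.89,889.65,124,20.88,B
800,837.34,125,21.35,B
794.56,843.93,126,17.52,B
3836.39,1322.03,127,20.48,B
3794.28,1331.63,128,19.3,B
3872.44,1270.96,129,21.46,B
3803.9,1307.55,130,20.07,B
3793.1,1345.63,131,21.26,B
3824.4,1328.39,132,21.55,B
3784.1,1323.19,133,17.25,B
3779.11,1349.71,134,19.35,B
3823.67,1351.25,135,21.18,B
3876.66,1276.09,136,18.04,B
3837.75,1313.44,137,23.04,B
3838.79,1327.48,138,22.71,B
3841.6,1320.12,139,17.79,B
3820.71,1310.52,140,19.65,B
3828.53,1293.05,141,21.14,B
1800.7,1204.18,142,18.93,B
1811.32,1192.37,143,18.76,B
1772.21,1216.83,144,21.28,B
1833.37,1169.25,145,20.69,B
1823.27,1189.61,146,22.24,B
1842.16,1230.24,147,17.68,B
1836.31,1176.44,148,17.31,B
1841.88,1209.63,149,23.04,B
1842.2,1201.9,150,20.67,B
1777.99,1214.12,151,20.53,B
1845.43,1192.96,152,22.29,B
1814.95,1172.66,153,18.72,B
1817.04,1179.61,154,19.72,B
1829.88,1212.92,155,23.22,B
1832.02,1171.72,156,24.03,B
1830.58,1147.53,157,23.36,B
1809.34,1231.9,158,15.19,B
1802.04,1199.64,159,21.04,B
1837.09,1181.67,160,20.04,B
2402.54,356.07,161,20.87,B
2374.08,384.46,162,19.27,B
2403.19,375.89,163,21.84,B
2320.8,362.93,164,21.64,B
2324.5,393.98,165,17.2,B
2339.16,393.46,166,21.4,B
2348.66,378.99,167,19.87,B
2368.86,319.69,168,16.94,B
2373.42,346.72,169,21.4,B
2349.03,311.58,170,20.35,B
2355.87,336.1,171,24.03,B
2370.73,327.83,172,23.29,B
2390.98,342.61,173,18.94,B
2398.91,364.23,174,19.4,B
2331.87,360.4,175,20.13,B
2358.85,386.83,176,17.75,B
2393.17,357.08,177,21.1,B
2386.49,374.5,178,21.65,B
2337.33,347.18,179,16.66,B
2382.09,375.04,180,21.79,B
2388.62,368.36,181,17.13,B
1479.74,3273.39,182,22.01,B
1457.71,3305.95,183,20.54,B
1439.48,3300.03,184,19.66,B
1497.15,3278.73,185,21.77,B
1497.93,3286.86,186,20.45,B
1463.73,3307.62,187,19.66,B
1448.92,3323.06,188,20.64,B
1461.25,3340.11,189,18.91,B
1467.17,3327.99,190,19.13,B
1469.57,3329.39,191,21.97,B
1459.74,3324.51,192,21.87,B
1413.9,3313.28,193,17.22,B
1407.69,3286.18,194,17.72,B
1516.99,3325.37,195,17.22,B
1427.09,3341.85,196,21.53,B
1431.69,3287.72,197,19.76,B
1454.04,3337.47,198,20.3,B
1462.14,3298.91,199,17.58,B
1368,1161.05,200,20.56,B
1396.68,1167.96,201,18.38,B
1364.79,1169.18,202,19.88,B
1406.7,1207.86,203,18.19,B
1393.63,1157.21,204,21.32,B
1392.07,1173.72,205,18.81,B
1359.35,1171.15,206,20.66,B
1400.87,1167.22,207,20.04,B
1442.38,1170.52,208,23.25,B
1418.09,1185.49,209,21.55,B
1467.7,1124.16,210,19,B
2782.61,1012.41,211,19.89,B
2770.68,932.63,212,20.29,B
2761.13,946.28,213,19.48,B
2798.6,911.51,214,19.26,B
2784.21,947.22,215,19.34,B
2815.28,984.24,216,21.56,B
2786.13,953.31,217,19.91,B
2788.2,937.17,218,21.85,B
2769.38,968.47,219,18.07,B
2762.51,966.84,220,22.27,B
2826.3,944.08,221,19.8,B
2788.82,933.16,222,17.64,B
2742.25,955.34,223,21.07,B
2805.57,968,224,18.24,B
2821.28,933.43,225,17.06,B
2936.38,1170.89,226,20.56,B
376.88,2214.12,227,22.52,B
2358.24,3508.21,228,21.5,B
3721.31,2818.8,229,19.75,B
3012.16,3027.53,230,19.68,B
1653.82,151.51,231,23.56,B
1614.33,583.25,232,18.65,B
1391.25,3902.76,233,18.07,B
579.82,2883.29,234,18.87,B
2506.85,3301.76,235,17.66,B
3666.26,1811.03,236,18.55,B
3119.19,3587.16,237,19.49,B
1722.88,1602.84,238,20.44,B
2011.71,2396.63,239,19.3,B
573.95,2929.18,240,20.04,B
3445.54,721.67,241,19.07,B
2936.55,482.51,242,18.02,B
2094.03,1385.71,243,18.68,B
3785.77,2787.83,244,19.45,B
1425.51,649.73,245,20.16,B
524.48,1909.17,246,17.83,B
3539.89,1026.04,247,19.94,B
507.85,1416.52,248,20.57,B
2470.42,703.46,249,21.67,B
1702.52,131.62,250,17.83,B
2060.86,2736.82,251,20.04,B
203.95,3022.4,252,23.52,B
1849.77,1932.97,253,20.02,B
807.41,1746.44,254,19.6,B
1152.96,-18,255,19.7,B
403.45,645.29,256,20.07,B
137.63,2458.75,257,16.88,B
3021.89,365.99,258,20.18,B
63.55,3032.76,259,20.05,B
1072.84,3754.79,260,21.97,B
3055.03,3414.77,261,18.64,B
1574.9,1976.31,262,20.74,B
2021.91,3964.68,263,21.25,B
1669.36,2977.14,264,23.63,B
2573.35,295.32,265,15.56,B
3792.3,3244.29,266,19.77,B
1823.81,2074.47,267,21.6,B
3049.36,3227.52,268,19.87,B
2565.1,2695.79,269,20.7,B
3782.04,484.38,270,20.36,B
1416.65,1691.14,271,17.56,B
1307.82,1109.17,272,21.35,B
922.96,954.03,273,27.9,B
776.51,3967.29,274,21.39,B
3339.88,2711.67,275,23.71,B
1114.63,28.03,276,21.42,B
2760.4,2709.04,277,17.07,B
849.81,806.92,278,18.22,B
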