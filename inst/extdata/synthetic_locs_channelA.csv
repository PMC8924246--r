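x_nm,y_nm,frame,precision_nm,channel
387.89,559.15,1,17.71,A
426.35,579.52,2,21.01,A
374.25,571.97,3,22.55,A
397.39,576.36,4,21.07,A
382.42,590.85,5,22.46,A
395,617.73,6,20.51,A
418.1,585.65,7,19.83,A
424.63,646.31,8,23.32,A
407.62,587.74,9,15.11,A
110.07,1794.19,10,20.67,A
83.8,1812.32,11,19.34,A
137.15,1754.55,12,17.3,A
83.94,1778.01,13,24.23,A
101.39,1773.54,14,19.82,A
130.87,1788.26,15,20.91,A
63.08,1770.24,16,20.79,A
130.66,1767.21,17,21.11,A
98.46,1762.82,18,18.91,A
124.59,1811.15,19,23.01,A
102.28,1765.71,20,21.87,A
117.1,1846.45,21,18.83,A
111.94,1767.3,22,17.49,A
82.37,1733.48,23,20.01,A
100.49,1804.21,24,20.3,A
1353.4,2500.42,25,18.27,A
1391.84,2495.84,26,20.52,A
1439.9,2472.08,27,20.49,A
1380.3,2568.61,28,19.28,A
1404.89,2501.69,29,15.67,A
1421.91,2516.5,30,19.33,A
1434.55,2537.96,31,20.67,A
1392.26,2502.16,32,19.15,A
1397.14,2570.9,33,18.53,A
1381.34,2512.04,34,19.14,A
1420.38,2517.61,35,22.2,A
1407.44,2511.44,36,22.74,A
1386.58,2488.87,37,26.24,A
1434.81,2491.6,38,19.68,A
1423.95,2499.65,39,23.21,A
1371.77,2497.89,40,18.78,A
1397.23,2496.96,41,23.01,A
1354.26,2485.88,42,19.48,A
3114.43,645.08,43,17.6,A
3142.4,559.05,44,20.27,A
3158.51,609.33,45,17.04,A
3131.51,577,46,20.08,A
3119.34,631.95,47,17.65,A
3122.38,569.12,48,17.96,A
3095.21,622.28,49,18.11,A
3132.04,621.22,50,21.12,A
3127.86,592.25,51,20.3,A
3126.25,593.45,52,19.78,A
3139.96,666.14,53,18.79,A
3137.74,595.68,54,19.98,A
3124.73,563.5,55,21.08,A
3117.54,582.18,56,20.82,A
3171.53,615.01,57,16.52,A
3183.15,586.11,58,19.11,A
3162.01,634.77,59,19.93,A
3154.69,603.16,60,22.58,A
3137.77,603.52,61,19.11,A
3163.67,615.19,62,18.2,A
3180.27,588.15,63,20.54,A
3341.46,2381.59,64,19.04,A
3268.08,2329.81,65,21.97,A
3309.49,2391.61,66,21.29,A
3287.25,2317.71,67,21.51,A
3317.32,2354.2,68,22.79,A
3318.2,2355.91,69,19.56,A
3335.21,2376.65,70,20.01,A
3268.56,2343.15,71,22.09,A
3292.24,2353.84,72,22.54,A
3270.28,2347.63,73,20.55,A
3299.78,2354.84,74,20.94,A
3343.31,2341.59,75,18.49,A
3309.67,2381.3,76,22.18,A
3330.82,2348.34,77,23.18,A
3311.99,2341.2,78,22.44,A
3317.04,2355.16,79,21.17,A
3159.18,2113.06,80,22.32,A
3203.26,2073.31,81,21.74,A
3177.44,2122.69,82,19.24,A
3176.07,2054.69,83,19.27,A
3156.83,2108.38,84,18.66,A
3185.38,2105.08,85,17.35,A
3163.92,2082.14,86,21.25,A
3194.53,2110.94,87,19.22,A
3156.16,2116.44,88,20.1,A
3182.53,2078.14,89,17.54,A
3150.13,2111.71,90,18.95,A
3161.37,2120.52,91,21.74,A
3199.68,2095.36,92,21.56,A
3135.7,2088.39,93,20.24,A
3207.62,2049.69,94,18.58,A
3210.46,2079.49,95,22.95,A
3213.78,2096.78,96,19.17,A
3192.9,2094.46,97,18.68,A
3214.72,2091.87,98,18.44,A
3201.89,2071.62,99,17.01,A
259.37,3375.62,100,18.57,A
278.57,3421.15,101,17.33,A
275.84,3437.07,102,23.2,A
263.07,3392.1,103,23.37,A
307.74,3436.47,104,17.99,A
310.54,3394.84,105,18.26,A
264.8,3454.34,106,21.2,A
271.31,3438.39,107,23.47,A
269.47,3401.09,108,17.23,A
324.89,3408.37,109,19.15,A
330.68,3380.2,110,21.49,A
232.16,3363.92,111,21.12,A
292.08,3395.47,112,22.77,A
905.19,3146.04,113,22.72,A
907.06,3089.42,114,18.12,A
939.98,3124.03,115,20.6,A
933.36,3167.56,116,17.64,A
919.77,3167.96,117,14.08,A
911.35,3161.41,118,19.41,A
913.01,3146.2,119,15.88,A
967,3171.73,120,19.92,A
918.53,3132.88,121,18.95,A
924.36,3129.57,122,15.09,A
918.6,3142.93,123,20.29,A
884.49,3160.43,124,15.74,A
891.66,3146.91,125,24.25,A
915.91,3207.54,126,19.75,A
914.28,3128.42,127,19.23,A
899.89,3148.33,128,19.56,A
923.22,3175.65,129,16.41,A
900.69,3160.37,130,20.47,A
929.26,3157.3,131,20.42,A
917.58,3182.27,132,19.92,A
905.52,3189.45,133,20.32,A
885.78,3167.8,134,17.74,A
2567.3,3603.57,135,18.53,A
2591.49,3617.61,136,22.12,A
2554.07,3573.61,137,17.93,A
2562.57,3591.03,138,19.89,A
2575.18,3600.36,139,19.68,A
2609.3,3582.8,140,16.66,A
2543.78,3582.47,141,22.05,A
2587.56,3630.36,142,13.05,A
2580.11,3597.51,143,20.19,A
2577.17,3595.67,144,16.23,A
2545.94,3570.14,145,21.91,A
2589.29,3619.22,146,20.02,A
26.11,3521.42,147,21.32,A
76.99,3503.79,148,18.98,A
100.09,3544.93,149,22.08,A
61.47,3511.12,150,19.41,A
134.64,3506.65,151,20.73,A
131.08,3509.62,152,21.05,A
85.72,3486.39,153,19.46,A
60.27,3549.61,154,18.8,A
147.77,3527.92,155,19.96,A
134.54,3526.19,156,19.99,A
115.06,3558.01,157,20.53,A
103.65,3542.4,158,20.63,A
67.69,3498.76,159,17.65,A
118.73,3479.88,160,21.24,A
127.99,3542,161,22.63,A
102.02,3533.88,162,17.53,A
82.91,3525.36,163,17.36,A
2032.65,3176.09,164,16.24,A
2017.41,3191.85,165,20.28,A
1994.23,3192.08,166,20.07,A
1978.73,3189.32,167,19.56,A
2015.28,3182.19,168,20.19,A
1944.89,3170.46,169,21.79,A
1966.75,3179.63,170,17.79,A
1990.14,3184.54,171,20.64,A
2006.16,3136.8,172,19.86,A
2001.48,3198.65,173,19.21,A
1981.36,3232.03,174,21.38,A
1982.56,3184.32,175,17.48,A
2009.96,3210.27,176,18.99,A
1996.77,3229.17,177,20.61,A
1989.09,3141.35,178,24.44,A
1988.43,3177.24,179,18.99,A
2016.68,3179.89,180,24,A
2009.65,3145.41,181,19.4,A
2017.91,3139.58,182,22.29,A
1984.6,3156.7,183,21.01,A
2042.17,3175.28,184,18.76,A
2001.77,3215.36,185,21.64,A
1989.46,3182.89,186,20.97,A
3076.15,1257.3,187,23.88,A
3079.12,1300.07,188,18.21,A
3089.83,1278.62,189,21.16,A
3011.04,1305.79,190,23.53,A
3061.63,1262.37,191,19.04,A
3092.49,1258.04,192,19.84,A
3065.53,1289.01,193,18.44,A
3074.07,1297.2,194,24.28,A
3053.94,1310.17,195,25.87,A
3066.95,1289.25,196,21.63,A
3094.03,1283.81,197,21.96,A
3105.87,1307.48,198,21.89,A
3101.83,1257.84,199,20.37,A
3058.21,1314.28,200,22.26,A
3085.57,1310.69,201,14.72,A
3105.82,1275.26,202,19.96,A
3102.21,1306.73,203,18.26,A
3075.64,1263.27,204,21.27,A
3073.54,1303.91,205,18.93,A
3048.34,1286.57,206,18.03,A
3072.9,1288.08,207,20.07,A
3094.56,1256.7,208,16.5,A
3060.83,1285.92,209,20.54,A
3058.03,1312.17,210,21.27,A
3063.52,1288.79,211,19.24,A
3026.12,1307.13,212,21.43,A
3087.65,1293.53,213,18.04,A
3066.37,1299.09,214,23.61,A
1203.76,114.3,215,17.53,A
3139.92,3386.09,216,21.08,A
2099.94,3035.28,217,20.4,A
823.37,2634.63,218,20.5,A
2078.53,879.44,219,19.72,A
2247.53,1030.31,220,17.76,A
373.86,3893.79,221,21.23,A
848.43,2100.73,222,20.96,A
3441.39,833.82,223,21.07,A
271.06,2778.67,224,18.11,A
1148.47,2361.16,225,18.56,A
228.07,265.65,226,20.21,A
2029.2,2205.53,227,18.89,A
2611.56,430.64,228,18.9,A
998.33,823.42,229,19.51,A
3315.53,3953.01,230,17.35,A
3828.06,239.93,231,19.43,A
1794.89,2947.02,232,19.16,A
1373.19,3644.02,233,21.26,A
405.9,1905.04,234,20.92,A
2265.79,161.35,235,18.45,A
1372.79,2030.7,236,20.32,A
2411.19,101.96,237,16.99,A
484.02,3620.34,238,20.75,A
3032.21,379.98,239,18.58,A
967.99,2624.5,240,18.83,A
1505.67,2577.94,241,17.81,A
3208.58,824.52,242,18.57,A
2973.96,436.67,243,20.08,A
2907.83,710.37,244,15.67,A
1571.77,3979.15,245,19.17,A
120.89,2836.76,246,20.26,A
3591.24,2771.73,247,19.95,A
786.48,3909.7,248,19.25,A
1798.91,916.96,249,22.02,A
3336.56,1216.21,250,18.04,A
3506.46,237.39,251,20.93,A
1475.06,3481.83,252,21.61,A
157.59,3265.04,253,21.15,A
3529.56,1959.54,254,20.63,A
1767.86,586.9,255,21.62,A
3691.09,2750.42,256,17.73,A
3808.78,3733.13,257,19.66,A
59.91,3999.91,258,22.59,A
358.94,1037.19,259,17.47,A
646.86,1760.89,260,18.22,A
465.6,877.22,261,20.86,A
2721.99,3608.72,262,20.13,A
2272.41,1322.06,263,20.61,A
3443.18,3269.71,264,20.53,A
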