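"t","S1","S0","RD"
0,1,1,0
0.05,0.991919,0.990034,0.00188500000000003
0.1,0.983998,0.980036,0.00396200000000002
0.15,0.976009,0.970405,0.00560400000000005
0.2,0.968406,0.960582,0.00782399999999994
0.25,0.960575,0.950948,0.00962699999999994
0.3,0.952902,0.941402,0.0115000000000001
0.35,0.945175,0.932025,0.01315
0.4,0.937596,0.92288,0.014716
0.45,0.930206,0.913648,0.016558
0.5,0.922879,0.904514,0.018365
0.55,0.915475,0.89558,0.019895
0.6,0.908196,0.886755,0.021441
0.65,0.900913,0.877889,0.0230239999999999
0.7,0.893824,0.869102,0.0247219999999999
0.75,0.886749,0.86048,0.026269
0.8,0.879692,0.851915,0.0277770000000001
0.85,0.872621,0.843528,0.0290929999999999
0.9,0.86565,0.835002,0.030648
0.95,0.858835,0.826618,0.0322170000000001
1,0.852034,0.818573,0.033461
1.05,0.845802,0.810376,0.0354260000000001
1.1,0.839607,0.802315,0.037292
1.15,0.833384,0.794152,0.039232
1.2,0.827401,0.786335,0.041066
1.25,0.821366,0.778526,0.04284
1.3,0.815374,0.770758,0.044616
1.35,0.809528,0.762949,0.046579
1.4,0.803714,0.755324,0.04839
1.45,0.797837,0.747775,0.0500620000000001
1.5,0.792022,0.740424,0.051598
1.55,0.78619,0.73305,0.0531400000000001
1.6,0.780541,0.725824,0.054717
1.65,0.774894,0.718545,0.056349
1.7,0.769408,0.711348,0.05806
1.75,0.763767,0.704012,0.059755
1.8,0.758131,0.696966,0.061165
1.85,0.752602,0.689911,0.0626909999999999
1.9,0.747165,0.682999,0.0641659999999999
1.95,0.741835,0.675965,0.06587
2,0.736636,0.669187,0.067449
2.05,0.731588,0.662247,0.069341
2.1,0.72656,0.655662,0.070898
2.15,0.721669,0.649049,0.07262
2.2,0.716665,0.642469,0.074196
2.25,0.711796,0.635923,0.075873
2.3,0.706827,0.629432,0.077395
2.35,0.70207,0.623059,0.0790109999999999
2.4,0.697198,0.616707,0.080491
2.45,0.692516,0.610282,0.082234
2.5,0.687789,0.604213,0.083576
2.55,0.682955,0.598046,0.084909
2.6,0.678258,0.592058,0.0862000000000001
2.65,0.673609,0.586037,0.087572
2.7,0.668974,0.580253,0.0887209999999999
2.75,0.664503,0.574472,0.090031
2.8,0.659883,0.568534,0.091349
2.85,0.655349,0.562831,0.092518
2.9,0.650936,0.557104,0.0938319999999999
2.95,0.646579,0.551401,0.095178
3,0.642235,0.545969,0.096266
3.05,0.638091,0.540358,0.097733
3.1,0.633988,0.534869,0.099119
3.15,0.629832,0.52933,0.100502
3.2,0.6257,0.523894,0.101806
3.25,0.621581,0.518447,0.103134
3.3,0.617531,0.513174,0.104357
3.35,0.613539,0.507938,0.105601
3.4,0.609621,0.502689,0.106932
3.45,0.605714,0.497533,0.108181
3.5,0.601856,0.492399,0.109457
3.55,0.597929,0.487419,0.11051
3.6,0.594054,0.4824,0.111654
3.65,0.590254,0.477399,0.112855
3.7,0.586447,0.472575,0.113872
3.75,0.582634,0.467656,0.114978
3.8,0.578797,0.462782,0.116015
3.85,0.575102,0.45812,0.116982
3.9,0.571381,0.453448,0.117933
3.95,0.567637,0.448816,0.118821
4,0.563905,0.444222,0.119683
4.05,0.560424,0.439595,0.120829
4.1,0.556934,0.43495,0.121984
4.15,0.553383,0.430503,0.12288
4.2,0.549926,0.425985,0.123941
4.25,0.546447,0.421449,0.124998
4.3,0.543083,0.417122,0.125961
4.35,0.539686,0.412659,0.127027
4.4,0.536291,0.408373,0.127918
4.45,0.53295,0.404056,0.128894
4.5,0.529693,0.399792,0.129901
4.55,0.526389,0.395675,0.130714
4.6,0.5232,0.391559,0.131641
4.65,0.519983,0.387282,0.132701
4.7,0.516712,0.383307,0.133405
4.75,0.513474,0.379403,0.134071
4.8,0.510299,0.375382,0.134917
4.85,0.507206,0.371412,0.135794
4.9,0.504026,0.367563,0.136463
4.95,0.501011,0.363777,0.137234
5,0.497922,0.359967,0.137955
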