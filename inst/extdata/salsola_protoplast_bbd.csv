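run_id,A_coded,B_coded,C_coded,A_actual,B_actual,C_actual,yield,viability,viable_cells
1,-1,-1,0,1.00,0.50,0.60,0.575,85.78,0.493
2,1,-1,0,3.00,0.50,0.60,0.256,85.58,0.219
3,-1,1,0,1.00,1.00,0.60,0.683,88.02,0.601
4,1,1,0,3.00,1.00,0.60,0.800,78.69,0.630
5,-1,0,-1,1.00,0.75,0.50,0.563,90.81,0.511
6,1,0,-1,3.00,0.75,0.50,0.383,84.65,0.324
7,-1,0,1,1.00,0.75,0.70,0.583,87.62,0.511
8,1,0,1,3.00,0.75,0.70,0.615,84.27,0.518
9,0,-1,-1,2.00,0.50,0.50,1.125,90.10,1.013
10,0,1,-1,2.00,1.00,0.50,1.460,90.62,1.323
11,0,-1,1,2.00,0.50,0.70,1.320,89.23,1.178
12,0,1,1,2.00,1.00,0.70,1.566,87.27,1.367
13,0,0,0,2.00,0.75,0.60,0.955,89.63,0.856
14,0,0,0,2.00,0.75,0.60,0.945,89.42,0.845
15,0,0,0,2.00,0.75,0.60,1.035,88.25,0.913
16,0,0,0,2.00,0.75,0.60,1.090,88.57,0.965
17,0,0,0,2.00,0.75,0.60,1.010,87.21,0.881
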