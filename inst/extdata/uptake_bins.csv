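t_start,t_end,t_mid,n,mean_fraction,sd_fraction
0.17,0.32,0.24,1,0.096,NA
0.50,0.65,0.58,3,0.167,0.014
0.67,0.82,0.74,4,0.215,0.063
0.83,0.98,0.91,1,0.300,NA
1.17,1.32,1.24,2,0.193,0.071
1.67,1.82,1.74,1,0.434,NA
1.83,1.98,1.91,1,0.321,NA
2.17,2.32,2.24,2,0.283,0.002
2.33,2.48,2.41,2,0.317,0.027
2.50,2.65,2.58,9,0.335,0.028
2.67,2.82,2.74,14,0.320,0.066
2.83,2.98,2.91,17,0.294,0.065
3.00,3.15,3.08,22,0.326,0.065
3.17,3.32,3.24,5,0.283,0.086
3.33,3.48,3.41,2,0.336,0.046
3.50,3.65,3.58,1,0.353,NA
3.67,3.82,3.74,1,0.244,NA
3.83,3.98,3.91,1,0.433,NA
4.00,4.15,4.08,1,0.341,NA
4.17,4.32,4.24,3,0.366,0.058
4.33,4.48,4.41,1,0.344,NA
4.67,4.82,4.74,2,0.395,NA
5.67,5.82,5.74,1,0.474,NA
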