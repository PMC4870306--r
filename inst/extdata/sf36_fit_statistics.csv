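scale,model,label,df,chisq,rmsea,rmsea_lo,rmsea_hi,ecvi,ecvi_lo,ecvi_hi,compared_to,df_diff,chisq_diff,ecvi_diff,ecvi_diff_lo,ecvi_diff_hi,note
MH,1a,measurement,25,61.559,0.058,0.040,0.076,0.279,0.235,0.341,NA,NA,NA,NA,NA,NA,
MH,1b,no_response_shift,31,158.28,0.097,0.082,0.112,0.386,0.304,0.485,1a,6,96.72,0.194,0.123,0.276,
MH,1c,response_shift,28,62.979,0.054,0.036,0.071,0.268,0.224,0.330,1a,3,1.320,-0.011,-0.007,0.003,
GH,2a,measurement,29,61.286,0.047,0.031,0.063,0.162,0.115,0.227,NA,NA,NA,NA,NA,NA,printed RMSEA appears swapped with model 2b
GH,2b,no_response_shift,37,72.601,0.051,0.033,0.068,0.173,0.130,0.233,2a,8,11.32,-0.011,-0.018,0.019,printed RMSEA appears swapped with model 2a
PF,3a,measurement,151,339.06,0.053,0.046,0.061,1.048,0.935,1.180,NA,NA,NA,NA,NA,NA,Satorra-Bentler mean-adjusted chi-square
PF,3b,no_response_shift,169,477.64,0.065,0.058,0.072,1.284,1.143,1.442,3a,18,380.7,0.791,0.654,0.945,difference uses unadjusted DWLS chi-squares
PF,3c,response_shift,166,374.98,0.054,0.047,0.061,1.062,0.942,1.200,3a,15,46.75,0.038,-0.001,0.095,difference uses unadjusted DWLS chi-squares
RP,4a,measurement,15,29.727,0.048,0.021,0.072,0.165,0.138,0.210,NA,NA,NA,NA,NA,NA,printed RMSEA 0.048 vs 0.0475 computed from printed T and df
RP,4b,no_response_shift,18,72.543,0.083,0.064,0.104,0.249,0.120,0.318,NA,NA,NA,NA,NA,NA,
RP,4c,response_shift,17,51.313,0.068,0.047,0.090,0.205,0.164,0.263,NA,NA,NA,NA,NA,NA,
BP,5a,measurement,1,1.798,0.043,0.000,0.143,0.045,0.044,0.064,NA,NA,NA,NA,NA,NA,
BP,5b,no_response_shift,3,39.766,0.168,0.124,0.216,0.123,0.085,0.179,5a,2,37.968,0.078,0.040,0.133,
BP,5c,response_shift,2,5.941,0.067,0.000,0.133,0.073,0.038,0.125,5a,1,4.143,0.005,-0.002,0.029,
SF,6a,measurement,1,0.143,0.000,0.000,0.092,0.042,0.044,0.052,NA,NA,NA,NA,NA,NA,
SF,6b,no_response_shift,2,1.303,0.000,0.000,0.084,0.040,0.041,0.055,6a,1,1.16,-0.002,-0.002,0.015,
RE,7a,measurement,5,13.022,0.061,0.021,0.102,0.103,0.087,0.137,NA,NA,NA,NA,NA,NA,
RE,7b,no_response_shift,7,17.834,0.060,0.026,0.095,0.105,0.085,0.143,NA,NA,NA,NA,NA,NA,
VT,8a,measurement,11,4.730,0.000,0.000,0.009,0.126,0.140,0.141,NA,NA,NA,NA,NA,NA,
VT,8b,no_response_shift,17,12.326,0.000,0.000,0.030,0.116,0.126,0.141,8a,6,7.596,-0.010,-0.014,0.016,
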