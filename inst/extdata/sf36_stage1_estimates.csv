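scale,item,m,bvn,inv_df,inv_chisq,inv_p,t1,t2,t3,t4,t5,mean_pre,mean_post,sd_pre,sd_post,rho,excluded,note
MH,24,6,TRUE,3,4.14,0.25,-1.96,-1.41,-0.90,0.19,0.85,3.23,3.83,1.74,1.85,0.59,FALSE,
MH,25,6,TRUE,3,0.59,0.90,-2.34,-1.84,-1.14,-0.63,0.10,4.70,4.75,2.19,1.84,0.61,FALSE,
MH,26,6,TRUE,3,15.6,0.009,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,TRUE,threshold invariance rejected; occasion-specific thresholds (pre -1.62 -0.92 -0.23 0.16 1.20; post -1.69 -1.03 -0.23 0.03 1.24)
MH,28,6,TRUE,3,5.52,0.14,-2.16,-1.64,-1.16,-0.13,0.60,4.09,4.24,1.96,1.90,0.53,FALSE,
MH,30,6,TRUE,3,5.41,0.14,-1.68,-1.28,-0.51,-0.21,0.62,4.40,4.12,2.61,2.47,0.64,FALSE,
GH,1,5,TRUE,2,3.61,0.16,-1.31,-0.07,1.10,1.65,NA,1.08,1.04,0.90,0.71,0.62,FALSE,
GH,33,5,TRUE,2,3.63,0.16,-1.62,-1.17,-0.23,0.14,NA,3.72,3.40,2.32,2.05,0.55,FALSE,
GH,34,5,TRUE,2,4.88,0.09,-0.77,-0.10,0.52,1.13,NA,1.19,1.11,1.56,1.41,0.49,FALSE,
GH,35,5,TRUE,2,2.25,0.32,-1.34,-0.79,0.31,0.72,NA,2.39,2.46,1.91,1.72,0.56,FALSE,
GH,36,5,TRUE,2,4.91,0.09,-0.53,-0.07,0.44,1.26,NA,1.22,1.07,2.29,2.02,0.62,FALSE,
PF,3,3,TRUE,NA,NA,NA,0.37,1.55,NA,NA,NA,-0.26,-0.38,0.80,0.91,0.60,FALSE,
PF,4,3,TRUE,NA,NA,NA,-0.48,0.63,NA,NA,NA,0.42,0.45,0.91,0.89,0.65,FALSE,
PF,5,3,TRUE,NA,NA,NA,-0.59,0.59,NA,NA,NA,0.49,0.51,0.90,0.79,0.72,FALSE,
PF,6,3,TRUE,NA,NA,NA,-0.79,0.18,NA,NA,NA,0.91,0.73,1.05,1.02,0.74,FALSE,
PF,7,3,TRUE,NA,NA,NA,-1.48,-0.39,NA,NA,NA,1.40,1.31,0.95,0.88,0.71,FALSE,
PF,8,3,TRUE,NA,NA,NA,-1.12,-0.06,NA,NA,NA,1.06,1.06,0.94,0.95,0.73,FALSE,
PF,9,3,TRUE,NA,NA,NA,-0.60,0.17,NA,NA,NA,0.81,0.74,1.28,1.32,0.74,FALSE,
PF,10,3,TRUE,NA,NA,NA,-1.08,-0.36,NA,NA,NA,1.55,1.45,1.34,1.43,0.70,FALSE,
PF,11,3,TRUE,NA,NA,NA,-1.36,-0.65,NA,NA,NA,1.91,1.95,1.36,1.48,0.67,FALSE,
PF,12,3,TRUE,NA,NA,NA,-1.78,-0.98,NA,NA,NA,1.96,2.52,1.00,1.47,0.66,FALSE,
RP,13,2,NA,NA,NA,NA,0.47,NA,NA,NA,NA,-0.53,-0.42,1.00,1.00,0.52,FALSE,
RP,14,2,NA,NA,NA,NA,0.22,NA,NA,NA,NA,-0.23,-0.21,1.00,1.00,0.51,FALSE,
RP,15,2,NA,NA,NA,NA,0.47,NA,NA,NA,NA,-0.44,-0.51,1.00,1.00,0.55,FALSE,
RP,16,2,NA,NA,NA,NA,0.38,NA,NA,NA,NA,-0.32,-0.45,1.00,1.00,0.49,FALSE,
BP,21,6,TRUE,3,9.77,0.02,-2.34,-1.53,-0.55,NA,0.41,2.92,2.85,1.18,1.28,0.55,FALSE,4th printed threshold corrupt in source table
BP,22,5,TRUE,2,0.58,0.75,-1.74,-1.23,-0.56,0.11,NA,3.63,2.85,2.06,1.28,0.51,TRUE,printed means/SDs inconsistent with printed effect size; excluded from numeric checks
SF,20,5,TRUE,2,1.48,0.48,-1.98,-1.38,-0.90,-0.06,NA,3.28,3.28,1.61,1.71,0.42,FALSE,
SF,32,5,TRUE,2,3.09,0.21,-1.51,-1.02,-0.05,0.33,NA,3.16,3.06,1.98,2.15,0.48,FALSE,
RE,17,2,NA,NA,NA,NA,-0.19,NA,NA,NA,NA,0.14,0.25,1.00,1.00,0.52,FALSE,
RE,18,2,NA,NA,NA,NA,-0.21,NA,NA,NA,NA,0.16,0.25,1.00,1.00,0.60,FALSE,
RE,19,2,NA,NA,NA,NA,-0.40,NA,NA,NA,NA,0.39,0.42,1.00,1.00,0.47,FALSE,
VT,23,6,TRUE,3,6.67,0.08,-1.74,-1.17,-0.31,0.04,0.99,3.18,2.90,1.77,1.72,0.56,FALSE,
VT,27,6,TRUE,3,1.05,0.79,-1.48,-0.66,0.18,0.52,1.26,1.93,1.68,1.24,1.21,0.58,FALSE,
VT,29,6,TRUE,3,3.46,0.33,-1.89,-1.43,-0.86,0.07,0.64,4.36,3.95,2.31,2.08,0.45,FALSE,
VT,31,6,TRUE,3,5.86,0.12,-1.46,-0.83,-0.27,0.77,1.32,2.47,2.16,1.64,1.64,0.52,FALSE,
HC,2,5,TRUE,2,6.96,0.03,NA,NA,NA,NA,NA,1.77,1.97,1.22,1.35,0.03,FALSE,printed threshold row corrupt in source table
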