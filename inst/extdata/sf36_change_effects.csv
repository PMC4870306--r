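scale,item,observed,observed_stars,stage1_true,stage1_true_stars,modeled,modeled_stars,recalibration,recalibration_stars,reprioritization,reprioritization_stars,stage2_true,stage2_true_stars,note
MH,24,0.33,**,0.37,**,0.36,**,0.30,**,0.01,,0.04,,
MH,25,0.12,*,0.03,,0.06,,NA,,NA,,0.06,,
MH,26,0.06,,NA,,NA,,NA,,NA,,NA,,stage 1 recalibration; stage 2 change not interpretable
MH,28,0.08,,0.08,,0.05,,NA,,NA,,0.05,,
MH,30,-0.08,,-0.13,*,-0.13,*,-0.16,**,NA,,0.03,,
GH,1,-0.08,,-0.05,,-0.08,,NA,,NA,,-0.08,,
GH,33,-0.08,,-0.15,*,-0.04,,NA,,NA,,-0.04,,
GH,34,-0.06,,-0.06,,-0.07,,NA,,NA,,-0.07,,
GH,35,0.05,,0.04,,-0.05,,NA,,NA,,-0.05,,
GH,36,-0.08,,-0.08,,-0.11,*,NA,,NA,,-0.11,*,
PF,3,-0.04,,-0.15,*,-0.04,,NA,,0.00,,-0.04,,
PF,4,0.03,,0.04,,-0.04,,NA,,NA,,-0.04,,
PF,5,0.02,,0.02,,-0.04,,NA,,NA,,-0.04,,
PF,6,-0.17,**,-0.24,**,-0.05,,NA,,NA,,-0.05,,
PF,7,-0.04,,-0.12,*,-0.05,,NA,,NA,,-0.05,,
PF,8,0.00,,0.00,,-0.05,,NA,,NA,,-0.05,,
PF,9,-0.06,,-0.08,,-0.05,,NA,,NA,,-0.05,,
PF,10,-0.10,*,-0.10,*,-0.06,,NA,,NA,,-0.06,,
PF,11,-0.04,,0.03,,-0.05,,NA,,NA,,-0.05,,
PF,12,0.00,,0.51,**,0.46,**,0.51,**,-0.02,,-0.03,,
RP,13,0.07,,0.11,*,0.02,,0.08,,NA,,-0.06,,
RP,14,0.02,,0.03,,-0.06,,NA,,NA,,-0.06,,
RP,15,-0.04,,-0.07,,-0.07,,NA,,NA,,-0.07,,
RP,16,-0.09,,-0.13,*,-0.06,,NA,,NA,,-0.06,,
BP,21,-0.07,,-0.06,,-0.06,,-0.23,**,NA,,0.17,**,
BP,22,0.08,,0.16,**,0.16,**,NA,,NA,,0.16,**,
SF,20,-0.03,,0.00,,-0.04,,NA,,NA,,-0.04,,
SF,32,-0.06,,-0.05,,-0.03,,NA,,NA,,-0.03,,
RE,17,0.08,,0.12,*,0.09,,NA,,NA,,0.09,,
RE,18,0.06,,0.09,,0.10,*,NA,,NA,,0.10,*,
RE,19,0.02,,0.04,,0.08,,NA,,NA,,0.08,,
VT,23,-0.13,*,-0.17,**,-0.19,**,NA,,NA,,-0.19,**,
VT,27,-0.20,**,-0.22,**,-0.27,**,NA,,NA,,-0.27,**,
VT,29,-0.14,*,-0.18,**,-0.16,**,NA,,NA,,-0.16,**,
VT,31,-0.18,**,-0.20,**,-0.20,**,NA,,NA,,-0.20,**,
HC,2,0.11,*,0.11,*,NA,,NA,,NA,,NA,,single-item scale; stage 1 only
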