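scale,item,occasion,m,c1,c2,c3,c4,c5,c6
MH,24,1,6,14,30,55,182,91,64
MH,24,2,6,10,16,35,154,118,103
MH,25,1,6,7,13,24,80,112,200
MH,25,2,6,2,7,16,76,136,199
MH,26,1,6,23,55,100,69,141,48
MH,26,2,6,20,45,114,45,167,45
MH,28,1,6,8,17,33,145,119,114
MH,28,2,6,7,12,22,153,120,122
MH,30,1,6,20,22,85,48,135,126
MH,30,2,6,21,29,81,52,154,99
GH,1,1,5,50,153,162,40,31,NA
GH,1,2,5,32,179,174,40,11,NA
GH,33,1,5,24,29,118,60,205,NA
GH,33,2,5,20,41,131,59,185,NA
GH,34,1,5,94,100,102,76,64,NA
GH,34,2,5,99,91,125,73,48,NA
GH,35,1,5,46,56,172,58,104,NA
GH,35,2,5,35,47,197,56,101,NA
GH,36,1,5,130,71,80,101,54,NA
GH,36,2,5,131,87,71,112,35,NA
PF,3,1,3,274,138,25,NA,NA,NA
PF,3,2,3,289,120,28,NA,NA,NA
PF,4,1,3,142,181,114,NA,NA,NA
PF,4,2,3,135,185,117,NA,NA,NA
PF,5,1,3,128,184,125,NA,NA,NA
PF,5,2,3,114,161,172,NA,NA,NA
PF,6,1,3,85,149,203,NA,NA,NA
PF,6,2,3,104,161,172,NA,NA,NA
PF,7,1,3,31,117,289,NA,NA,NA
PF,7,2,3,30,128,279,NA,NA,NA
PF,8,1,3,57,151,229,NA,NA,NA
PF,8,2,3,58,150,229,NA,NA,NA
PF,9,1,3,115,129,193,NA,NA,NA
PF,9,2,3,126,127,184,NA,NA,NA
PF,10,1,3,54,95,288,NA,NA,NA
PF,10,2,3,68,97,272,NA,NA,NA
PF,11,1,3,35,75,327,NA,NA,NA
PF,11,2,3,41,73,323,NA,NA,NA
PF,12,1,3,11,63,363,NA,NA,NA
PF,12,2,3,19,47,371,NA,NA,NA
RP,13,1,2,306,131,NA,NA,NA,NA
RP,13,2,2,290,147,NA,NA,NA,NA
RP,14,1,2,259,178,NA,NA,NA,NA
RP,14,2,2,254,183,NA,NA,NA,NA
RP,15,1,2,293,144,NA,NA,NA,NA
RP,15,2,2,303,134,NA,NA,NA,NA
RP,16,1,2,273,164,NA,NA,NA,NA
RP,16,2,2,294,143,NA,NA,NA,NA
BP,21,1,6,3,20,97,78,88,151
BP,21,2,6,7,21,93,95,81,140
BP,22,1,5,17,27,89,120,184,NA
BP,22,2,5,13,23,49,125,227,NA
SF,20,1,5,9,25,43,131,229,NA
SF,20,2,5,13,23,49,125,227,NA
SF,32,1,5,24,36,145,68,164,NA
SF,32,2,5,34,41,132,74,156,NA
RE,17,1,2,195,242,NA,NA,NA,NA
RE,17,2,2,175,262,NA,NA,NA,NA
RE,18,1,2,190,247,NA,NA,NA,NA
RE,18,2,2,176,261,NA,NA,NA,NA
RE,19,1,2,153,284,NA,NA,NA,NA
RE,19,2,2,147,290,NA,NA,NA,NA
VT,23,1,6,16,32,105,58,145,81
VT,23,2,6,21,42,104,60,155,55
VT,27,1,6,26,73,133,56,94,55
VT,27,2,6,35,96,134,53,83,36
VT,29,1,6,13,19,48,135,90,132
VT,29,2,6,11,28,56,147,100,95
VT,31,1,6,29,52,77,166,61,52
VT,31,2,6,37,53,106,155,56,20
HC,2,1,5,32,83,272,43,7,NA
HC,2,2,5,34,69,243,78,13,NA
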