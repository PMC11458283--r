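trait,level,run,subject,mean,sd
CP_ADC,diet,1,Ref_1,98,0.09
CP_ADC,diet,1,RegFeM_diet,86,1.14
CP_ADC,diet,1,GoldFeM_diet,93,0.62
CP_ADC,diet,1,IRFeM_diet,97,0.10
CP_ADC,diet,1,PBM_64_diet,95,0.32
CP_ADC,diet,1,CM_diet,97,0.22
CP_ADC,diet,2,Ref_2,98,0.17
CP_ADC,diet,2,IRFeM_plus_diet,97,0.07
CP_ADC,diet,3,Ref_3,98,0.37
CP_ADC,diet,3,PBM_LA_diet,96,0.16
CP_ADC,diet,3,PBM_50_diet,89,0.25
CP_ADC,diet,3,PPCon_diet,99,0.01
CP_ADC,diet,3,BM_diet,93,0.25
CP_ADC,diet,3,IRSBM_diet,98,0.08
CP_ADC,ingredient,1,RegFeM,73,2.42
CP_ADC,ingredient,1,GoldFeM,88,1.27
CP_ADC,ingredient,1,IRFeM,96,0.22
CP_ADC,ingredient,1,PBM_64,89,0.80
CP_ADC,ingredient,1,CM,94,0.81
CP_ADC,ingredient,2,IRFeM_plus,96,0.15
CP_ADC,ingredient,3,PBM_LA,93,0.38
CP_ADC,ingredient,3,PBM_50,73,0.68
CP_ADC,ingredient,3,PPCon,100,0.06
CP_ADC,ingredient,3,BM,87,0.51
CP_ADC,ingredient,3,IRSBM,97,0.24
NPV,diet,1,Ref_1,46,6.97
NPV,diet,1,RegFeM_diet,29,8.92
NPV,diet,1,GoldFeM_diet,33,3.72
NPV,diet,1,IRFeM_diet,23,6.50
NPV,diet,1,PBM_64_diet,46,7.69
NPV,diet,1,CM_diet,40,11.53
NPV,diet,2,Ref_2,45,7.74
NPV,diet,2,IRFeM_plus_diet,25,1.62
NPV,diet,3,Ref_3,39,1.75
NPV,diet,3,PBM_LA_diet,40,0.61
NPV,diet,3,PBM_50_diet,35,1.52
NPV,diet,3,PPCon_diet,38,2.93
NPV,diet,3,BM_diet,31,1.53
NPV,diet,3,IRSBM_diet,38,1.95
NPV,ingredient,1,RegFeM,11,18.76
NPV,ingredient,1,GoldFeM,18,7.75
NPV,ingredient,1,IRFeM,-6,14.48
NPV,ingredient,1,PBM_64,46,19.00
NPV,ingredient,1,CM,24,42.44
NPV,ingredient,2,IRFeM_plus,0.34,3.64
NPV,ingredient,3,PBM_LA,40,1.31
NPV,ingredient,3,PBM_50,27,4.11
NPV,ingredient,3,PPCon,37,6.60
NPV,ingredient,3,BM,23,3.06
NPV,ingredient,3,IRSBM,37,5.71
CL_ADC,diet,1,Ref_1,94,0.67
CL_ADC,diet,1,RegFeM_diet,83,1.18
CL_ADC,diet,1,GoldFeM_diet,88,0.64
CL_ADC,diet,1,IRFeM_diet,90,0.14
CL_ADC,diet,1,PBM_64_diet,94,0.73
CL_ADC,diet,1,CM_diet,95,0.35
CL_ADC,diet,2,Ref_2,89,0.98
CL_ADC,diet,2,IRFeM_plus_diet,87,0.54
CL_ADC,diet,3,Ref_3,90,1.24
CL_ADC,diet,3,PBM_LA_diet,92,0.77
CL_ADC,diet,3,PBM_50_diet,89,1.22
CL_ADC,diet,3,PPCon_diet,91,0.50
CL_ADC,diet,3,BM_diet,85,1.43
CL_ADC,diet,3,IRSBM_diet,89,1.73
CL_ADC,ingredient,1,RegFeM,24,8.08
CL_ADC,ingredient,1,GoldFeM,39,5.97
CL_ADC,ingredient,1,IRFeM,6,3.65
CL_ADC,ingredient,1,PBM_64,98,3.23
CL_ADC,ingredient,1,CM,101,1.67
CL_ADC,ingredient,2,IRFeM_plus,55,13.97
CL_ADC,ingredient,3,PBM_LA,99,3.51
CL_ADC,ingredient,3,PBM_50,87,4.78
CL_ADC,ingredient,3,PPCon,95,2.71
CL_ADC,ingredient,3,BM,-39,33.82
CL_ADC,ingredient,3,IRSBM,84,19.73
LPV,diet,1,Ref_1,81,10.1
LPV,diet,1,RegFeM_diet,55,14.3
LPV,diet,1,GoldFeM_diet,66,6.8
LPV,diet,1,IRFeM_diet,60,8.0
LPV,diet,1,PBM_64_diet,76,13.7
LPV,diet,1,CM_diet,67,14.5
LPV,diet,2,Ref_2,50,7.6
LPV,diet,2,IRFeM_plus_diet,22,8.5
LPV,diet,3,Ref_3,74,1.4
LPV,diet,3,PBM_LA_diet,76,1.0
LPV,diet,3,PBM_50_diet,68,3.2
LPV,diet,3,PPCon_diet,74,7.0
LPV,diet,3,BM_diet,67,8.1
LPV,diet,3,IRSBM_diet,70,4.3
LPV,ingredient,1,RegFeM,-94,98.6
LPV,ingredient,1,GoldFeM,-54,63.9
LPV,ingredient,1,IRFeM,-459,208.0
LPV,ingredient,1,PBM_64,58,60.9
LPV,ingredient,1,CM,17,68.1
LPV,ingredient,2,IRFeM_plus,-669,220.3
LPV,ingredient,3,PBM_LA,85,4.8
LPV,ingredient,3,PBM_50,50,12.5
LPV,ingredient,3,PPCon,72,38.3
LPV,ingredient,3,BM,-94,190.0
LPV,ingredient,3,IRSBM,22,49.3
OM_ADC,diet,1,Ref_1,80,0.58
OM_ADC,diet,1,RegFeM_diet,73,2.06
OM_ADC,diet,1,GoldFeM_diet,79,0.88
OM_ADC,diet,1,IRFeM_diet,82,0.19
OM_ADC,diet,1,PBM_64_diet,80,0.45
OM_ADC,diet,1,CM_diet,75,0.13
OM_ADC,diet,2,Ref_2,76,1.26
OM_ADC,diet,2,IRFeM_plus_diet,81,0.46
OM_ADC,diet,3,Ref_3,79,1.5
OM_ADC,diet,3,PBM_LA_diet,83,0.30
OM_ADC,diet,3,PBM_50_diet,78,0.36
OM_ADC,diet,3,PPCon_diet,85,0.21
OM_ADC,diet,3,BM_diet,81,0.54
OM_ADC,diet,3,IRSBM_diet,81,0.40
OM_ADC,ingredient,1,RegFeM,58,6.81
OM_ADC,ingredient,1,GoldFeM,77,2.91
OM_ADC,ingredient,1,IRFeM,88,0.71
OM_ADC,ingredient,1,PBM_64,81,1.64
OM_ADC,ingredient,1,CM,65,0.46
OM_ADC,ingredient,2,IRFeM_plus,92,1.67
OM_ADC,ingredient,3,PBM_LA,93,1.04
OM_ADC,ingredient,3,PBM_50,73,1.60
OM_ADC,ingredient,3,PPCon,100,0.72
OM_ADC,ingredient,3,BM,85,1.76
OM_ADC,ingredient,3,IRSBM,85,1.38
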