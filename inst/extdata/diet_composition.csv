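diet_id,run,role,ingredient,dry_matter,gross_energy,crude_protein,crude_lipid,crude_fiber,crude_ash,tio2,ph,printed_nfe,printed_om,printed_nfe_om
Ref_1,1,reference,,909,23.4,434,174,88,32,5.4,4.9,272,968,28
RegFeM_diet,1,test,RegFeM,910,23.8,593,154,68,32,5.6,5.0,153,968,16
GoldFeM_diet,1,test,GoldFeM,906,23.7,601,144,70,30,5.4,5.3,155,970,16
IRFeM_diet,1,test,IRFeM,897,22.9,553,127,65,55,5.4,7.0,200,945,21
PBM_64_diet,1,test,PBM_64,915,23.1,557,173,69,65,5.4,5.3,136,935,15
CM_diet,1,test,CM,902,22.8,437,175,100,44,5.4,5.4,244,956,26
Ref_2,2,reference,,909,23.4,434,174,88,32,5.4,4.9,272,968,28
IRFeM_plus_diet,2,test,IRFeM_plus,896,22.2,558,128,64,56,5.4,6.5,194,944,21
Ref_3,3,reference,,897,23.0,399,183,70,52,5.4,8.9,296,948,31
PBM_LA_diet,3,test,PBM_LA,902,23.4,502,176,50,70,5.3,7.8,202,930,22
PBM_50_diet,3,test,PBM_50,888,29.8,465,149,50,137,5.3,8.1,202,863,23
PPCon_diet,3,test,PPCon,902,23.0,516,169,44,67,5.3,7.1,204,933,22
BM_diet,3,test,BM,906,23.4,568,124,49,46,5.3,7.6,213,954,22
IRSBM_diet,3,test,IRSBM,873,22.1,427,138,71,64,5.4,8.0,300,936,32
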