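ingredient,run,dry_matter,crude_protein,crude_lipid,crude_ash,organic_matter
RegFeM,1,960,925,69,25,975
GoldFeM,1,921,947,49,19,981
IRFeM,1,913,832,16,132,868
PBM_64,1,938,696,118,143,857
CM,1,923,379,110,74,926
IRFeM_plus,2,913,832,16,132,868
PBM_LA,3,927,745,120,120,880
PBM_50,3,955,544,147,334,666
PPCon,3,957,745,96,106,894
BM,3,928,958,19,32,968
IRSBM,3,945,491,41,92,908
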