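lake_code,area_ha,n,region,latitude,longitude,altitude,stocked
CA,746,17,Abitibi-Temiscamingue,46.54,-78.31,329,FALSE
HA,39,36,Abitibi-Temiscamingue,48.47,-78.70,363,FALSE
MG,622,19,Abitibi-Temiscamingue,46.53,-78.39,253,FALSE
KI,30044,17,Abitibi-Temiscamingue,46.91,-78.99,269,TRUE
PA,109,30,Outaouais,46.14,-76.20,252,TRUE
CE,793,22,Outaouais,46.30,-76.11,181,TRUE
AC,673,28,Outaouais,46.25,-77.10,283,TRUE
CY,725,41,Outaouais,46.12,-76.27,194,TRUE
BS,1437,30,Outaouais,46.22,-76.05,164,TRUE
MI,4973,34,Outaouais,46.19,-75.81,159,TRUE
BO,531,17,Laurentides,47.08,-75.85,299,FALSE
MA,919,18,Laurentides,47.03,-75.80,329,FALSE
TU,352,34,Laurentides,47.44,-74.85,436,FALSE
GR,137,19,Laurentides,46.65,-74.56,485,TRUE
PM,357,26,Laurentides,46.39,-75.29,317,TRUE
TZ,958,24,Laurentides,46.25,-74.64,226,TRUE
CR,1267,15,Laurentides,46.28,-75.50,209,TRUE
PB,5475,17,Laurentides,45.97,-75.74,198,TRUE
AL,40663,15,Nord-du-Quebec,50.90,-73.29,390,FALSE
OF,5110,29,Nord-du-Quebec,54.55,-72.43,431,FALSE
WA,8184,25,Nord-du-Quebec,50.15,-73.99,463,FALSE
ES,743,32,Bas-St-Laurent,47.19,-69.56,321,TRUE
PO,894,10,Bas-St-Laurent,47.49,-69.27,207,TRUE
MZ,1864,23,Bas-St-Laurent,48.32,-67.80,271,TRUE
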