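group,sample,size,subgroup
European hunter-gatherers,Western,3,hunter_gatherers
European hunter-gatherers,Switzerland,1,hunter_gatherers
European hunter-gatherers,Sweden,1,hunter_gatherers
European hunter-gatherers,Motala,6,hunter_gatherers
European hunter-gatherers,Eastern,3,hunter_gatherers
Early Neolithic,Anatolia,2,early_farmers
Early Neolithic,Anatolia_Neolithic,24,early_farmers
Early Neolithic,Macedonia_EN,1,early_farmers
Early Neolithic,Macedonia_LN,2,early_farmers
Early Neolithic,Hungary_EN,10,early_farmers
Early Neolithic,LBK_EN,15,early_farmers
Early Neolithic,Iberia_EN,4,early_farmers
Eneolithic to Middle Bronze Age steppe,Samara_Eneolithic,3,samara_eneolithic
Eneolithic to Middle Bronze Age steppe,Yamnaya_Kalmykia,6,steppe_emba
Eneolithic to Middle Bronze Age steppe,Yamnaya_Samara,9,steppe_emba
Eneolithic to Middle Bronze Age steppe,Afanasievo,5,steppe_emba
Eneolithic to Middle Bronze Age steppe,Poltavka,4,steppe_emba
Eneolithic to Middle Bronze Age steppe,Potapovka,3,steppe_emba
Middle Neolithic to Copper Age Europe,Iberia_MN,4,middle_neolithic
Middle Neolithic to Copper Age Europe,Central_MN,6,middle_neolithic
Middle Neolithic to Copper Age Europe,Sweden,1,copper_age
Middle Neolithic to Copper Age Europe,Remedello,3,copper_age
Middle Neolithic to Copper Age Europe,Tyrol,1,copper_age
Middle Neolithic to Copper Age Europe,Iberia_Chalcolithic,12,copper_age
Middle Neolithic to Copper Age Europe,Spain,3,copper_age
Middle Neolithic to Copper Age Europe,Anatolia_ChL,1,copper_age
Bronze Age Europe,Russia_EBA,1,bronze_age_europe
Bronze Age Europe,Northern_LNBA,10,bronze_age_europe
Bronze Age Europe,Central_LNBA,35,bronze_age_europe
Bronze Age Europe,Bell_Beaker_LN,17,bronze_age_europe
Bronze Age Europe,Hungary_BA,12,bronze_age_europe
Late Bronze to Iron Age steppe,Sintashta,5,steppe_lbia
Late Bronze to Iron Age steppe,Andronovo,3,steppe_lbia
Late Bronze to Iron Age steppe,Srubnaya,12,steppe_lbia
Late Bronze to Iron Age steppe,Scythia,1,steppe_lbia
Western Asia,Georgia,2,western_asia
Western Asia,Iran_HotuIIIb,1,western_asia
Western Asia,Iran_N,4,western_asia
Western Asia,Iran_EN,4,western_asia
Western Asia,Iran_LN,1,western_asia
Western Asia,Iran_ChL,5,western_asia
Western Asia,Armenia_ChL,5,western_asia
Western Asia,Armenia_EBA,3,western_asia
Western Asia,Armenia_MLBA,1,western_asia
Western Asia,Iran_IA,1,western_asia
Western Asia,Iran_recent,1,western_asia
Western Asia,Natufian,6,western_asia
Western Asia,Levant_N,13,western_asia
Western Asia,Levant_BA,3,western_asia
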