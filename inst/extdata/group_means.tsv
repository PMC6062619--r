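subgroup	ancestry	percent
hunter_gatherers	Northern European	71.6
hunter_gatherers	Southern European	27.4
hunter_gatherers	Oceanian	0.9
early_farmers	Southern European	47.2
early_farmers	Western Asian	31.9
early_farmers	Arabian	14.2
early_farmers	Northern African	6.8
samara_eneolithic	Northern European	64.4
samara_eneolithic	Southern Asian	18.2
samara_eneolithic	Circumpolar	8.8
samara_eneolithic	Amerindian	4.3
samara_eneolithic	Southern European	4.3
steppe_emba	Northern European	54.7
steppe_emba	Southern Asian	27.8
steppe_emba	Southern European	7.9
steppe_emba	Kalash	4.7
steppe_emba	Amerindian	4.2
steppe_emba	Western Asian	0.8
middle_neolithic	Southern European	64.2
middle_neolithic	Western Asian	18.2
middle_neolithic	Northern European	6.2
middle_neolithic	Arabian	6.2
middle_neolithic	Northern African	4.3
middle_neolithic	Oceanian	0.9
copper_age	Southern European	71.8
copper_age	Western Asian	10.9
copper_age	Northern European	7.6
copper_age	Northern African	5.6
copper_age	Arabian	4.2
bronze_age_europe	Northern European	49
bronze_age_europe	Southern European	40
bronze_age_europe	Western Asian	5.9
bronze_age_europe	Southern Asian	5.1
steppe_lbia	Northern European	50.9
steppe_lbia	Southern European	23.9
steppe_lbia	Southern Asian	17.7
steppe_lbia	Kalash	3.4
steppe_lbia	Western Asian	2.5
steppe_lbia	Amerindian	1.6
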