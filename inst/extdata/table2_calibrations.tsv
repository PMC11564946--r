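id	ingroup_taxa	placement	prior_mean_ma	prior_sd_ma	evidence	active
A1	Aphidoidea_others	stem	244.5000	2.5000	fossil_stage	true
A2	Lethocerus_deyrollei	stem	200.3000	1.0000	fossil_stage	true
A3	Ledra_auditura	stem	130.7000	1.4000	fossil_dated	true
A4	Aphis_gossypii	stem	107.0000	6.0000	fossil_stage	true
A5	Nilaparvata_lugens	stem	51.2500	0.3100	fossil_dated	true
A6	Geisha_distinctissima	stem	61.0000	5.0000	fossil_stage	true
B	Epiophlebia_superstes	stem	203.1000	1.0000	fossil_stage	true
C	Derotettix_mendosensis	stem	98.7900	0.6200	fossil_dated	true
C-notapplied	Derotettix_mendosensis	stem	49.5120	0.0190	fossil_dated	false
D	Platypedia_putnami|Davispia_group	crown	57.6000	1.6000	fossil_stage	true
D-notapplied-1	Platypedia_putnami|Davispia_group	crown	35.1500	1.6500	fossil_dated	false
D-notapplied-2	Platypedia_putnami|Davispia_group	crown	35.1500	1.6500	fossil_dated	false
E	Cicadetta_group|Paracicadetta_group	crown	28.4650	5.4350	fossil_stage	true
E-methods	Cicadetta_group|Paracicadetta_group	crown	31.0000	2.9000	fossil_stage	false
F	Lyristes_plebejus	stem	30.4400	1.5200	fossil_dated	true
G1	Cryptotympana_facialis|Cryptotympana_atrata	crown	16.4500	0.4500	fossil_stage	true
G2	Hyalessa_maculaticollis	crown	16.4500	0.4500	fossil_stage	true
H	Meimuna_opalifera|Meimuna_kuroiwae	crown	6.4000	0.4000	fossil_dated	true
Q1-6	Mogannia_minuta|Mogannia_hebes|Cryptotympana_facialis|Platypleura_kaempferi|Graptopsaltria_nigrofuscata	crown	1.5500	0.1500	geological_event	true
Q7	Meimuna_opalifera	crown	0.0240	0.0024	geological_event	true
Q7-methods	Meimuna_opalifera	crown	0.2400	0.0000	geological_event	false
Q8-12	Meimuna_kuroiwae|Tanna_japonensis|Euterpnosia_chibensis	crown	1.5500	0.1500	geological_event	true
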