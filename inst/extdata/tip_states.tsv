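tip	state
Actornithophilus_sp1	1
Actornithophilus_sp2	1
Amyrsidea_minuta	0
Austromenopon_sp1	0
Austromenopon_sp2	1
Ciconiphilus_sp	0
Colpocephalum_griffoneae	0
Colpocephalum_sp1	0
Colpocephalum_sp2	0
Eomenopon_sp	0
Franciscoloa_sp1	0
Franciscoloa_sp2	0
Franciscoloa_sp3	0
Laemobothrion_sp1	0
Laemobothrion_sp2	0
Laemobothrion_sp3	0
Laemobothrion_tinnunculi	1
Menacanthus_cornutus	0
Myrsidea_sp1	1
Myrsidea_sp2	1
Osborniella_crotophagae	0
Piagetiella_sp	0
Plegadiphilus_sp	0
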