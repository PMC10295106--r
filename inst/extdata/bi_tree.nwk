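(((Laemobothrion_sp1,Laemobothrion_sp3),(Laemobothrion_sp2,Laemobothrion_tinnunculi)),((Plegadiphilus_sp,(Menacanthus_cornutus,Amyrsidea_minuta)),(((Myrsidea_sp1,Myrsidea_sp2),(Austromenopon_sp1,Austromenopon_sp2)),((Actornithophilus_sp1,Actornithophilus_sp2),(Ciconiphilus_sp,(Colpocephalum_sp1,(Colpocephalum_griffoneae,(Colpocephalum_sp2,(Eomenopon_sp,(Franciscoloa_sp1,(Franciscoloa_sp2,(Franciscoloa_sp3,(Osborniella_crotophagae,Piagetiella_sp)))))))))))));
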