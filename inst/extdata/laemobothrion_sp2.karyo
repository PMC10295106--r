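# Laemobothrion sp. 2 (ex black kite): typical single-chromosome mt genome,
# 14,626 bp, all 37 genes; differs from L. sp. 1 / L. sp. 3 in the location
# of seven genes (nad3, trnG, trnW, trnV, trnF, trnM, trnQ); 327-bp NCR
# between cob and nad1.
# NOTE: within-chromosome gene order is a synthetic reconstruction obtained
# from the L. sp. 1 fixture by relocating exactly those seven genes; it is
# not the published appendix order.
species: Laemobothrion_sp2
host: black kite
C1: cox1 L2 cox2 V H D rrnL M rrnS N -E S1 cob NCR:327 nad1 T W nad2 I G cox3 K F A atp8 atp6 Q S2 R nad4L nad4 Y nad5 L1 P nad3 C nad6 size=14626
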