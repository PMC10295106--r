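# Actornithophilus sp. 2 (ex masked lapwing): fragmented mt genome of six
# minichromosomes (1,698-4,361 bp); 35 of 37 genes identified (trnP and
# trnR not found). M1 (smallest) has 3 genes (E-nad4L-nad4, identical in
# content to Act. sp. 1 M1); M6 (largest) has 12 genes. Relative to
# Act. sp. 1: M2+M3 here correspond to the single M2 of Act. sp. 1 (one
# split/merger); trnQ, trnW, trnL1, nad5, trnD and trnL2 are translocated
# between minichromosomes; trnA, trnQ and trnW are inverted.
# NOTE: within-chromosome gene order is a synthetic reconstruction
# constrained by the published counts, censuses, cluster strings and
# rearrangement sets; it is not the published figure order.
species: Actornithophilus_sp2
host: masked lapwing
M1: E nad4L nad4 size=1698
M2: V K cob nad1 -Q
M3: nad6 H S2 rrnS nad5
M4: nad2 S1 F L1 L2
M5: Y atp8 atp6 N -W
M6: G I cox2 cox1 C cox3 -A nad3 M T rrnL D size=4361
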