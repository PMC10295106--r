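# Actornithophilus sp. 1 (ex pied oystercatcher): fragmented mt genome of
# five minichromosomes (2,005-6,112 bp); 35 of 37 genes identified (trnP and
# trnR not found). M1 (smallest) has 3 genes (E-nad4L-nad4, shared with
# Act. sp. 2); M5 (largest) has 15 genes. M2 carries four non-coding
# regions of 86-832 bp. Five derived gene clusters are shared with
# Act. sp. 2: V-K-cob-nad1, nad6-H-S2, nad2-S1-F, Y-atp8-atp6-N,
# G-I-cox2-cox1-C-cox3.
# NOTE: within-chromosome gene order is a synthetic reconstruction
# constrained by the published counts, censuses, cluster strings and
# rearrangement sets; it is not the published figure order.
species: Actornithophilus_sp1
host: pied oystercatcher
M1: E nad4L nad4 size=2005
M2: V K NCR:86 cob nad1 NCR:120 rrnS nad6 NCR:200 H S2 NCR:832
M3: nad2 S1 F nad5
M4: Y atp8 atp6 N D
M5: G I cox2 cox1 C cox3 A T M nad3 rrnL Q W L2 L1 size=6112
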