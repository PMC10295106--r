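# Austromenopon sp. 2 (ex sooty tern and crested tern): fragmented mt
# genome of two minichromosomes; M1 9,499 bp with 16 genes (NCRs: 50 bp
# between cox1 and atp6, 49 bp between nad2 and atp8), M2 4,943 bp with 21
# genes (NCRs: 141 bp between trnS1 and trnQ, 80 bp between trnQ and nad4L).
# Shares six derived gene clusters with Austromenopon sp. 1:
# cox2-cox1-atp6-atp8, nad2-nad5-I, nad3-Y, rrnL-rrnS-L1, nad4L-nad4-E,
# P-K-S1.
# NOTE: within-chromosome gene order is a synthetic reconstruction
# constrained by the published counts, censuses, NCR placements and
# shared-cluster strings; it is not the published figure order.
species: Austromenopon_sp2
host: sooty tern and crested tern
M1: cox2 cox1 NCR:50 atp6 atp8 NCR:49 nad2 nad5 I F nad3 Y W cob G nad1 A C size=9499
M2: rrnL rrnS L1 T P K S1 NCR:141 Q NCR:80 nad4L nad4 E M cox3 D nad6 H L2 R S2 V N size=4943
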