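# Laemobothrion sp. 1 (ex Eurasian coot): typical single-chromosome mt
# genome, 14,155 bp, all 37 genes; all genes transcribed in the same
# orientation except trnE; 111-bp NCR between trnD and rrnL. Same gene
# arrangement as Laemobothrion sp. 3.
# NOTE: within-chromosome gene order is a synthetic reconstruction
# constrained by the published statements (orientation of trnE, NCR
# placement, the seven genes relocated in L. sp. 2); it is not the
# published appendix order.
species: Laemobothrion_sp1
host: Eurasian coot
C1: cox1 L2 cox2 H D NCR:111 rrnL V rrnS N -E S1 cob Q nad1 T G nad2 I M W cox3 K A atp8 atp6 F nad3 S2 R nad4L nad4 Y nad5 L1 P C nad6 size=14155
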