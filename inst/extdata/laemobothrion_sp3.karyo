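# Laemobothrion sp. 3 (ex Australasian swamphen): typical single-chromosome
# mt genome, 14,308 bp, all 37 genes; same gene arrangement and orientations
# as Laemobothrion sp. 1, including the 111-bp NCR between trnD and rrnL.
# NOTE: synthetic reconstruction mirroring the L. sp. 1 fixture.
species: Laemobothrion_sp3
host: Australasian swamphen
C1: cox1 L2 cox2 H D NCR:111 rrnL V rrnS N -E S1 cob Q nad1 T G nad2 I M W cox3 K A atp8 atp6 F nad3 S2 R nad4L nad4 Y nad5 L1 P C nad6 size=14308
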