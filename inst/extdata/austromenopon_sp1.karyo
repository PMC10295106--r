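# Austromenopon sp. 1 (ex sooty shearwater): typical single-chromosome
# mt genome, 14,992 bp, all 37 genes; non-coding regions of 127 bp
# (between cox1 and atp6) and 327 bp (between trnM and trnD).
# NOTE: within-chromosome gene order is a synthetic reconstruction
# constrained by the published chromosome count, census, NCR placements and
# shared-cluster strings; it is not the published figure order.
species: Austromenopon_sp1
host: sooty shearwater
C1: cox2 cox1 NCR:127 atp6 atp8 T nad2 nad5 I Q nad3 Y G rrnL rrnS L1 V nad4L nad4 E S2 P K S1 H cob N nad1 cox3 R A L2 nad6 C M NCR:327 D F W size=14992
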