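# Myrsidea sp. 1 (ex satin bowerbird): fragmented mt genome of four
# minichromosomes (1,969-6,185 bp); 23 of 37 genes identified (13
# protein-coding, 2 rRNA, 8 tRNA; 14 tRNA genes not found).
# M1: rrnL only, with a 790-bp NCR (1,969 bp). M2: rrnS only, with a
# 2,494-bp NCR (3,194 bp). M3 (5,167 bp): 8 genes with a 27-bp NCR between
# nad3 and trnS1; shared whole with Myrsidea sp. 2
# (Y-nad5-L1-nad3-S1-cox2-cox1-cox3). M4 (6,185 bp): 13 genes with a 59-bp
# NCR between nad2 and trnM; carries the
# G-cob-Q-atp6-atp8-nad4L-nad4-nad6-nad1 cluster shared with Myr. sp. 2.
# NOTE: the order of genes not fixed by the cluster strings is a synthetic
# reconstruction; it is not the published figure order.
species: Myrsidea_sp1
host: satin bowerbird
M1: rrnL NCR:790 size=1969
M2: rrnS NCR:2494 size=3194
M3: Y nad5 L1 nad3 NCR:27 S1 cox2 cox1 cox3 size=5167
M4: G cob Q atp6 atp8 nad4L nad4 nad6 nad1 C nad2 NCR:59 M W size=6185
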