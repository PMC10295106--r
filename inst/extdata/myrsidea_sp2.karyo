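# Myrsidea sp. 2 (ex citrine warbler): fragmented mt genome of three
# minichromosomes, characterized in a prior study and packaged here only at
# the granularity restated for the comparison with Myrsidea sp. 1: the
# shared whole minichromosome Y-nad5-L1-nad3-S1-cox2-cox1-cox3, the shared
# G-cob-Q-atp6-atp8-nad4L-nad4-nad6-nad1 cluster, rrnL and rrnS on one
# minichromosome (unlike Myr. sp. 1), 13 protein-coding + 2 rRNA + 7 tRNA
# genes, with tRNA placements differing from Myr. sp. 1.
# NOTE: synthetic cluster-level reconstruction; not a published gene map.
species: Myrsidea_sp2
host: citrine warbler
A: Y nad5 L1 nad3 S1 cox2 cox1 cox3
B: G cob Q atp6 atp8 nad4L nad4 nad6 nad1 nad2 F
C: rrnL rrnS V
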