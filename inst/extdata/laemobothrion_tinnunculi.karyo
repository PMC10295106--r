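# Laemobothrion (Laemobothrion) tinnunculi (ex Australian hobby):
# fragmented mt genome of three minichromosomes, characterized in a prior
# study and packaged at the restated partition granularity: cob alone on one
# minichromosome; nad2, trnP, trnW and trnG on a second; all other 32 genes
# on the third.
# NOTE: the within-chromosome order of the 32-gene minichromosome is a
# synthetic reconstruction (its sister species L. sp. 2's order minus the
# genes on the two small minichromosomes); only the 1/4/32 partition is
# published.
species: Laemobothrion_tinnunculi
host: Australian hobby
T1: cob
T2: nad2 P W G
T3: cox1 L2 cox2 V H D rrnL M rrnS N -E S1 nad1 T I cox3 K F A atp8 atp6 Q S2 R nad4L nad4 Y nad5 L1 nad3 C nad6
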