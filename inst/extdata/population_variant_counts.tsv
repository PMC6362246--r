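# Published SNP class counts by sea-cucumber population (larval
# transcriptome study; "all contigs" universe): transitions,
# transversions and indels per population, plus the pooled row.
population	snps_per_kb	transitions	transversions	indels
russian	5.04	77164	41755	3874
chinese	6	117064	63519	5144
south_korean	5.85	101518	57111	5996
all	33.57	689365	455283	58932
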