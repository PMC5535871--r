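# Intron pairs of the ANRIL locus reported to contain reverse-complementary
# Alu repeat pairs (hg19 rmsk analysis at this locus), as published;
# written here with intron_i < intron_j.
intron_i	intron_j
1	14
1	12
1	11
6	11
7	11
1	6
6	7
5	7
1	5
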