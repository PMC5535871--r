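# Skipped-exon (SE) events at the CDKN2B-AS1 locus extracted from RefSeq
# (SUPPA generateEvents ioe-style identifiers), one event per line.
# Format: GENE;SE:chrom:e1end-e2start:e2end-e3start:strand
CDKN2B-AS1;SE:chr9:22029593-22032673:22032985-22046316:+
CDKN2B-AS1;SE:chr9:22049227-22056251:22056386-22077678:+
CDKN2B-AS1;SE:chr9:22049227-22056251:22056386-22112319:+
CDKN2B-AS1;SE:chr9:22049227-22097257:22097363-22112319:+
CDKN2B-AS1;SE:chr9:22049227-22056251:22056386-22120199:+
CDKN2B-AS1;SE:chr9:22049227-22120199:22120409-22120503:+
CDKN2B-AS1;SE:chr9:22056386-22058358:22059053-22061952:+
CDKN2B-AS1;SE:chr9:22056386-22061952:22062025-22063943:+
CDKN2B-AS1;SE:chr9:22056386-22063943:22064017-22077678:+
CDKN2B-AS1;SE:chr9:22064017-22065661:22065756-22066234:+
CDKN2B-AS1;SE:chr9:22064017-22066234:22066352-22077678:+
CDKN2B-AS1;SE:chr9:22112394-22113665:22113798-22118643:+
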