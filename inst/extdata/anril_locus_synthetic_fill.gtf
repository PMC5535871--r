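# 19-exon model of the long ANRIL (CDKN2B-AS1) transcript, chr9, + strand,
# hg19 coordinates, 1-based inclusive (GTF dialect).
# Boundary provenance (see the `anchor` attribute per record):
#   both  - both boundaries recovered exactly from published skipped-exon
#           event coordinates at this locus (exons 3, 7, 8, 9, 10, 11, 12,
#           14, 15, 16, 18)
#   start / end - only that boundary recovered (exon 2 end, exon 4 start,
#           exon 6 end, exon 13 start, exon 17 start, exon 19 start)
#   none  - SYNTHETIC placeholder boundaries, chosen to respect exon order
#           and the locus's published intron-length structure (exon 1,
#           exon 5); not measured values.
chr9	backsplice	exon	21994791	21995300	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "1"; anchor "none";
chr9	backsplice	exon	22029409	22029593	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "2"; anchor "end";
chr9	backsplice	exon	22032674	22032985	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "3"; anchor "both";
chr9	backsplice	exon	22046317	22046500	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "4"; anchor "start";
chr9	backsplice	exon	22047181	22047272	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "5"; anchor "none";
chr9	backsplice	exon	22049075	22049227	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "6"; anchor "end";
chr9	backsplice	exon	22056252	22056386	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "7"; anchor "both";
chr9	backsplice	exon	22058359	22059053	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "8"; anchor "both";
chr9	backsplice	exon	22061953	22062025	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "9"; anchor "both";
chr9	backsplice	exon	22063944	22064017	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "10"; anchor "both";
chr9	backsplice	exon	22065662	22065756	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "11"; anchor "both";
chr9	backsplice	exon	22066235	22066352	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "12"; anchor "both";
chr9	backsplice	exon	22077679	22077824	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "13"; anchor "start";
chr9	backsplice	exon	22097258	22097363	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "14"; anchor "both";
chr9	backsplice	exon	22112320	22112394	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "15"; anchor "both";
chr9	backsplice	exon	22113666	22113798	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "16"; anchor "both";
chr9	backsplice	exon	22118644	22118773	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "17"; anchor "start";
chr9	backsplice	exon	22120200	22120409	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "18"; anchor "both";
chr9	backsplice	exon	22120504	22121093	.	+	.	gene_id "CDKN2B-AS1"; transcript_id "CDKN2B-AS1.t1"; exon_id "19"; anchor "start";
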