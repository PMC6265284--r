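##gff-version 2
chrT	toy	transcript	1001	3000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.1"; biotype "coding";
chrT	toy	exon	1001	1800	.	+	.	gene_id "GENE1"; transcript_id "GENE1.1"; biotype "coding";
chrT	toy	exon	2201	3000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.1"; biotype "coding";
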