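##gff-version 2
chrT	toy	transcript	1001	3000	.	+	.	gene_id "GENE1"; transcript_id "TX_KNOWN"; class_code "=";
chrT	toy	exon	1001	1800	.	+	.	gene_id "GENE1"; transcript_id "TX_KNOWN"; class_code "=";
chrT	toy	exon	2201	3000	.	+	.	gene_id "GENE1"; transcript_id "TX_KNOWN"; class_code "=";
chrT	toy	transcript	2501	2900	.	-	.	gene_id "TX_LNC1"; transcript_id "TX_LNC1"; class_code "x";
chrT	toy	exon	2501	2900	.	-	.	gene_id "TX_LNC1"; transcript_id "TX_LNC1"; class_code "x";
chrT	toy	transcript	2951	3250	.	+	.	gene_id "TX_SENSE"; transcript_id "TX_SENSE"; class_code "u";
chrT	toy	exon	2951	3250	.	+	.	gene_id "TX_SENSE"; transcript_id "TX_SENSE"; class_code "u";
chrT	toy	transcript	5001	5100	.	+	.	gene_id "TX_SHORT"; transcript_id "TX_SHORT"; class_code "u";
chrT	toy	exon	5001	5100	.	+	.	gene_id "TX_SHORT"; transcript_id "TX_SHORT"; class_code "u";
chrT	toy	transcript	6001	6600	.	-	.	gene_id "TX_CODING"; transcript_id "TX_CODING"; class_code "u";
chrT	toy	exon	6001	6600	.	-	.	gene_id "TX_CODING"; transcript_id "TX_CODING"; class_code "u";
chrT	toy	transcript	8001	8400	.	+	.	gene_id "TX_LNC2"; transcript_id "TX_LNC2"; class_code "u";
chrT	toy	exon	8001	8400	.	+	.	gene_id "TX_LNC2"; transcript_id "TX_LNC2"; class_code "u";
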