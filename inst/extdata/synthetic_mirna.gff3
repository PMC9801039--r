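##gff-version 3
# Synthetic miRBase-style annotation used in examples and tests.
# Coordinates and identifiers are invented; the dialect (feature types,
# ID / Name / Derives_from attributes) follows miRBase genome GFF3.
chr17	.	miRNA_primary_transcript	100000	100084	.	+	.	ID=SMI0001;Name=syn-mir-1
chr17	.	miRNA	100010	100031	.	+	.	ID=SMIMAT0001;Name=syn-miR-1-5p;Derives_from=SMI0001
chr17	.	miRNA	100050	100071	.	+	.	ID=SMIMAT0002;Name=syn-miR-1-3p;Derives_from=SMI0001
chr17	.	miRNA_primary_transcript	105000	105090	.	-	.	ID=SMI0002;Name=syn-mir-2
chr17	.	miRNA	105010	105031	.	-	.	ID=SMIMAT0003;Name=syn-miR-2-5p;Derives_from=SMI0002
chr17	.	miRNA_primary_transcript	200000	200080	.	+	.	ID=SMI0003;Name=syn-mir-3
chr17	.	miRNA	200010	200031	.	+	.	ID=SMIMAT0004;Name=syn-miR-3-5p;Derives_from=SMI0003
chrX	.	miRNA_primary_transcript	50000	50090	.	+	.	ID=SMI0004;Name=syn-mir-4
chrX	.	miRNA	50010	50031	.	+	.	ID=SMIMAT0005;Name=syn-miR-4-3p;Derives_from=SMI0004
chrX	.	miRNA	50050	50071	.	+	.	ID=SMIMAT0006;Name=syn-miR-4-5p;Derives_from=SMI0004
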