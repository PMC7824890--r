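##gff-version 3
mm10_synth	isocat	gene	1	2457	.	-	.	ID=gene-mSirt1;Name=mSirt1
mm10_synth	isocat	mRNA	101	2357	.	-	.	ID=rna-mSirt1-v1;Parent=gene-mSirt1;Name=v1;reference=true
mm10_synth	isocat	exon	2184	2357	.	-	.	ID=rna-mSirt1-v1-exon1;Parent=rna-mSirt1-v1;Name=e1;novel=false
mm10_synth	isocat	exon	1976	2101	.	-	.	ID=rna-mSirt1-v1-exon2;Parent=rna-mSirt1-v1;Name=e2;novel=false
mm10_synth	isocat	exon	1700	1843	.	-	.	ID=rna-mSirt1-v1-exon3;Parent=rna-mSirt1-v1;Name=e3;novel=false
mm10_synth	isocat	exon	1454	1576	.	-	.	ID=rna-mSirt1-v1-exon4;Parent=rna-mSirt1-v1;Name=e4;novel=false
mm10_synth	isocat	exon	1169	1324	.	-	.	ID=rna-mSirt1-v1-exon5;Parent=rna-mSirt1-v1;Name=e5;novel=false
mm10_synth	isocat	exon	941	1081	.	-	.	ID=rna-mSirt1-v1-exon6;Parent=rna-mSirt1-v1;Name=e6;novel=false
mm10_synth	isocat	exon	651	800	.	-	.	ID=rna-mSirt1-v1-exon7;Parent=rna-mSirt1-v1;Name=e7;novel=false
mm10_synth	isocat	exon	439	567	.	-	.	ID=rna-mSirt1-v1-exon8;Parent=rna-mSirt1-v1;Name=e8;novel=false
mm10_synth	isocat	exon	101	289	.	-	.	ID=rna-mSirt1-v1-exon9;Parent=rna-mSirt1-v1;Name=e9;novel=false
mm10_synth	isocat	CDS	2184	2357	.	-	.	ID=rna-mSirt1-v1-cds1;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	1976	2101	.	-	.	ID=rna-mSirt1-v1-cds2;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	1700	1843	.	-	.	ID=rna-mSirt1-v1-cds3;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	1454	1576	.	-	.	ID=rna-mSirt1-v1-cds4;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	1169	1324	.	-	.	ID=rna-mSirt1-v1-cds5;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	941	1081	.	-	.	ID=rna-mSirt1-v1-cds6;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	651	800	.	-	.	ID=rna-mSirt1-v1-cds7;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	439	567	.	-	.	ID=rna-mSirt1-v1-cds8;Parent=rna-mSirt1-v1
mm10_synth	isocat	CDS	101	289	.	-	.	ID=rna-mSirt1-v1-cds9;Parent=rna-mSirt1-v1
mm10_synth	isocat	mRNA	101	2357	.	-	.	ID=rna-mSirt1-v2;Parent=gene-mSirt1;Name=v2
mm10_synth	isocat	exon	2184	2357	.	-	.	ID=rna-mSirt1-v2-exon1;Parent=rna-mSirt1-v2;Name=e1;novel=false
mm10_synth	isocat	exon	1700	1843	.	-	.	ID=rna-mSirt1-v2-exon2;Parent=rna-mSirt1-v2;Name=e3;novel=false
mm10_synth	isocat	exon	1454	1576	.	-	.	ID=rna-mSirt1-v2-exon3;Parent=rna-mSirt1-v2;Name=e4;novel=false
mm10_synth	isocat	exon	1169	1324	.	-	.	ID=rna-mSirt1-v2-exon4;Parent=rna-mSirt1-v2;Name=e5;novel=false
mm10_synth	isocat	exon	941	1081	.	-	.	ID=rna-mSirt1-v2-exon5;Parent=rna-mSirt1-v2;Name=e6;novel=false
mm10_synth	isocat	exon	651	800	.	-	.	ID=rna-mSirt1-v2-exon6;Parent=rna-mSirt1-v2;Name=e7;novel=false
mm10_synth	isocat	exon	439	567	.	-	.	ID=rna-mSirt1-v2-exon7;Parent=rna-mSirt1-v2;Name=e8;novel=false
mm10_synth	isocat	exon	101	289	.	-	.	ID=rna-mSirt1-v2-exon8;Parent=rna-mSirt1-v2;Name=e9;novel=false
mm10_synth	isocat	CDS	2184	2357	.	-	.	ID=rna-mSirt1-v2-cds1;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	1700	1843	.	-	.	ID=rna-mSirt1-v2-cds2;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	1454	1576	.	-	.	ID=rna-mSirt1-v2-cds3;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	1169	1324	.	-	.	ID=rna-mSirt1-v2-cds4;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	941	1081	.	-	.	ID=rna-mSirt1-v2-cds5;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	651	800	.	-	.	ID=rna-mSirt1-v2-cds6;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	439	567	.	-	.	ID=rna-mSirt1-v2-cds7;Parent=rna-mSirt1-v2
mm10_synth	isocat	CDS	101	289	.	-	.	ID=rna-mSirt1-v2-cds8;Parent=rna-mSirt1-v2
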