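##gff-version 3
hs10_synth	isocat	gene	1	2773	.	+	.	ID=gene-SIRT1;Name=SIRT1
hs10_synth	isocat	mRNA	101	2673	.	+	.	ID=rna-SIRT1-v1;Parent=gene-SIRT1;Name=v1;reference=true
hs10_synth	isocat	exon	101	280	.	+	.	ID=rna-SIRT1-v1-exon1;Parent=rna-SIRT1-v1;Name=e1;novel=false
hs10_synth	isocat	exon	534	668	.	+	.	ID=rna-SIRT1-v1-exon2;Parent=rna-SIRT1-v1;Name=e2;novel=false
hs10_synth	isocat	exon	809	958	.	+	.	ID=rna-SIRT1-v1-exon3;Parent=rna-SIRT1-v1;Name=e3;novel=false
hs10_synth	isocat	exon	1047	1166	.	+	.	ID=rna-SIRT1-v1-exon4;Parent=rna-SIRT1-v1;Name=e4;novel=false
hs10_synth	isocat	exon	1356	1520	.	+	.	ID=rna-SIRT1-v1-exon5;Parent=rna-SIRT1-v1;Name=e5;novel=false
hs10_synth	isocat	exon	1647	1790	.	+	.	ID=rna-SIRT1-v1-exon6;Parent=rna-SIRT1-v1;Name=e6;novel=false
hs10_synth	isocat	exon	1898	2053	.	+	.	ID=rna-SIRT1-v1-exon7;Parent=rna-SIRT1-v1;Name=e7;novel=false
hs10_synth	isocat	exon	2197	2328	.	+	.	ID=rna-SIRT1-v1-exon8;Parent=rna-SIRT1-v1;Name=e8;novel=false
hs10_synth	isocat	exon	2473	2673	.	+	.	ID=rna-SIRT1-v1-exon9;Parent=rna-SIRT1-v1;Name=e9;novel=false
hs10_synth	isocat	CDS	101	280	.	+	.	ID=rna-SIRT1-v1-cds1;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	534	668	.	+	.	ID=rna-SIRT1-v1-cds2;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	809	958	.	+	.	ID=rna-SIRT1-v1-cds3;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	1047	1166	.	+	.	ID=rna-SIRT1-v1-cds4;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	1356	1520	.	+	.	ID=rna-SIRT1-v1-cds5;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	1647	1790	.	+	.	ID=rna-SIRT1-v1-cds6;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	1898	2053	.	+	.	ID=rna-SIRT1-v1-cds7;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	2197	2328	.	+	.	ID=rna-SIRT1-v1-cds8;Parent=rna-SIRT1-v1
hs10_synth	isocat	CDS	2473	2673	.	+	.	ID=rna-SIRT1-v1-cds9;Parent=rna-SIRT1-v1
hs10_synth	isocat	mRNA	370	2673	.	+	.	ID=rna-SIRT1-v2;Parent=gene-SIRT1;Name=v2
hs10_synth	isocat	exon	370	429	.	+	.	ID=rna-SIRT1-v2-exon1;Parent=rna-SIRT1-v2;Name=ex1';novel=true
hs10_synth	isocat	exon	534	668	.	+	.	ID=rna-SIRT1-v2-exon2;Parent=rna-SIRT1-v2;Name=e2;novel=false
hs10_synth	isocat	exon	1047	1166	.	+	.	ID=rna-SIRT1-v2-exon3;Parent=rna-SIRT1-v2;Name=e4;novel=false
hs10_synth	isocat	exon	1356	1520	.	+	.	ID=rna-SIRT1-v2-exon4;Parent=rna-SIRT1-v2;Name=e5;novel=false
hs10_synth	isocat	exon	1647	1790	.	+	.	ID=rna-SIRT1-v2-exon5;Parent=rna-SIRT1-v2;Name=e6;novel=false
hs10_synth	isocat	exon	1898	2053	.	+	.	ID=rna-SIRT1-v2-exon6;Parent=rna-SIRT1-v2;Name=e7;novel=false
hs10_synth	isocat	exon	2197	2328	.	+	.	ID=rna-SIRT1-v2-exon7;Parent=rna-SIRT1-v2;Name=e8;novel=false
hs10_synth	isocat	exon	2473	2673	.	+	.	ID=rna-SIRT1-v2-exon8;Parent=rna-SIRT1-v2;Name=e9;novel=false
hs10_synth	isocat	CDS	370	429	.	+	.	ID=rna-SIRT1-v2-cds1;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	534	668	.	+	.	ID=rna-SIRT1-v2-cds2;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	1047	1166	.	+	.	ID=rna-SIRT1-v2-cds3;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	1356	1520	.	+	.	ID=rna-SIRT1-v2-cds4;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	1647	1790	.	+	.	ID=rna-SIRT1-v2-cds5;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	1898	2053	.	+	.	ID=rna-SIRT1-v2-cds6;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	2197	2328	.	+	.	ID=rna-SIRT1-v2-cds7;Parent=rna-SIRT1-v2
hs10_synth	isocat	CDS	2473	2673	.	+	.	ID=rna-SIRT1-v2-cds8;Parent=rna-SIRT1-v2
hs10_synth	isocat	mRNA	1047	2673	.	+	.	ID=rna-SIRT1-v3;Parent=gene-SIRT1;Name=v3
hs10_synth	isocat	exon	1047	1166	.	+	.	ID=rna-SIRT1-v3-exon1;Parent=rna-SIRT1-v3;Name=e4;novel=false
hs10_synth	isocat	exon	1230	1277	.	+	.	ID=rna-SIRT1-v3-exon2;Parent=rna-SIRT1-v3;Name=ex4';novel=true
hs10_synth	isocat	exon	1356	1520	.	+	.	ID=rna-SIRT1-v3-exon3;Parent=rna-SIRT1-v3;Name=e5;novel=false
hs10_synth	isocat	exon	1647	1790	.	+	.	ID=rna-SIRT1-v3-exon4;Parent=rna-SIRT1-v3;Name=e6;novel=false
hs10_synth	isocat	exon	1898	2053	.	+	.	ID=rna-SIRT1-v3-exon5;Parent=rna-SIRT1-v3;Name=e7;novel=false
hs10_synth	isocat	exon	2197	2328	.	+	.	ID=rna-SIRT1-v3-exon6;Parent=rna-SIRT1-v3;Name=e8;novel=false
hs10_synth	isocat	exon	2473	2673	.	+	.	ID=rna-SIRT1-v3-exon7;Parent=rna-SIRT1-v3;Name=e9;novel=false
hs10_synth	isocat	CDS	1047	1166	.	+	.	ID=rna-SIRT1-v3-cds1;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	1230	1277	.	+	.	ID=rna-SIRT1-v3-cds2;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	1356	1520	.	+	.	ID=rna-SIRT1-v3-cds3;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	1647	1790	.	+	.	ID=rna-SIRT1-v3-cds4;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	1898	2053	.	+	.	ID=rna-SIRT1-v3-cds5;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	2197	2328	.	+	.	ID=rna-SIRT1-v3-cds6;Parent=rna-SIRT1-v3
hs10_synth	isocat	CDS	2473	2673	.	+	.	ID=rna-SIRT1-v3-cds7;Parent=rna-SIRT1-v3
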