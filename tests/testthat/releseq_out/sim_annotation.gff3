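##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-22
chrSim	rtracklayer	CDS	1339	1608	.	-	0	ID=g0001;gene_id=g0001;operon_id=op001;operon_position=1
chrSim	rtracklayer	CDS	191	1318	.	-	0	ID=g0002;gene_id=g0002;operon_id=op001;operon_position=2
chrSim	rtracklayer	CDS	1809	2849	.	+	0	ID=g0003;gene_id=g0003;operon_id=op002;operon_position=1
chrSim	rtracklayer	CDS	2870	4021	.	+	0	ID=g0004;gene_id=g0004;operon_id=op002;operon_position=2
chrSim	rtracklayer	CDS	4042	5295	.	+	0	ID=g0005;gene_id=g0005;operon_id=op002;operon_position=3
chrSim	rtracklayer	CDS	5316	6377	.	+	0	ID=g0006;gene_id=g0006;operon_id=op002;operon_position=4
chrSim	rtracklayer	CDS	6398	7714	.	+	0	ID=g0007;gene_id=g0007;operon_id=op002;operon_position=5
chrSim	rtracklayer	CDS	11529	12749	.	-	0	ID=g0008;gene_id=g0008;operon_id=op003;operon_position=1
chrSim	rtracklayer	CDS	10489	11508	.	-	0	ID=g0009;gene_id=g0009;operon_id=op003;operon_position=2
chrSim	rtracklayer	CDS	9251	10468	.	-	0	ID=g0010;gene_id=g0010;operon_id=op003;operon_position=3
chrSim	rtracklayer	CDS	7995	9230	.	-	0	ID=g0011;gene_id=g0011;operon_id=op003;operon_position=4
chrSim	rtracklayer	CDS	14324	15433	.	-	0	ID=g0012;gene_id=g0012;operon_id=op004;operon_position=1
chrSim	rtracklayer	CDS	12990	14303	.	-	0	ID=g0013;gene_id=g0013;operon_id=op004;operon_position=2
chrSim	rtracklayer	CDS	15674	17002	.	-	0	ID=g0014;gene_id=g0014;
chrSim	rtracklayer	CDS	17243	18736	.	-	0	ID=g0015;gene_id=g0015;
chrSim	rtracklayer	CDS	18937	20037	.	+	0	ID=g0016;gene_id=g0016;
chrSim	rtracklayer	CDS	20318	21634	.	-	0	ID=g0017;gene_id=g0017;
chrSim	rtracklayer	CDS	21875	23251	.	-	0	ID=g0018;gene_id=g0018;
chrSim	rtracklayer	CDS	23452	24717	.	+	0	ID=g0019;gene_id=g0019;
chrSim	rtracklayer	CDS	24958	26055	.	+	0	ID=g0020;gene_id=g0020;
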