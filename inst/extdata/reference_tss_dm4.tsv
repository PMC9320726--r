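gene	strain	method	promoter	replicon	position	strand	utr_length	minus35_box	minus10_box	spacer	comment
dcmA	M. extorquens DM4	dRNA-seq	P_A	chromosome	2562877	+	173	TTGACA	TATAGA	16	this study
dcmA	M. extorquens DM4	nuclease S1	P_A	chromosome	NA	+	175	TTGACA	TATAGA	16	TSS identified from cloned DNA
dcmA	Methylophilus sp. DM11	primer extension	P_A	NA	NA	NA	122	TTGACA	TATAGT	17	different genus
dcmR	M. extorquens DM4	dRNA-seq	P_R1	chromosome	2562332	-	66	TTGCGC	TAACTA	17	this study
dcmR	M. extorquens DM4	nuclease S1	P_R1	chromosome	NA	-	62	TTGCGC	TAACTA	17	TSS identified from cloned DNA
dcmR	M. extorquens DM4	dRNA-seq	P_R2	chromosome	2562423	-	157	TTTACT	TTTACT	16	this study
dcmR	M. extorquens DM4	nuclease S1	P_R2	chromosome	NA	-	157	TTTACT	TTTACT	16	TSS identified from cloned DNA
glyA	M. extorquens DM4	dRNA-seq	NA	chromosome	3888433	-	75	TTGGCC	ACGAAT	18	this study
glyA	M. extorquens AM1	primer extension	NA	NA	NA	NA	84	ATCACC	TGCCGC	16	other TSSs with 63 and 38 nt 5'UTR
lspA	M. extorquens DM4	dRNA-seq	P_ileS	chromosome	3023525	+	150	TTCCCC	TAGAAG	17	150 nt upstream of ileS; no TSS upstream of lspA
lspA	M. extorquens AM1	primer extension	P_orf181	NA	NA	NA	129	TCGACG	GGTGCC	19	faint primer extension band; low promoter activity
mxaF	M. extorquens DM4	dRNA-seq	NA	chromosome	5068109	-	168	AAGACA	TAGAAA	18	this study
mxaF	M. extorquens AM1	nuclease S1	NA	NA	NA	NA	167	AAGACA	TAGAAA	18	run-off too; reported 167-168 nt
mxaF	M. organophilum XX	primer extension	NA	NA	NA	NA	170	AAGACA	TAGAAA	18	sequence variation downstream of -10 box
mxaW	M. extorquens DM4	dRNA-seq	NA	chromosome	5068271	+	41	TTGACC	ACCGTT	18	this study
mxaW	M. extorquens AM1	primer extension	NA	NA	NA	NA	52	TTGGCA	ACCCAT	NA	sequence not found in AM1 genome
mxaW	M. organophilum XX	primer extension	NA	NA	NA	NA	54	TTGACC	ACCACT	18	other strain
mtkA	M. extorquens DM4	dRNA-seq	NA	chromosome	2393413	+	31	TTCCCG	GAAGGT	17	this study
mtkA	M. extorquens AM1	primer extension	Pqsc2-1	NA	NA	NA	46	TTGAGA	AGTAAT	19	qsc2 operon; predominant on methanol
mtkA	M. extorquens AM1	primer extension	Pqsc2-2	NA	NA	NA	80	AAGTCA	AAGAAA	30	30-nt spacer in AM1 genome; atypical
pqqA	M. extorquens DM4	dRNA-seq	P_mxbM	chromosome	2416334	-	119	TGGCGC	TGATGG	19	upstream of adjacent gene mxbM; no TSS upstream of pqqA
pqqA	M. extorquens AM1	primer extension	P_pqqD	NA	NA	NA	95	TTGCAG	CGATAT	16	promoter checked with xylE fusion
sga	M. extorquens DM4	dRNA-seq	P_sga	chromosome	2388788	+	46	TTGCGC	CGGGAT	16	this study; second orphan-class TSS at 2388435
sga	M. extorquens AM1	primer extension	P_qsc1	NA	NA	NA	63	GTGCCC	CCGGCA	18	qsc1 operon; UTR cell partly ambiguous in source table
sga	M. extorquens AM1	primer extension	P_qsc1	NA	NA	NA	43	TTGAAT	CATCGA	17	second qsc1 TSS
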