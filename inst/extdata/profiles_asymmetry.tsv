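# Curated marker profiles: genes whose knock-down elicits ASE left/right
# asymmetry defects (bilateral ASE marker unaffected, or ambiguous with a
# clear contralateral swap). reported_phenotype carries the published class
# labels verbatim. See PROVENANCE for the aser_extra entries.
gene_id	functional_category	domain	asel	asel_extra	aser	aser_extra	ase_bilateral	ase_extra	neurons	muscle	gut	hypodermis	viable	pre200_arrest	reported_phenotype
klp-16	cell/organelle	Kinesin-like	+		wt		wt								Class IV (mixed)
F21H12.1	chromatin	Histone methyltransferase complex (WD40 domain)	+		+		wt						yes		Class II (2-ASER)
lin-49	chromatin	Histone acetylltransferase complex (bromodomain)	-		+		wt						yes		Class II (2-ASER)
ash-2	chromatin	Histone methyltransferase complex (SPRY domain)	+		+		wt								Class II (2-ASER)
dpy-30	chromatin	Histone methyltransferase complex	+		+		wt								Class II (2-ASER)
uri-1	chromosome	Prefoldin	+		-		ne								Class I (2-ASEL)
smk-1	chromosome	Regulatory subunit of the protein phosphatase 4	-		+/-	yes	+/-								Class II (2-ASER)
tac-1	chromosome	Microtubule-based processes (TACC protein family)	+		wt		wt								Class IV (mixed)
sams-3	metabolism	S-adenosylmethionine synthetase	+		-		wt						yes		Class IV (mixed)
sams-4	metabolism	S-adenosylmethionine synthetase	+		-		wt						yes		Class IV (mixed)
grp-1	signaling	Guanine nucleotide exchange factor	+		wt		wt						yes		Class IV (mixed)
smo-1	signaling	SUMO	-		+		wt								Class II (2-ASER)
C07A9.2	splicing	G10 splicing factor family (BUD31 ortholog)	+		wt		wt								Class IV (mixed)
rsp-7	splicing	SR protein family (RNA binding RRM domain)	-		+/-	yes	+/-								Class II (2-ASER)
ddx-23	splicing	U5 snRNP-like RNA helicase subunit (DEAD and helicase)	-		+		wt								Class II (2-ASER)
die-1	transcription	C2H2 Zn finger transcription factor	-		+		wt								Class II (2-ASER)
lsy-22	transcription	Groucho-like	+		-		+/-								Class I (2-ASEL)
lsy-2	transcription	C2H2 Zn finger transcription factor	-		+		wt						yes		Class II (2-ASER)
fozi-1	transcription	C2H2 Zn finger transcription factor	+		wt		wt								Class IV (mixed)
lim-6	transcription	LIM homeobox	-		+		wt						yes		Class II (2-ASER)
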