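# Curated marker profiles: genes whose knock-down elicits ASE cell/lineage
# defects (ectopic or lost ASEL/ASER cells without a complete loss of ASE
# fate). The *_extra columns are the ">2 cells" observations. See
# PROVENANCE for notes.
gene_id	functional_category	domain	asel	asel_extra	aser	aser_extra	ase_bilateral	ase_extra	neurons	muscle	gut	hypodermis	viable	pre200_arrest	reported_phenotype
lis-1	cell/organelle	WD40	-		wt		+/-								loss ASEL
lrg-1	chromosome	let-99 related (pseudogene)	+		+/-		+	yes							ectopic ASEL; also ectopic ASER lineage
par-3	blastomere	PDZ domain	+		+	yes	+	yes							ectopic ASEL; also ectopic ASER lineage
mei-2	blastomere	Microtubule regulator (similar to katanin)	+		-		+/-	yes							ectopic ASEL; also loss of ASER lineage
par-2	blastomere	RING finger	+	yes	-		ne								ectopic ASEL; also loss of ASER lineage
lit-1	blastomere	Serine/threonine kinase (Wnt signalling)	-		+	yes	+	yes							ectopic ASER
pie-1	blastomere	Zinc finger, CCCH-type	+	yes	-		+	yes							ectopic ASEL; also loss of ASER lineage
ced-3	signalling	Caspase	+	yes	+		+	yes					yes		ectopic ASEL; also ectopic ASER lineage
oac-35	signalling	Integral membrane O-acyltransferase	+	yes	-		ne								ectopic ASEL; also loss of ASER lineage
wwp-1	signalling	E3 ubiquitin ligase	+		+	yes	+/-	yes							ectopic ASEL; also ectopic ASER lineage
ref-1	transcription	bHLH	+		wt		+	yes					yes		ectopic ASEL
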