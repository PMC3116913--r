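# Curated marker profiles: genes whose knock-down elicits broad neuronal
# defects (ASEL and the dopaminergic/cholinergic panel lost, muscle intact).
# Cell tokens as printed: + intact/ectopic, - lost, +/- mixed, wt wildtype,
# ne not embryonic lethal, blank = not done. See PROVENANCE for notes.
gene_id	functional_category	domain	asel	asel_extra	aser	aser_extra	ase_bilateral	ase_extra	neurons	muscle	gut	hypodermis	viable	pre200_arrest	reported_phenotype
tbg-1	cell/organelle	Tubulin	-						-	+		-			broad neuronal
his-42	chromosome	Histone H3	-						-	+	+	-			broad neuronal
zyg-9	chromosome	Microtubule-associated protein	-						-	+	+	-			broad neuronal
R04F11.3	chromosome	DNA polymerase subunit Cdc27	-						-	+	+	ne			broad neuronal
R53.6	chromosome	DNA replication (GINS complex subunit)	-						-	+	+	-			broad neuronal
his-3	chromosome	Histone H2A	-						-	+	+	-			broad neuronal
csc-1	chromosome	Subunit of the Aurora B kinase complex	-		-		-		-	+	+	-			broad neuronal
his-13	chromosome	Histone H3	-						-	+	+	-			broad neuronal
his-4	chromosome	Histone 2B	-						-	+	-	-			broad neuronal
pole-2	chromosome	DNA polymerase epsilon, subunit B	-						-	+	-	-			broad neuronal
ran-3	chromosome	Spindle formation (RCC repeat)	-						-	+	-	-			broad neuronal
gpr-1	blastomere	G protein regulator (GoLoco motif)	-						-	+	+	-			broad neuronal
mex-3	blastomere	RNA binding KH domain	-		-		ne		-	+	+	-			broad neuronal
mex-5	blastomere	RNA binding CCCH domain	-						-	+	+	-			broad neuronal
gpr-2	blastomere	G protein regulator (GoLoco motif)	-						-	+	-	-			broad neuronal
T01H3.4	novel	Transmembrane domains	-						-	+	+	-			broad neuronal
C30B5.4	RNA reg.	RNA binding RRM domain	-						-	+	-	-			broad neuronal
T09A5.9	signalling	Regulatory subunit protein phosphatase 1	-						-	+	+	-			broad neuronal
F19F10.9	splicing	SART-1 family (U4/U6.U5 snRNP associated protein)	-						-	+	+	-			broad neuronal
M03C11.7	splicing	Pre-mRNA processing factor 3	-						-	+		-			broad neuronal
D1054.14	splicing	PRP38-like splicing factor	-						-	+	-	-			broad neuronal
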