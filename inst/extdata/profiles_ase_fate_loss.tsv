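# Curated marker profiles: genes whose knock-down elicits a bilateral loss
# of ASE cell fate (ASEL and ASER fate markers lost; dopaminergic and
# cholinergic neuron markers unaffected). See PROVENANCE for notes.
gene_id	functional_category	domain	asel	asel_extra	aser	aser_extra	ase_bilateral	ase_extra	neurons	muscle	gut	hypodermis	viable	pre200_arrest	reported_phenotype
hda-1	chromatin	Histone deacetylase	-		-		-		+	-	+	-			loss of ASE fate
cdk-7	chromosome	Cyclin-dependent Kinase	-		-		-		+	+	-	-			loss of ASE fate
cdk-9	chromosome	Cyclin-dependent Kinase	-		-		-		+	+	+	-			loss of ASE fate
csnk-1	chromosome	Casein Kinase	-		-		-		ne	+	ne	+			loss of ASE fate
F09D1.1	chromosome	Ubiquitin hydrolase	-		-		-		+	-	+	-			loss of ASE fate
him-10	chromosome	Nuf2 kinetochore homolog	-		-		+/-		+	-	+	-			loss of ASE fate
rfc-1	chromosome	Replication factor C	-		-		ne			-	+	-			loss of ASE fate
rpb-8	chromosome	RNA polymerase subunit 8	-		-		-		+	+	-	-			loss of ASE fate
spdl-1	chromosome	Coiled coil protein required for chrom segregation	-		-		ne		+	+	+	+			loss of ASE fate
sur-6	chromosome	Protein phosphatase 2A, regulatory subunit	-		-		+/-		+	-	+	-			loss of ASE fate
aph-1	blastomere	Transmembrane protein req. for Notch signaling	-		-		ne		+	+	+	+			loss of ASE fate
par-6	blastomere	PDZ domain	-		-		+/-		+	+	-	-			loss of ASE fate
glp-1	blastomere	Notch	-		-		-		+	+	+	-			loss of ASE fate
pfd-6	metabolism	Prefoldin	-		-		+/-			-	+	-			loss of ASE fate
rnf-113	metabolism	Hydrolase (HAD) and RING finger	-		-		-		+	+	+	-			loss of ASE fate
mel-32	metabolism	Serine hydroxymethyltransferase (Ser->Gly)	-		-		wt		-	+	-	+			loss of ASE fate
ccdc-55	novel	Conserved coiled-coil	-		-		-		+	+	+	-			loss of ASE fate
F37C12.1	novel	Conserved coiled-coil	-		-		-		+	+	-	-			loss of ASE fate
mog-4	RNA reg.	DEAH helicase	-		-		ne		+	+	+	-			loss of ASE fate
mog-5	RNA reg.	DEAH helicase	-		-		-		ne	+	-	-			loss of ASE fate
rnp-6	RNA reg.	RNA-binding RRM domain	-		-		+/-		+	+	+	-			loss of ASE fate
mag-1	RNA reg.	MAGonashi homolog	-		-		wt		+	+	+	-			loss of ASE fate
D1043.1	splicing	INTS7 homolog; Integrator complex component	-		+/-		+/-		+	-	-	-			loss of ASE fate
F23F1.5	splicing	Snurportin	-		-		+/-		+	+	+	+			loss of ASE fate
K07C5.6	splicing	Pre-mRNA splicing Prp180-interacting	-		-		-		+	+	-	-			loss of ASE fate
nxt-1	splicing	RNA export factor	-		-		ne		+						loss of ASE fate
ZC376.6	splicing	Integrator subunit	-		-		+/-		+	+	+	-			loss of ASE fate
Y65B4A.6	splicing	Tsl. Initiation factor (DEAD/DEAH helicase)	-		-		wt		+						loss of ASE fate
che-1	transcription	ZF - C2H2 - 4	-		-		-		+	+	+	+	yes		loss of ASE fate
F28B3.1	transcription	Disco (C2H2) -interacting protein AMP-binding	-		-		ne		ne	+	-	-			loss of ASE fate
hlh-14	transcription	bHLH	-		-		-		+		+	+	yes		loss of ASE fate
let-49	transcription	Mediator complex	-		-		ne								loss of ASE fate
mdt-17	transcription	Mediator complex	-		wt		-		+						loss of ASE fate
pqn-38	transcription	Mediator complex	-		-		-		+	+	+	-			loss of ASE fate
sel-8	transcription	Mastermind homolog in Notch signaling	-		-		-		+	+	+	-			loss of ASE fate
skn-1	transcription	bZIP	-		-		-		+	+		ne			loss of ASE fate
sknr-1	transcription	bZIP	-		-		-		+	+	+	-			loss of ASE fate
F54D5.11	transcription	TFIIE beta subunit	-		-		-		+	+	-	-			loss of ASE fate
taf-1	transcription	TBP-associated factor (bromodomain)	-		-		-		ne	+	+	-			loss of ASE fate
taf-5	transcription	TBP-associated factor (WD40 domain)	-		-		-		+	+	+	-			loss of ASE fate
tlf-1	transcription	TATA binding TFIID	-		-		+/-		+	-	-	-			loss of ASE fate
let-526	transcription	ARID/BRIGHT	-		-		wt		+	+	+	+			loss of ASE fate
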