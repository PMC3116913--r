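# Canonical marker archetypes per phenotypic class: the phenotype each
# assay shows for a fully penetrant clone of that class. primary/aser:
# LOSS, ECTOPIC or NONE; ase (bilateral reporter): OFF, ECTOPIC or NONE;
# tissue markers: LOST or INTACT. The asymmetry archetype is the 2-ASER
# class (ASEL lost, ectopic ASER, bilateral marker unaffected).
top_class	primary	aser	ase	neurons	muscle	gut	hypodermis
WT	NONE	NONE	NONE	INTACT	INTACT	INTACT	INTACT
EARLY_ARREST	LOSS	LOSS	OFF	LOST	LOST	LOST	LOST
BROAD_NEURONAL	LOSS	LOSS	OFF	LOST	INTACT	INTACT	LOST
ASE_FATE_LOSS	LOSS	LOSS	OFF	INTACT	INTACT	INTACT	INTACT
ASE_LINEAGE	ECTOPIC	NONE	ECTOPIC	INTACT	INTACT	INTACT	INTACT
ASYMMETRY	LOSS	ECTOPIC	NONE	INTACT	INTACT	INTACT	INTACT
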