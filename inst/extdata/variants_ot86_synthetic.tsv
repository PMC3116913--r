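# SYNTHETIC whole-genome-sequencing variant table demonstrating the mutant
# cloning candidate filter (not real sequencing data; see PROVENANCE).
# Mapping interval used in the demonstration: II:3000000-18000000.
chromosome	position	ref	alt	quality	multiplicity	depth	consequence	annotation
II	5000000	C	T	2	1	10	protein_coding_change	fails quality threshold
II	5100000	G	A	5	3	10	protein_coding_change	fails multiplicity threshold
II	5200000	A	T	5	1	2	protein_coding_change	fails depth threshold
I	5300000	C	A	5	1	10	protein_coding_change	wrong chromosome
II	2000000	C	A	5	1	10	protein_coding_change	left of mapping interval
II	19000000	G	T	5	1	10	protein_coding_change	right of mapping interval
II	5400000	C	T	9	1	12	protein_coding_change	present in background genomes
II	5500000	G	A	8	1	15	non_coding	non-coding, in interval
II	5600000	T	C	7	1	9	non_coding	non-coding, in interval
II	12000000	T	A	3	1	3	other	in interval, not a coding change
II	6200000	G	A	12	1	11	protein_coding_change	candidate missense
II	8123456	C	T	25	1	18	protein_coding_change	premature stop in rbbp-5 locus
II	9900000	A	G	14	1	13	protein_coding_change	candidate missense
II	15000000	C	G	10	1	9	protein_coding_change	candidate missense
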