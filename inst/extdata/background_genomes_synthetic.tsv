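# SYNTHETIC background variant set: variants also observed in other
# sequenced genomes of different genotypes; candidates matching any record
# here are considered strain background and eliminated (see PROVENANCE).
chromosome	position	ref	alt	quality	multiplicity	depth	consequence	annotation
II	5400000	C	T	11	1	20	protein_coding_change	shared strain background
III	7700000	A	G	9	1	14	non_coding	shared strain background
X	1234567	G	C	6	1	8	protein_coding_change	shared strain background
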