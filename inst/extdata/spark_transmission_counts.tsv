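parent	offspring_role	allele_range	count	n_offspring	n_carrier_families
mother	male_proband	premutation	15	99	58
mother	male_sibling	premutation	4	99	58
mother	female_proband	premutation	3	99	58
mother	female_sibling	premutation	4	99	58
father	male_proband	premutation	0	99	58
father	male_sibling	premutation	0	99	58
father	female_proband	premutation	3	99	58
father	female_sibling	premutation	5	99	58
mother	male_proband	normal	11	99	58
mother	male_sibling	normal	6	99	58
mother	female_proband	normal	2	99	58
mother	female_sibling	normal	7	99	58
father	male_proband	normal	0	99	58
father	male_sibling	normal	0	99	58
father	female_proband	normal	0	99	58
father	female_sibling	normal	0	99	58
NA	male_proband	de_novo	1	99	58
NA	male_sibling	de_novo	0	99	58
NA	female_proband	de_novo	1	99	58
NA	female_sibling	de_novo	1	99	58
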