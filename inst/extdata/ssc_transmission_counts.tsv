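parent	offspring_role	allele_range	count	n_offspring	n_carrier_families
mother	male_proband	premutation	10	141	79
mother	male_sibling	premutation	7	141	79
mother	female_proband	premutation	3	141	79
mother	female_sibling	premutation	6	141	79
father	male_proband	premutation	0	141	79
father	male_sibling	premutation	0	141	79
father	female_proband	premutation	2	141	79
father	female_sibling	premutation	4	141	79
mother	male_proband	normal	19	141	79
mother	male_sibling	normal	14	141	79
mother	female_proband	normal	2	141	79
mother	female_sibling	normal	7	141	79
father	male_proband	normal	0	141	79
father	male_sibling	normal	0	141	79
father	female_proband	normal	0	141	79
father	female_sibling	normal	0	141	79
NA	male_proband	de_novo	3	141	79
NA	male_sibling	de_novo	1	141	79
NA	female_proband	de_novo	0	141	79
NA	female_sibling	de_novo	1	141	79
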