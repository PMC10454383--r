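role	processed	genotyped	carriers
father	3075	3067	19
mother	3078	3077	22
male_proband	2509	2497	16
male_sibling	1133	1127	4
female_proband	614	614	7
female_sibling	1136	1136	10
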