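role	processed	genotyped	carriers
father	2364	2362	22
mother	2369	2365	42
male_proband	2060	2055	13
male_sibling	906	905	8
female_proband	321	321	6
female_sibling	1011	1008	11
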