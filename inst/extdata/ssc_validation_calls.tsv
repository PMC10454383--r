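sample_id	family_id	role	sex	pcr	eh_offtarget	eh_region_only
SSC02135	11372	father	male	Y/23	Y/23	Y/23
SSC02130	11372	mother	female	29/48	29/70	29/70
SSC02128	11372	male_proband	male	Y/48	Y/46	Y/46
SSC02136	11372	male_sibling	male	Y/48	Y/57	Y/51
SSC02349	11676	father	male	Y/27	Y/281	Y/27
SSC02338	11676	mother	female	29/30	29/30	29/30
SSC02330	11676	female_proband	female	27/30	27/30	27/30
SSC02350	11676	female_sibling	female	27/29	27/29	27/29
SSC07297	13390	father	male	Y/30	Y/30	Y/30
SSC07289	13390	mother	female	30/33	30/33	30/33
SSC07282	13390	male_proband	male	Y/33	Y/157	Y/71
SSC07298	13390	female_sibling	female	30/30	30/30	30/30
SSC12025	14489	father	male	Y/30	Y/30	Y/30
SSC12020	14489	mother	female	39/46	39/92	38/68
SSC12016	14489	male_proband	male	Y/39	Y/128	Y/71
SSC12026	14489	male_sibling	male	Y/39	Y/168	Y/72
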