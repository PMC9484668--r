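population	sex	sample_size	n_variants	n_nonsynonymous	n_lof	n_pathogenic_k2	most_common_variant	most_common_af_pct
ALL	ALL	141456	75	68	7	32	rs17151919	0.84
afr	ALL	12487	13	12	1	4	rs17151919	8.41
asj	ALL	5185	1	1	0	0	rs17151919	0.26
eas	ALL	9977	14	13	1	6	rs148407750	0.31
fin	ALL	12562	3	3	0	0	rs751272426	0.04
nfe	ALL	64603	41	37	4	16	rs17151919	0.04
amr	ALL	17720	14	14	0	5	rs17151919	0.45
oth	ALL	3614	8	8	0	5	rs17151919	0.38
sas	ALL	15308	16	14	2	3	rs17151919	0.03
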