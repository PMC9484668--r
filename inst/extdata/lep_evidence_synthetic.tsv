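variant_id	clinical_case	functional_evidence	references
rs28954113	true	true	PMID:9537324; PMID:19657113
rs724159998	true	false	PMID:25678777
rs1307773933	true	true	PMID:9202122
rs747703977	true	true	PMID:20223363
rs1800564	true	false	PMID:18347007
rs17151919	false	true	PMID:15504928
lit_only_01	true	false	PMID:30000001
lit_only_02	true	false	PMID:30000002
lit_only_03	true	false	PMID:30000003
lit_only_04	true	false	PMID:30000004
lit_only_05	true	false	PMID:30000005
lit_only_06	true	false	PMID:30000006
lit_only_07	true	false	PMID:30000007
lit_only_08	true	false	PMID:30000008
lit_only_09	true	false	PMID:30000009
lit_only_10	true	false	PMID:30000010
lit_only_11	true	false	PMID:30000011
lit_only_12	true	false	PMID:30000012
lit_only_13	true	false	PMID:30000013
lit_only_14	true	false	PMID:30000014
lit_only_15	true	false	PMID:30000015
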