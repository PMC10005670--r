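variant_id	maf_responders	maf_nonresponders	odds_ratio	ci_low	ci_high	score
rs115675705	0.01	0.02	0.73	0.10	5.22	1
rs117788606	0.01	0.01	0.74	0.05	11.9	1
rs11983997	0.18	0.23	0.73	0.41	1.32	1
rs80189144	0.12	0.14	0.84	0.42	1.68	1
rs799157	0.03	0.05	0.59	0.18	2.00	1
rs117860853	0.01	0.03	0.48	0.08	2.91	1
rs142084074	0.01	0.01	0.74	0.05	11.9	1
rs144018203	0.01	0.01	0.73	0.04	11.7	1
rs112803755	0.01	0.02	0.74	0.10	5.31	1
rs55707100	0.06	0.03	1.71	0.51	5.68	-1
rs148931404	0.01	0.01	1.46	0.13	16.3	-1
rs147438979	0.02	0.01	2.96	0.33	26.9	-1
rs77542162	0.00	0.01	NA	NA	NA	NA
rs141844019	0.01	0.01	1.49	0.13	16.6	-1
rs112952132	0.01	0.01	0.73	0.04	11.7	1
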