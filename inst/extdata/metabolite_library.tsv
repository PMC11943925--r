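metabolite	ppm	rel_intensity	baseline_log_mean	baseline_log_sd	affected
isovalerate	0.85	2	0.3	0.12	FALSE
2-hydroxybutyrate	0.90	3	0.4	0.12	FALSE
2-oxoisocaproate	0.95	2	0.2	0.12	FALSE
dihydrothymine	1.13	3	0.2	0.12	FALSE
ethanol	1.19	3	0.5	0.12	FALSE
lactate	1.33	3	1.5	0.12	TRUE
alanine	1.48	3	1	0.12	TRUE
2-hydroxybutyrate	1.70	1	0.4	0.12	FALSE
acetate	1.92	3	1.2	0.12	TRUE
isovalerate	2.05	1	0.3	0.12	FALSE
2-oxoisocaproate	2.10	1	0.2	0.12	FALSE
methionine sulfoxide	2.16	1	0.3	0.12	FALSE
succinate	2.41	4	1	0.12	TRUE
dihydrothymine	2.48	1	0.2	0.12	FALSE
citrate	2.54	2	1.8	0.12	TRUE
methylamine	2.60	3	0.2	0.12	FALSE
citrate	2.66	2	1.8	0.12	TRUE
dimethylamine	2.72	6	1	0.12	FALSE
methionine sulfoxide	2.77	2	0.3	0.12	FALSE
trimethylamine	2.88	9	0.4	0.12	FALSE
dimethylglycine	2.93	6	0.5	0.12	FALSE
creatine phosphate	3.00	3	0.6	0.12	FALSE
creatinine	3.05	3	2.5	0.12	FALSE
cis-aconitate	3.11	2	0.4	0.12	FALSE
choline	3.16	9	0.5	0.12	FALSE
trimethylamine N-oxide	3.21	9	1.3	0.12	FALSE
taurine	3.27	2	1.6	0.12	TRUE
1-methyluric acid	3.32	3	0.5	0.12	FALSE
phosphoryl choline	3.38	9	0.3	0.12	FALSE
taurine	3.43	2	1.6	0.12	TRUE
glycolate	3.49	2	0.4	0.12	FALSE
glycine	3.56	2	1.1	0.12	FALSE
n-phenylacetylglycine	3.62	2	0.8	0.12	FALSE
ethanol	3.68	2	0.5	0.12	FALSE
dimethylglycine	3.74	2	0.5	0.12	FALSE
alanine	3.80	1	1	0.12	TRUE
6-anhydro-beta-d-glucose	3.86	1	0.3	0.12	FALSE
creatine phosphate	3.91	2	0.6	0.12	FALSE
hippurate	3.97	2	1.4	0.12	TRUE
creatinine	4.06	2	2.5	0.12	FALSE
lactate	4.12	1	1.5	0.12	TRUE
6-anhydro-beta-d-glucose	4.35	1	0.3	0.12	FALSE
trigonelline	4.43	3	0.7	0.12	TRUE
n-methylnicotinamide	4.48	3	0.5	0.12	FALSE
allantoin	5.37	1	1	0.12	FALSE
n-phenylacetylglycine	7.36	3	0.8	0.12	FALSE
n-phenylacetylglycine	7.42	2	0.8	0.12	FALSE
hippurate	7.55	2	1.4	0.12	TRUE
hippurate	7.64	1	1.4	0.12	TRUE
hippurate	7.84	2	1.4	0.12	TRUE
trigonelline	8.07	1	0.7	0.12	TRUE
n-methylnicotinamide	8.18	1	0.5	0.12	FALSE
formate	8.46	1	0.4	0.12	FALSE
trigonelline	8.83	2	0.7	0.12	TRUE
n-methylnicotinamide	8.90	1	0.5	0.12	FALSE
trigonelline	9.11	1	0.7	0.12	TRUE
n-methylnicotinamide	9.26	1	0.5	0.12	FALSE
unassigned 22	0.52	1	0	0.12	FALSE
unassigned 03	0.57	1	0	0.12	FALSE
unassigned 05	0.62	1	0	0.12	FALSE
unassigned 01	0.67	1	0	0.12	FALSE
unassigned 19	0.72	1	0	0.12	FALSE
unassigned 43	1.02	1	0	0.12	FALSE
unassigned 02	1.27	1	0	0.12	FALSE
unassigned 52	1.62	1	0	0.12	FALSE
unassigned 48	1.82	1	0	0.12	FALSE
unassigned 26	1.87	1	0	0.12	FALSE
unassigned 17	1.97	1	0	0.12	FALSE
unassigned 44	2.22	1	0	0.12	FALSE
unassigned 53	2.27	1	0	0.12	FALSE
unassigned 16	2.32	1	0	0.12	FALSE
unassigned 30	2.82	1	0	0.12	FALSE
unassigned 27	4.17	1	0	0.12	FALSE
unassigned 13	4.22	1	0	0.12	FALSE
unassigned 28	4.27	1	0	0.12	FALSE
unassigned 51	5.07	1	0	0.12	FALSE
unassigned 24	5.17	1	0	0.12	FALSE
unassigned 23	5.22	1	0	0.12	FALSE
unassigned 36	5.27	1	0	0.12	FALSE
unassigned 21	5.32	1	0	0.12	FALSE
unassigned 38	6.27	1	0	0.12	FALSE
unassigned 29	6.32	1	0	0.12	FALSE
unassigned 49	6.37	1	0	0.12	FALSE
unassigned 45	6.42	1	0	0.12	FALSE
unassigned 56	6.52	1	0	0.12	FALSE
unassigned 15	6.57	1	0	0.12	FALSE
unassigned 42	6.67	1	0	0.12	FALSE
unassigned 08	6.77	1	0	0.12	FALSE
unassigned 32	6.82	1	0	0.12	FALSE
unassigned 55	6.87	1	0	0.12	FALSE
unassigned 09	6.92	1	0	0.12	FALSE
unassigned 41	6.97	1	0	0.12	FALSE
unassigned 20	7.02	1	0	0.12	FALSE
unassigned 07	7.07	1	0	0.12	FALSE
unassigned 10	7.12	1	0	0.12	FALSE
unassigned 25	7.27	1	0	0.12	FALSE
unassigned 37	7.47	1	0	0.12	FALSE
unassigned 31	7.72	1	0	0.12	FALSE
unassigned 39	7.77	1	0	0.12	FALSE
unassigned 50	8.02	1	0	0.12	FALSE
unassigned 18	8.12	1	0	0.12	FALSE
unassigned 46	8.27	1	0	0.12	FALSE
unassigned 14	8.32	1	0	0.12	FALSE
unassigned 04	8.37	1	0	0.12	FALSE
unassigned 12	8.52	1	0	0.12	FALSE
unassigned 40	8.57	1	0	0.12	FALSE
unassigned 54	8.67	1	0	0.12	FALSE
unassigned 35	8.72	1	0	0.12	FALSE
unassigned 47	8.77	1	0	0.12	FALSE
unassigned 34	8.97	1	0	0.12	FALSE
unassigned 33	9.02	1	0	0.12	FALSE
unassigned 11	9.17	1	0	0.12	FALSE
unassigned 57	9.37	1	0	0.12	FALSE
unassigned 06	9.42	1	0	0.12	FALSE
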