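pdb	states	class	lro	rco	aco	mrsd	rmsd	d_nx	d_nx_per_n_printed	d_total_e3_printed	d_total_per_n_printed	n
1A6N	3	alpha	1.4	0.1	14.0	26.2	29.2	285	1.9	4.24	28.1	151
1APS	2	mixed	4.2	0.2	21.8	22.7	25.4	201	2.1	2.43	24.8	98
1BDD	2	alpha	0.9	0.1	5.2	14.0	14.9	76.5	1.3	0.91	15.2	60
1BNI	3	mixed	2.5	0.1	12.3	20.8	22.8	209	1.9	2.46	22.8	108
1CBI	3	beta	2.8	0.1	18.8	25.1	27.9	286	2.1	3.70	27.2	136
1CEI	3	alpha	1.0	0.1	9.1	16.7	18.9	71.4	0.8	1.49	17.5	85
1CIS	2	mixed	3.3	0.2	10.8	15.1	16.8	99.7	1.5	1.10	16.6	66
1CSP	2	beta	3.0	0.2	11.0	16.8	18.4	98.0	1.5	1.23	18.3	67
1EAL	3	beta	2.5	0.1	15.7	24.9	27.9	278	2.2	3.44	27.1	127
1ENH	2	alpha	0.4	0.1	7.4	13.5	14.9	28.0	0.5	0.76	14.1	54
1G6P	2	beta	3.8	0.2	11.7	16.4	18.0	83.1	1.3	1.17	17.7	66
1GXT	3	mixed	3.7	0.2	18.6	21.1	23.5	148	1.7	2.03	22.8	89
1HRC	2	alpha	2.2	0.1	11.7	19.6	22.2	126	1.2	2.17	20.8	104
1IFC	3	beta	2.8	0.1	17.7	25.1	27.9	284	2.2	3.58	27.3	131
1IMQ	2	alpha	1.7	0.1	10.4	16.1	17.9	80.7	0.9	1.46	17.0	86
1LMB	2	alpha	1.1	0.1	7.1	17.0	18.6	76.8	0.9	1.55	17.9	87
1MJC	2	beta	3.0	0.2	11.0	17.5	19.2	110	1.6	1.32	19.1	69
1NYF	2	beta	2.8	0.2	10.6	15.3	17.0	87.4	1.5	0.97	16.8	58
1PBA	2	mixed	2.6	0.1	12.0	18.9	20.8	156	1.9	1.69	20.8	81
1PGB	2	mixed	2.1	0.2	9.7	14.1	15.7	25.4	0.5	0.81	14.5	56
1PKS	2	beta	3.8	0.2	15.2	17.9	20.2	136	1.8	1.50	19.7	76
1PSF	3	beta	2.8	0.2	11.7	16.8	19.4	72.1	1.0	1.23	17.8	69
1RA9	3	mixed	3.4	0.1	22.3	25.5	28.6	402	2.5	4.46	28.1	159
1RIS	2	mixed	3.0	0.2	18.4	21.5	23.9	163	1.7	2.25	23.2	97
1SHG	2	beta	3.0	0.2	10.9	15.1	16.7	92.3	1.6	0.95	16.7	57
1SRL	2	beta	3.1	0.2	11.0	14.8	16.3	94.5	1.7	0.92	16.5	56
1TIT	3	beta	4.1	0.2	15.8	18.7	20.8	154	1.7	1.82	20.4	89
1UBQ	2	mixed	2.4	0.2	11.5	17.0	18.9	92.1	1.2	1.39	18.2	76
1VII	2	alpha	0.4	0.1	4.0	8.1	9.2	4.1	0.1	0.30	8.2	36
1WIT	2	beta	5.0	0.2	18.9	20.4	22.7	168	1.8	2.07	22.2	93
2A5E	3	mixed	2.6	0.1	8.3	22.2	23.9	354	2.3	3.82	24.5	156
2ABD	2	alpha	2.3	0.1	12.0	18.2	20.0	77.5	0.9	1.65	19.1	86
2AIT	2	beta	4.1	0.2	14.4	16.9	18.7	107	1.5	1.36	18.3	74
2CI2	2	mixed	2.7	0.2	10.0	15.1	16.9	78.3	1.2	1.06	16.4	65
2CRO	3	alpha	1.2	0.1	7.3	14.0	15.5	37.3	0.6	0.95	14.6	65
2HQI	2	mixed	4.3	0.2	13.6	16.3	18.4	86.9	1.2	1.26	17.5	72
2PDD	2	alpha	1.0	0.1	4.8	10.6	11.5	19.9	0.5	0.48	11.0	43
2RN2	3	mixed	3.6	0.1	19.3	27.7	30.9	521	3.4	4.81	31.0	155
1O6D	NA	knotted	3.1	0.1	18.9	26.2	28.7	515	3.5	4.36	29.7	147
2HA8	NA	knotted	3.3	0.1	16.2	25.7	28.5	671	4.1	4.84	29.9	162
2K0A	NA	knotted	3.4	0.1	14.6	22.4	24.5	369	3.4	2.81	25.8	109
2EFV	NA	knotted	2.1	0.2	12.6	20.0	21.8	147	1.8	1.79	21.8	82
1NS5	3	knotted	2.9	0.1	18.2	27.5	30.4	503	3.3	4.71	30.8	153
1MXI	3	knotted	2.8	0.1	16.7	26.1	29.0	643	4.0	4.85	30.1	161
3MLG	3	knotted	1.2	0.1	21.4	27.7	30.8	481	2.8	5.16	30.5	169
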