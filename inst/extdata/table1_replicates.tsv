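sample_id	tissue	protocol	replicate	total_reads	unique_mapped	exonic_reads	exonic_pct
B_M_1	blood	polyA	1	50000000	43215282	38254168	76.51
B_M_2	blood	polyA	2	50000000	42476355	37646793	75.29
B_M_3	blood	polyA	3	50000000	42185029	37072203	74.14
B_M_4	blood	polyA	4	50000000	42954993	37813280	75.63
B_T_1	blood	riboZ	1	50000000	41513424	11665272	23.33
B_T_2	blood	riboZ	2	50000000	41614111	11714372	23.43
B_T_3	blood	riboZ	3	50000000	41637819	11641934	23.28
B_T_4	blood	riboZ	4	50000000	41265342	11405741	22.81
C_M_1	colon	polyA	1	50000000	43281953	38971070	77.94
C_M_2	colon	polyA	2	50000000	44375310	40053155	80.11
C_M_3	colon	polyA	3	50000000	42908688	38368949	76.74
C_M_4	colon	polyA	4	50000000	44432717	39891693	79.78
C_T_1	colon	riboZ	1	50000000	42294547	23989467	47.98
C_T_2	colon	riboZ	2	50000000	41719947	22908423	45.82
C_T_3	colon	riboZ	3	50000000	42491691	24288251	48.58
C_T_4	colon	riboZ	4	50000000	42028918	23779962	47.56
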