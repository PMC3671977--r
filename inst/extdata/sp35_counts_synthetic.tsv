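# SYNTHETIC spectral-count matrix for the 35-protein seminal-plasma
# catalog: a deterministic constraint-guided reconstruction (seed 42,
# library size 500) consistent with the packaged classification table.
# The study's raw counts are unpublished; this matrix reproduces their
# printed categorization, not their values. Isoform accessions appear
# as separate rows in the replicates where the identification table
# lists them; resolve_aliases() folds them into the 35-row catalog.
accession	NN1	NN2	NN3	NN4	NN5	NA1	NA2	NA3	NA4	OA1	OA2	ON1
4505821	606	554	488	569	623	587	544	616	562	568	556	521
4506885	25	1	1	1	1	1	1	1	20	1	11	10
4502027	1	1	1	25	1	1	20	1	1	11	1	10
54607120	1	1	25	1	1	20	1	1	1	11	1	10
5453678	25	1	1	1	1	1	20	1	1	1	11	10
221316614	1	25	1	1	0	1	0	1	0	0	0	10
11386147	1	1	1	1	25	1	20	1	1	1	11	10
4503143	1	25	1	1	1	1	1	20	1	11	1	10
4502173	0	1	1	25	1	1	1	1	20	1	0	10
4502337	1	1	1	12	1	10	1	1	1	1	10	10
42716297	1	1	1	1	12	1	10	1	1	10	1	1
151301154	0	1	34	1	1	0	0	0	0	0	0	10
4503109	1	1	59	0	1	1	1	1	10	10	1	1
5031863	1	1	1	1	10	0	1	10	1	1	1	1
38049014	1	0	27	1	0	20	1	1	1	26	1	10
6382064	1	1	31	1	0	10	1	0	1	1	13	1
4503107	0	54	1	1	1	0	44	1	1	0	10	11
4507509	0	1	1	13	0	0	10	1	1	0	10	10
4757826	0	1	0	10	1	10	1	0	1	0	2	10
31543380	1	10	0	0	0	1	0	1	18	0	0	10
56676397	0	0	0	0	0	0	4	0	0	1	10	2
167857790	0	1	0	11	0	0	0	4	0	0	0	0
50363217	1	2	9	0	0	1	1	0	20	0	2	10
4557871	4	0	0	0	1	7	1	1	0	0	5	0
4507065	0	0	0	5	0	1	7	1	0	5	0	0
4506713	0	9	3	0	0	0	0	4	0	2	0	0
104487006	0	0	5	0	0	0	1	0	8	0	0	3
25121982	9	0	3	0	0	0	0	4	0	0	0	0
32171249	0	0	0	4	1	0	0	1	3	2	0	0
4503139	3	1	0	0	1	2	1	1	0	0	0	0
19923082	0	0	1	4	0	4	0	0	0	2	0	0
4505529	0	0	0	5	0	0	0	0	0	0	0	0
110735433	0	0	0	0	0	4	0	0	0	2	0	1
4503009	10	1	0	1	0	0	1	10	1	4	1	2
47132551	1	0	0	0	12	0	0	10	1	0	10	0
71834855	1	0	0	0	0	0	0	0	0	0	26	0
89033736	0	0	0	0	0	10	1	1	1	14	1	0
4758236	0	0	0	0	1	0	1	0	20	11	1	0
16933542	0	1	0	1	0	1	1	0	0	0	0	3
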