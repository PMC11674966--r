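gene_id	chromosome	cytoband
GENE_1p_001	1	1p11
GENE_1p_002	1	1p12
STIL	1	1p33
GENE_1q_001	1	1q11
GENE_1q_002	1	1q12
GENE_1q_003	1	1q21
GENE_2p_001	2	2p11
GENE_2p_002	2	2p12
GENE_2p_003	2	2p21
GENE_2q_001	2	2q11
GENE_2q_002	2	2q12
GENE_2q_003	2	2q21
GENE_3p_001	3	3p11
GENE_3p_002	3	3p12
GENE_3p_003	3	3p21
GENE_3q_001	3	3q11
GENE_3q_002	3	3q12
GENE_3q_003	3	3q21
GENE_4p_001	4	4p11
GENE_4p_002	4	4p12
GENE_4p_003	4	4p21
GENE_4q_001	4	4q11
GENE_4q_002	4	4q12
GENE_4q_003	4	4q21
GENE_5p_001	5	5p11
GENE_5p_002	5	5p12
GENE_5p_003	5	5p21
GENE_5q_001	5	5q11
GENE_5q_002	5	5q12
GENE_5q_003	5	5q21
GENE_6p_001	6	6p11
GENE_6p_002	6	6p12
GENE_6p_003	6	6p21
GENE_6q_001	6	6q11
GENE_6q_002	6	6q12
GENE_6q_003	6	6q21
GENE_7p_001	7	7p11
GENE_7p_002	7	7p12
GENE_7p_003	7	7p21
GENE_7q_001	7	7q11
GENE_7q_002	7	7q12
GENE_7q_003	7	7q21
GENE_8p_001	8	8p11
GENE_8p_002	8	8p12
GENE_8p_003	8	8p21
GENE_8q_001	8	8q11
GENE_8q_002	8	8q12
GENE_8q_003	8	8q21
GENE_9p_001	9	9p11
GENE_9p_002	9	9p12
GENE_9p_003	9	9p21
GENE_9q_001	9	9q11
GENE_9q_002	9	9q12
GENE_9q_003	9	9q21
GENE_10p_001	10	10p11
GENE_10p_002	10	10p12
GENE_10p_003	10	10p21
GENE_10q_001	10	10q11
GENE_10q_002	10	10q12
GENE_10q_003	10	10q21
GENE_11p_001	11	11p11
GENE_11p_002	11	11p12
GENE_11p_003	11	11p21
GENE_11q_001	11	11q11
GENE_11q_002	11	11q12
GENE_11q_003	11	11q21
GENE_12p_001	12	12p11
GENE_12p_002	12	12p12
GENE_12p_003	12	12p21
GENE_12q_001	12	12q11
GENE_12q_002	12	12q12
GENE_12q_003	12	12q21
GENE_13q_001	13	13q11
GENE_13q_002	13	13q12
GENE_13q_003	13	13q21
GENE_14q_001	14	14q11
GENE_14q_002	14	14q12
GENE_14q_003	14	14q21
GENE_15q_001	15	15q11
GENE_15q_002	15	15q12
GENE_15q_003	15	15q21
GENE_16p_001	16	16p11
GENE_16p_002	16	16p12
GENE_16p_003	16	16p21
GENE_16q_001	16	16q11
GENE_16q_002	16	16q12
GENE_16q_003	16	16q21
GENE_17p_001	17	17p11
GENE_17p_002	17	17p12
GENE_17p_003	17	17p21
GENE_17q_001	17	17q11
GENE_17q_002	17	17q12
GENE_17q_003	17	17q21
GENE_18p_001	18	18p11
GENE_18p_002	18	18p12
GENE_18p_003	18	18p21
GENE_18q_001	18	18q11
GENE_18q_002	18	18q12
GENE_18q_003	18	18q21
GENE_19p_001	19	19p11
GENE_19p_002	19	19p12
GENE_19p_003	19	19p21
GENE_19q_001	19	19q11
GENE_19q_002	19	19q12
GENE_19q_003	19	19q21
GENE_20p_001	20	20p11
GENE_20p_002	20	20p12
GENE_20p_003	20	20p21
GENE_20q_001	20	20q11
GENE_20q_002	20	20q12
GENE_20q_003	20	20q21
GENE_21q_001	21	21q11
GENE_21q_002	21	21q12
GENE_21q_003	21	21q21
GENE_22q_001	22	22q11
GENE_22q_002	22	22q12
GENE_22q_003	22	22q21
GENE_Xp_001	X	Xp11
GENE_Xp_002	X	Xp12
GENE_Xp_003	X	Xp21
GENE_Xq_001	X	Xq11
GENE_Xq_002	X	Xq12
GENE_Xq_003	X	Xq21
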