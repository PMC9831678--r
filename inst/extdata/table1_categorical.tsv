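variable	level	negative	positive
gender	Male	75	74
gender	Female	38	31
smoking	Yes	50	56
smoking	No	63	49
drinking	Yes	19	22
drinking	No	94	83
antibiotic_history	Yes	24	27
antibiotic_history	No	89	78
diabetes	Yes	9	22
diabetes	No	104	83
site	Tongue	65	43
site	Buccal	21	20
site	Gingival	13	19
site	Palate	4	5
site	Oral floor	8	12
site	Others	2	6
appearance	Exogenous	54	52
appearance	Ulcer	48	45
appearance	Infiltrating	11	8
t_staging	T1/T2	56	33
t_staging	T3	37	20
t_staging	T4	20	52
n_staging	N0	63	43
n_staging	N1	25	22
n_staging	N2	22	37
n_staging	N3	3	3
cervical_lymph_node_metastasis	Yes	50	62
cervical_lymph_node_metastasis	No	63	43
pathological_grading	High	83	62
pathological_grading	Moderate	29	40
pathological_grading	Poor	1	3
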