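variable	unit	mean_negative	sd_negative	mean_positive	sd_positive
age	years	52.06	12.59	52.81	12.44
bmi	kg/m2	22.90	2.68	22.71	2.92
white_blood_cell	1e9/L	6.50	1.74	6.82	2.35
neutrophils	1e9/L	3.84	1.47	4.21	2.09
lymphocyte	1e9/L	2.04	0.76	1.92	0.65
neutrophil_lymphocyte_ratio	ratio	2.12	1.15	2.43	1.53
monocytes	1e9/L	0.44	0.14	0.62	1.15
c_reactive_protein	mg/L	2.76	5.92	2.85	4.61
procalcitonin	ng/mL	0.06	0.02	0.28	2.18
albumin	g/L	40.92	3.35	41.33	3.82
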