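metabolite	quant_type	iso_1_rep1	iso_1_rep2	iso_1_rep3	iso_2_rep1	iso_2_rep2	iso_2_rep3	ctrl_01	ctrl_02	ctrl_03	blank_01	blank_02
glucose	height	120	150	135	1900	2100	2050	1500	2000	1800	12	18
alanine	height	480	510	470	90	85	110	950	1000	900	5	6
uracil	area	60	75	70	65	80	72	700	650	720	2	3
succinate	height	3100	2900	3050	2950	3020	2980	1000	980	1050	10	8
trehalose	height	40	45	42	38	50	44	30	28	35	25	30
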