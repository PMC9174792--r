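sample_id	role	isolate	replicate
iso_1_rep1	culture	iso_1	1
iso_1_rep2	culture	iso_1	2
iso_1_rep3	culture	iso_1	3
iso_2_rep1	culture	iso_2	1
iso_2_rep2	culture	iso_2	2
iso_2_rep3	culture	iso_2	3
ctrl_01	uninoculated_control	NA	1
ctrl_02	uninoculated_control	NA	2
ctrl_03	uninoculated_control	NA	3
blank_01	extraction_blank	NA	1
blank_02	extraction_blank	NA	2
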