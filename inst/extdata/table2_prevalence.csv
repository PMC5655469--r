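ethnicity,sex,age_band,prevalence_pct
non_maori,male,40-44,1.19
non_maori,male,45-49,4.82
non_maori,male,50-54,4.79
non_maori,male,55-59,6.27
non_maori,male,60-64,6.30
non_maori,male,65-69,11.40
non_maori,male,70-74,11.44
non_maori,male,75-79,12.75
non_maori,male,80-84,12.85
non_maori,female,40-44,0.80
non_maori,female,45-49,4.47
non_maori,female,50-54,4.47
non_maori,female,55-59,10.45
non_maori,female,60-64,10.41
non_maori,female,65-69,16.98
non_maori,female,70-74,16.92
non_maori,female,75-79,21.55
non_maori,female,80-84,21.50
maori,male,40-44,0.86
maori,male,45-49,2.88
maori,male,50-54,2.88
maori,male,55-59,9.72
maori,male,60-64,9.72
maori,male,65-69,14.43
maori,male,70-74,14.43
maori,male,75-79,20.84
maori,male,80-84,20.84
maori,female,40-44,1.29
maori,female,45-49,4.83
maori,female,50-54,4.83
maori,female,55-59,6.98
maori,female,60-64,6.98
maori,female,65-69,13.10
maori,female,70-74,13.10
maori,female,75-79,18.34
maori,female,80-84,18.34
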