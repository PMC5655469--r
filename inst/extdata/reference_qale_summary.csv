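ethnicity,sex,qale_no_oa,qale_oa,qale_counterfactual,per_person_loss,population_loss
non_maori,male,19.73,12.20,15.54,3.34,166023
non_maori,female,21.96,12.22,15.77,3.55,272568
maori,male,17.57,10.05,12.64,2.60,11562
maori,female,19.78,12.17,15.55,3.38,17087
all,all,20.67,12.14,15.57,3.44,467240
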