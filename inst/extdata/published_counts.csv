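name,n,N
initial_participants,17330,NA
eligible_two_valid_weights,15533,17330
excluded_ineligible_pregnancy,247,15533
study_population,15286,NA
ref_excl_late_baseline,115,NA
ref_excl_preterm,1783,NA
ref_excl_stillbirth,393,NA
reference_subpopulation,12995,NA
preterm_birth,1993,15286
low_birth_weight,3758,15286
sga_10th,5471,15265
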