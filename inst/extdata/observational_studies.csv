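label,or,ci_low,ci_high,n_cases,n_controls,outcome_class
swedish_cohort,1.50,1.10,2.00,NA,NA,schizophrenia
dunedin,NA,NA,NA,NA,NA,related_disorder
eca,NA,NA,NA,NA,NA,related_disorder
edsp,NA,NA,NA,NA,NA,related_disorder
nemesis,NA,NA,NA,NA,NA,related_disorder
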