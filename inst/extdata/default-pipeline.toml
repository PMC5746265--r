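# Synthetic cohort + recurrence statistics pipeline.

[cohort]
mode = "logistic"      # single population, labels from a logistic
n = 200                # model on RFV; "groups" gives the 24/13 split
logistic_beta0 = -2
logistic_beta_rfv = 0.06
seed = 1

[stats]
gate_p = 0.05
R_threshold = 0.7
removal_p = 0.10
criterion = "LRT"
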