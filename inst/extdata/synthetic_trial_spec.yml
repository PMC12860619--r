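# Synthetic trial spec (all quantities are invented truths, not trial data):
# stratum event rates, homozygote prevalence, and fixed arm sizes.
r_hA: 0.33
r_hP: 0.04
r_nA: 0.09
r_nP: 0.01
pi: 0.15
n_h_active: 141
n_h_placebo: 133
n_n_active: 757
n_n_placebo: 764
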