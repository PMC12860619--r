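# Shared fixtures for the suite. All numeric anchors were computed once by
# independent arithmetic / simulation on the published cell counts and are
# frozen here.

minimal_table <- function() {
  strat_table(1, 1, 1, 1, 1, 1, 1, 1, drug = "toy", outcome = "toy")
}

# synthetic truth at trial-scale arm sizes, close to the lecanemab
# any-ARIA-E point estimates
trial_scale_spec <- function() {
  synthetic_spec(r_hA = 0.33, r_hP = 0.04, r_nA = 0.09, r_nP = 0.01,
                 pi = 0.15,
                 n_h_active = 141, n_h_placebo = 133,
                 n_n_active = 757, n_n_placebo = 764)
}

# brute-force agent-level simulator: N patients, genotype ~ Bern(pi),
# homozygotes withheld with probability p (event rate r_hP if withheld,
# r_hA otherwise), non-homozygotes always treated at r_nA. Returns the
# realized event proportion; independent of the closed-form code path.
simulate_policy_risk <- function(n, r_hA, r_hP, r_nA, pi, p) {
  homo <- stats::rbinom(n, 1, pi) == 1
  withheld <- homo & stats::rbinom(n, 1, p) == 1
  rate <- ifelse(withheld, r_hP, ifelse(homo, r_hA, r_nA))
  mean(stats::rbinom(n, 1, rate))
}
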