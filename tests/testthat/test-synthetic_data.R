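test_that("degenerate true rates give degenerate tables", {
  z <- synthetic_spec(0, 0, 0, 0, pi = 0.5,
                      n_h_active = 5, n_h_placebo = 5,
                      n_n_active = 5, n_n_placebo = 5)
  t0 <- generate_trial(z, seed = 1)
  expect_equal(c(t0$A_h, t0$C_h, t0$A_n, t0$C_n), rep(0L, 4))
  o <- synthetic_spec(1, 1, 1, 1, pi = 0.5,
                      n_h_active = 5, n_h_placebo = 5,
                      n_n_active = 5, n_n_placebo = 5)
  t1 <- generate_trial(o, seed = 1)
  expect_equal(c(t1$B_h, t1$D_h, t1$B_n, t1$D_n), rep(0L, 4))
})

test_that("generation is reproducible and honours fixed arm sizes", {
  sp <- trial_scale_spec()
  a <- generate_trial(sp, seed = 99)
  b <- generate_trial(sp, seed = 99)
  expect_equal(a, b)
  expect_equal(a$A_h + a$B_h, 141L)
  expect_equal(a$C_h + a$D_h, 133L)
  expect_equal(a$A_n + a$B_n, 757L)
  expect_equal(a$C_n + a$D_n, 764L)
})

test_that("generated point rates sit within binomial error of the truth", {
  sp <- trial_scale_spec()
  tab <- generate_trial(sp, seed = 7)
  r <- point_rates(tab)
  for (cell in list(c("r_hA", 141), c("r_hP", 133),
                    c("r_nA", 757), c("r_nP", 764))) {
    truth <- sp[[cell[1]]]
    se <- sqrt(truth * (1 - truth) / as.numeric(cell[2]))
    expect_lt(abs(r[[cell[1]]] - truth), 3 * se + 1e-12)
  }
})

test_that("total-N mode randomizes stratum membership around pi", {
  sp <- synthetic_spec(0.3, 0.05, 0.1, 0.01, pi = 0.15, n_total = 4000)
  pis <- vapply(1:30, function(i) pi_hat(generate_trial(sp, seed = i)), 0)
  se <- sqrt(0.15 * 0.85 / 4000)
  expect_lt(abs(mean(pis) - 0.15), 3 * se / sqrt(30))
  expect_gt(stats::sd(pis), 0)    # membership really is random
})

test_that("generated point NNTs bracket the fixture point estimate", {
  # truth set exactly at the lecanemab any-ARIA-E point estimates
  pts <- point_rates(builtin_table("lecanemab", "any-ARIA-E"))
  sp <- synthetic_spec(pts$r_hA, pts$r_hP, pts$r_nA, pts$r_nP, pi = pts$pi,
                       n_h_active = 141, n_h_placebo = 133,
                       n_n_active = 757, n_n_placebo = 764)
  target <- nnt(pts$r_hA - pts$r_hP, pts$pi, 1)   # 22.696
  nnts <- vapply(1:40, function(i) {
    r <- point_rates(generate_trial(sp, seed = 1000 + i))
    nnt(r$r_hA - r$r_hP, r$pi, 1)
  }, 0)
  expect_lt(min(nnts), target)
  expect_gt(max(nnts), target)
})

test_that("recovery experiment reports coverage and is attributable", {
  sp <- trial_scale_spec()
  rep1 <- recovery_experiment(sp, n_replicates = 25, n_draws = 800,
                              p = 1, seed = 13)
  rep2 <- recovery_experiment(sp, n_replicates = 25, n_draws = 800,
                              p = 1, seed = 13)
  expect_identical(rep1$coverage, rep2$coverage)
  expect_true(rep1$coverage >= 0 && rep1$coverage <= 1)
  expect_equal(rep1$true_nnt, 1 / (0.15 * (0.33 - 0.04)))
  expect_length(rep1$covered, 25L)
  # the two seed streams are distinct
  expect_false(identical(rep1$table_seeds, rep1$post_seeds))

  one <- recovery_experiment(sp, n_replicates = 1, n_draws = 500, seed = 2)
  expect_true(one$coverage %in% c(0, 1))
})

test_that("degenerate recovery targets are refused or skipped explicitly", {
  harmful <- synthetic_spec(0.05, 0.10, 0.05, 0.01, pi = 0.2,
                            n_h_active = 100, n_h_placebo = 100,
                            n_n_active = 100, n_n_placebo = 100)
  expect_error(recovery_experiment(harmful, n_replicates = 2, seed = 1),
               "RD_h <= 0")
  skipped <- recovery_experiment(trial_scale_spec(), n_replicates = 2,
                                 p = 0, seed = 1)
  expect_equal(skipped$status, "skipped")
  expect_identical(skipped$true_nnt, Inf)
  expect_true(is.na(skipped$coverage))
})

test_that("spec files validate their fields", {
  f <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(r_hA = 0.3, r_hP = 0.05, r_nA = 0.1, pi = 0.15,
                        n_total = 1000), f)
  expect_error(read_synthetic_spec(f), "r_nP")

  g <- system.file("extdata", "synthetic_trial_spec.yml",
                   package = "ariannt")
  sp <- read_synthetic_spec(g)
  expect_s3_class(sp, "synthetic_spec")
  expect_equal(sp$mode, "fixed")
  expect_error(synthetic_spec(0.3, 0.05, 0.1, 0.01, pi = 0.15,
                              n_h_active = 10, n_h_placebo = 10,
                              n_n_active = 10, n_n_placebo = 10,
                              n_total = 100),
               "not both")
})
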