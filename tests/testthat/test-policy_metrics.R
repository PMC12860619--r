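# Frozen closed-form anchors, computed by independent arithmetic on the
# published cell counts:
#   lecanemab any-ARIA-E:  pi = 274/1795, r_hA = 46/141, r_hP = 5/133,
#     r_nA = 67/757 -> risk_base 0.1247964, risk_policy(p=1) 0.08073554,
#     ARR(p=1) 0.0440609, reduction(p=1) 0.3530622, NNT(p=1) 22.69586
#   lecanemab any-ARIA-H NNT(p=1) 36.48728; donanemab any-ARIA-H 19.97053
#   donanemab any-ARIA-E 16.02691; lecanemab symptomatic 71.05418 and
#   reduction 0.5116606.

lec_e <- point_rates(builtin_table("lecanemab", "any-ARIA-E"))

test_that("baseline and policy risks match hand arithmetic", {
  expect_equal(risk_base(lec_e$r_hA, lec_e$r_nA, lec_e$pi),
               0.1247964, tolerance = 1e-6)
  expect_equal(risk_policy(lec_e$r_hA, lec_e$r_hP, lec_e$r_nA, lec_e$pi,
                           p = 1),
               0.08073554, tolerance = 1e-6)
  # limits in pi and p
  expect_equal(risk_base(0.3, 0.1, pi = 0), 0.1)
  expect_equal(risk_base(0.3, 0.1, pi = 1), 0.3)
  expect_equal(risk_policy(0.3, 0.1, 0.2, 0.5, p = 0),
               risk_base(0.3, 0.2, 0.5))
  expect_equal(risk_policy(0.3, 0.3, 0.2, 0.5, p = 0.7),
               risk_base(0.3, 0.2, 0.5))
  expect_error(risk_base(1.2, 0.1, 0.5), "\\[0, 1\\]")
})

test_that("ARR, NNT and reduction match the published point estimates", {
  rd_h <- lec_e$r_hA - lec_e$r_hP
  expect_equal(arr(rd_h, lec_e$pi, p = 1), 0.0440609, tolerance = 1e-6)
  expect_equal(arr(0.5, 0.5, 0.5), 0.125)
  expect_equal(arr(rd_h, lec_e$pi, p = 0), 0)

  point_nnt <- function(drug, outcome, p = 1) {
    r <- point_rates(builtin_table(drug, outcome))
    nnt(r$r_hA - r$r_hP, r$pi, p)
  }
  expect_equal(point_nnt("lecanemab", "any-ARIA-E"), 22.69586,
               tolerance = 1e-6)
  expect_equal(point_nnt("donanemab", "any-ARIA-E"), 16.02691,
               tolerance = 1e-6)
  expect_equal(point_nnt("lecanemab", "any-ARIA-H"), 36.48728,
               tolerance = 1e-6)
  expect_equal(point_nnt("donanemab", "any-ARIA-H"), 19.97053,
               tolerance = 1e-6)
  expect_equal(point_nnt("lecanemab", "symptomatic-ARIA-E"), 71.05418,
               tolerance = 1e-6)

  expect_equal(reduction(rd_h, lec_e$r_hA, lec_e$r_nA, lec_e$pi, p = 1),
               0.3530622, tolerance = 1e-6)
  sym <- point_rates(builtin_table("lecanemab", "symptomatic-ARIA-E"))
  expect_equal(reduction(sym$r_hA - sym$r_hP, sym$r_hA, sym$r_nA, sym$pi,
                         p = 1),
               0.5116606, tolerance = 1e-6)
  expect_equal(reduction(rd_h, lec_e$r_hA, lec_e$r_nA, lec_e$pi, p = 0), 0)
  expect_error(reduction(0.1, 0, 0, 0.5, 1), "undefined")
})

test_that("zero or negative ARR maps NNT to infinity, never to an error", {
  expect_identical(nnt(0.2, 0.15, p = 0), Inf)
  expect_identical(nnt(0, 0.15, p = 1), Inf)
  expect_identical(nnt(-0.1, 0.15, p = 1), Inf)
})

test_that("risk_base - risk_policy equals ARR to machine precision", {
  set.seed(42)
  for (i in 1:200) {
    r_hA <- runif(1); r_hP <- runif(1); r_nA <- runif(1)
    pi <- runif(1); p <- runif(1)
    expect_equal(risk_base(r_hA, r_nA, pi) -
                   risk_policy(r_hA, r_hP, r_nA, pi, p),
                 arr(r_hA - r_hP, pi, p),
                 tolerance = 1e-12)
  }
})

test_that("NNT scales exactly as 1/p and reduction linearly in p", {
  rd_h <- lec_e$r_hA - lec_e$r_hP
  ps <- c(0.1, 0.25, 0.5, 0.8, 1)
  expect_equal(nnt(rd_h, lec_e$pi, ps), nnt(rd_h, lec_e$pi, 1) / ps)
  expect_equal(reduction(rd_h, lec_e$r_hA, lec_e$r_nA, lec_e$pi, ps),
               ps * reduction(rd_h, lec_e$r_hA, lec_e$r_nA, lec_e$pi, 1))
  # strict monotonicity for positive RD_h
  nn <- nnt(rd_h, lec_e$pi, ps)
  expect_true(all(diff(nn) < 0))
  expect_true(all(diff(reduction(rd_h, lec_e$r_hA, lec_e$r_nA,
                                 lec_e$pi, ps)) > 0))
})

test_that("an agent-level simulator reproduces the closed forms", {
  set.seed(2718)
  n <- 2e5
  p <- 0.4
  sim_base <- simulate_policy_risk(n, lec_e$r_hA, lec_e$r_hP, lec_e$r_nA,
                                   lec_e$pi, p = 0)
  sim_pol <- simulate_policy_risk(n, lec_e$r_hA, lec_e$r_hP, lec_e$r_nA,
                                  lec_e$pi, p = p)
  rb <- risk_base(lec_e$r_hA, lec_e$r_nA, lec_e$pi)
  rp <- risk_policy(lec_e$r_hA, lec_e$r_hP, lec_e$r_nA, lec_e$pi, p)
  se <- sqrt(rb * (1 - rb) / n)
  expect_lt(abs(sim_base - rb), 3 * se)
  expect_lt(abs(sim_pol - rp), 3 * se)
  expect_lt(abs((sim_base - sim_pol) - arr(lec_e$r_hA - lec_e$r_hP,
                                           lec_e$pi, p)),
            3 * sqrt(2) * se)
})

test_that("NNT_MRI divides by the assumed scans per event", {
  expect_equal(nnt_mri(80, 4), 20)
  expect_equal(nnt_mri(36.5, 1), 36.5)
  expect_identical(nnt_mri(Inf, 2), Inf)
  expect_error(nnt_mri(80, 0), "k must be > 0")
  expect_error(nnt_mri(80, -1), "k must be > 0")
})

test_that("policy_point assembles all metrics consistently", {
  df <- policy_point(builtin_table("donanemab", "any-ARIA-H"),
                     p = c(0, 0.25, 1), k = 2)
  expect_equal(df$risk_base - df$risk_policy, df$arr)
  expect_equal(df$nnt_mri, df$nnt / 2)
  expect_identical(df$nnt[df$p == 0], Inf)
  expect_equal(df$nnt[df$p == 0.25], 4 * df$nnt[df$p == 1])
  expect_equal(df$nnt[df$p == 1], 19.97053, tolerance = 1e-6)
})
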