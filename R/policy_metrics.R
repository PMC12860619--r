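#' Policy metrics for probabilistic genotype-guided withholding
#'
#' Closed-form metrics for the policy that withholds anti-amyloid therapy
#' from APOE \eqn{\epsilon4/\epsilon4} patients with probability `p`, given
#' stratum event rates and homozygote prevalence \eqn{\pi}:
#'
#' \itemize{
#'   \item baseline risk (treat everyone):
#'     \eqn{risk_{base} = \pi r_{hA} + (1-\pi) r_{nA}}
#'   \item policy risk: \eqn{risk_{policy} = \pi\{(1-p) r_{hA} + p\, r_{hP}\}
#'     + (1-\pi) r_{nA}}
#'   \item absolute risk reduction:
#'     \eqn{ARR = risk_{base} - risk_{policy} = p \pi RD_h}
#'     where \eqn{RD_h = r_{hA} - r_{hP}}
#'   \item number needed to test: \eqn{NNT = 1/ARR} (infinite when
#'     \eqn{ARR \le 0})
#'   \item fractional reduction in total events:
#'     \eqn{Reduction = ARR / risk_{base}}, proportional to `p`
#'   \item \eqn{NNT_{MRI} = NNT / k}, the tests needed to avert one MRI scan
#'     when each event triggers on average `k` additional scans.
#' }
#'
#' All functions are vectorized over draws, so they apply equally to point
#' estimates and to Monte-Carlo samples.
#'
#' @param r_hA,r_hP,r_nA Stratum event rates in \eqn{[0, 1]} (homozygote
#'   active, homozygote placebo, non-homozygote active).
#' @param RD_h Homozygote risk difference \eqn{r_{hA} - r_{hP}} in
#'   \eqn{[-1, 1]}.
#' @param pi Homozygote prevalence in \eqn{[0, 1]}.
#' @param p Withholding probability in \eqn{[0, 1]}.
#' @param nnt_value An NNT (positive or `Inf`).
#' @param k Average additional MRI scans per event; a pure user assumption,
#'   default 1.
#'
#' @return Numeric vectors: proportions for `risk_base`/`risk_policy`, reals
#'   for `arr`/`reduction`, positive reals or `Inf` for `nnt`/`nnt_mri`.
#'
#' @examples
#' rates <- point_rates(builtin_table("lecanemab", "any-ARIA-E"))
#' rd <- risk_differences(rates)
#' nnt(rd$RD_h, rates$pi, p = 1)        # ~22.7
#' reduction(rd$RD_h, rates$r_hA, rates$r_nA, rates$pi, p = 1)  # ~0.35
#' @name policy_metrics
NULL

.check_unit <- function(x, nm, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(nm, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(x)
}

#' @rdname policy_metrics
#' @export
risk_base <- function(r_hA, r_nA, pi) {
  .check_unit(r_hA, "r_hA"); .check_unit(r_nA, "r_nA"); .check_unit(pi, "pi")
  pi * r_hA + (1 - pi) * r_nA
}

#' @rdname policy_metrics
#' @export
risk_policy <- function(r_hA, r_hP, r_nA, pi, p) {
  .check_unit(r_hA, "r_hA"); .check_unit(r_hP, "r_hP")
  .check_unit(r_nA, "r_nA"); .check_unit(pi, "pi"); .check_unit(p, "p")
  pi * ((1 - p) * r_hA + p * r_hP) + (1 - pi) * r_nA
}

#' @rdname policy_metrics
#' @export
arr <- function(RD_h, pi, p) {
  .check_unit(RD_h, "RD_h", -1, 1); .check_unit(pi, "pi")
  .check_unit(p, "p")
  p * pi * RD_h
}

#' @rdname policy_metrics
#' @export
nnt <- function(RD_h, pi, p) {
  a <- arr(RD_h, pi, p)
  ifelse(a > 0, 1 / a, Inf)
}

#' @rdname policy_metrics
#' @export
reduction <- function(RD_h, r_hA, r_nA, pi, p) {
  base <- risk_base(r_hA, r_nA, pi)
  if (any(base <= 0)) {
    stop("risk_base is 0: reduction fraction undefined", call. = FALSE)
  }
  arr(RD_h, pi, p) / base
}

#' @rdname policy_metrics
#' @export
nnt_mri <- function(nnt_value, k) {
  if (!is.numeric(k) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  if (any(nnt_value[is.finite(nnt_value)] <= 0)) {
    stop("nnt_value must be positive or Inf", call. = FALSE)
  }
  nnt_value / k
}

#' Point-estimate policy metrics at given withholding probabilities
#'
#' Evaluates all closed-form policy metrics from a table's raw event
#' proportions (no prior, no sampling), one row per requested `p`.
#'
#' @param table A [strat_table()].
#' @param p Vector of withholding probabilities.
#' @param k Average additional MRI scans per event.
#' @param pi_override Optional prevalence override.
#' @return A data.frame with columns `p`, `risk_base`, `risk_policy`, `arr`,
#'   `nnt`, `reduction`, `nnt_mri`, plus attributes `drug`, `outcome`, `k`.
#' @examples
#' policy_point(builtin_table("donanemab", "any-ARIA-H"), p = c(0.25, 1))
#' @export
policy_point <- function(table, p = 1, k = 1, pi_override = NULL) {
  rates <- point_rates(table, pi_override = pi_override)
  rd <- risk_differences(rates)
  out <- data.frame(
    p           = p,
    risk_base   = risk_base(rates$r_hA, rates$r_nA, rates$pi),
    risk_policy = risk_policy(rates$r_hA, rates$r_hP, rates$r_nA,
                              rates$pi, p),
    arr         = arr(rd$RD_h, rates$pi, p),
    nnt         = nnt(rd$RD_h, rates$pi, p),
    reduction   = reduction(rd$RD_h, rates$r_hA, rates$r_nA, rates$pi, p))
  out$nnt_mri <- nnt_mri(out$nnt, k)
  attr(out, "drug") <- table$drug
  attr(out, "outcome") <- table$outcome
  attr(out, "k") <- k
  out
}
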