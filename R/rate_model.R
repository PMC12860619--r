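#' Jeffreys Beta posterior for a binomial event rate
#'
#' For a cell with `events` successes and `non_events` failures, the Jeffreys
#' prior Beta(0.5, 0.5) yields the conjugate posterior
#' Beta(events + 0.5, non_events + 0.5). Zero cells are handled by the prior
#' mass: (0, n) gives Beta(0.5, n + 0.5), a proper posterior concentrated
#' near zero but never degenerate.
#'
#' @param events,non_events Non-negative counts.
#' @return An object of class `beta_posterior`: `list(alpha, beta)` with both
#'   shape parameters positive.
#' @examples
#' posterior_params(46, 95)   # Beta(46.5, 95.5)
#' posterior_params(0, 0)     # the prior itself
#' @export
posterior_params <- function(events, non_events) {
  if (!is.numeric(events) || !is.numeric(non_events) ||
      events < 0 || non_events < 0) {
    stop("events and non_events must be non-negative counts", call. = FALSE)
  }
  structure(list(alpha = events + 0.5, beta = non_events + 0.5),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g), mean %.5f\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Raw event proportion
#'
#' The frequentist point estimate `events / n`, with no prior. Used for the
#' closed-form (non-sampled) policy metrics.
#'
#' @param events Non-negative count of events.
#' @param n Positive arm total.
#' @return `events / n`.
#' @examples
#' point_rate(46, 141)
#' @export
point_rate <- function(events, n) {
  if (n <= 0) stop("arm total n must be > 0", call. = FALSE)
  events / n
}

#' Point estimates of the four stratum rates and prevalence
#'
#' @param table A [strat_table()].
#' @param pi_override Optional prevalence override passed to [pi_hat()].
#' @return A list with `r_hA`, `r_hP`, `r_nA`, `r_nP` (raw proportions) and
#'   `pi`.
#' @export
point_rates <- function(table, pi_override = NULL) {
  table <- validate_strat_table(table)
  list(r_hA = point_rate(table$A_h, table$A_h + table$B_h),
       r_hP = point_rate(table$C_h, table$C_h + table$D_h),
       r_nA = point_rate(table$A_n, table$A_n + table$B_n),
       r_nP = point_rate(table$C_n, table$C_n + table$D_n),
       pi   = pi_hat(table, override = pi_override))
}

#' Joint Monte-Carlo sample of stratum rates and prevalence
#'
#' Draws `n_draws` independent samples of each stratum-by-arm event rate from
#' its Jeffreys Beta posterior (`r_hA ~ Beta(A_h + 0.5, B_h + 0.5)` and
#' analogues), and of the homozygote prevalence \eqn{\pi}. The five
#' components are sampled mutually independently; no joint structure is
#' imposed.
#'
#' \eqn{\pi} is treated the same way as the rates: with `pi_mode = "sampled"`
#' (default) it is drawn from Beta(n_h + 0.5, n_n + 0.5) where `n_h`, `n_n`
#' are the genotype-stratum totals; `pi_mode = "fixed"` holds it at
#' [pi_hat()] for every draw. At trial sample sizes the two modes differ
#' negligibly.
#'
#' @param table A [strat_table()].
#' @param n_draws Number of Monte-Carlo draws (default 1e5).
#' @param seed Integer seed; if non-NULL the draw is reproducible and the
#'   caller's RNG state is restored afterwards.
#' @param pi_mode `"sampled"` or `"fixed"`.
#' @param pi_override Optional prevalence override (forces `"fixed"`
#'   behaviour at the given value).
#' @return An object of class `rate_draws`: numeric vectors `r_hA`, `r_hP`,
#'   `r_nA`, `r_nP`, `pi` of length `n_draws`, plus `n_draws`, `seed`,
#'   `pi_mode`, and the table labels.
#' @examples
#' d <- sample_joint(builtin_table("lecanemab", "any-ARIA-E"),
#'                   n_draws = 1000, seed = 1)
#' mean(d$r_hA)   # close to 46.5/142
#' @export
sample_joint <- function(table, n_draws = 1e5, seed = NULL,
                         pi_mode = c("sampled", "fixed"),
                         pi_override = NULL) {
  table <- validate_strat_table(table)
  pi_mode <- match.arg(pi_mode)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) {
    stop("n_draws must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rb <- function(events, non_events) {
    post <- posterior_params(events, non_events)
    stats::rbeta(n_draws, post$alpha, post$beta)
  }
  r_hA <- rb(table$A_h, table$B_h)
  r_hP <- rb(table$C_h, table$D_h)
  r_nA <- rb(table$A_n, table$B_n)
  r_nP <- rb(table$C_n, table$D_n)
  if (!is.null(pi_override)) {
    pi_mode <- "fixed"
    pi <- rep(pi_hat(table, override = pi_override), n_draws)
  } else if (pi_mode == "fixed") {
    pi <- rep(pi_hat(table), n_draws)
  } else {
    nt <- .stratum_totals(table)
    pi <- stats::rbeta(n_draws, nt[["n_h"]] + 0.5, nt[["n_n"]] + 0.5)
  }
  structure(list(r_hA = r_hA, r_hP = r_hP, r_nA = r_nA, r_nP = r_nP,
                 pi = pi, n_draws = n_draws, seed = seed, pi_mode = pi_mode,
                 drug = table$drug, outcome = table$outcome),
            class = "rate_draws")
}

#' @export
print.rate_draws <- function(x, ...) {
  cat(sprintf("rate_draws: %s / %s, %d draws (seed %s, pi %s)\n",
              x$drug, x$outcome, x$n_draws,
              if (is.null(x$seed)) "unset" else x$seed, x$pi_mode))
  m <- vapply(x[c("r_hA", "r_hP", "r_nA", "r_nP", "pi")], stats::median, 0)
  print(round(m, 5))
  invisible(x)
}

#' Drug-attributable risk differences per draw
#'
#' Elementwise `RD_h = r_hA - r_hP` (homozygote stratum) and
#' `RD_n = r_nA - r_nP` (non-homozygote stratum). Only `RD_h` enters the
#' withholding-policy formulas; `RD_n` is computed and exposed for
#' completeness of the stratified picture.
#'
#' @param draws A `rate_draws` object from [sample_joint()], or any list with
#'   numeric `r_hA`, `r_hP`, `r_nA`, `r_nP` (e.g. [point_rates()] output).
#' @return An object of class `rd_draws`: vectors `RD_h` and `RD_n`, each in
#'   \eqn{[-1, 1]}.
#' @export
risk_differences <- function(draws) {
  for (nm in c("r_hA", "r_hP", "r_nA", "r_nP")) {
    if (is.null(draws[[nm]])) stop("draws lack component ", nm, call. = FALSE)
  }
  structure(list(RD_h = draws$r_hA - draws$r_hP,
                 RD_n = draws$r_nA - draws$r_nP),
            class = "rd_draws")
}

#' Export rate draws for audit
#'
#' Writes the per-draw rates and prevalence as plain CSV (one row per draw).
#'
#' @param draws A `rate_draws` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  df <- data.frame(r_hA = draws$r_hA, r_hP = draws$r_hP,
                   r_nA = draws$r_nA, r_nP = draws$r_nP, pi = draws$pi)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
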