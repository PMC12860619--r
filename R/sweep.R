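#' Median and 95% equal-tailed credible interval of Monte-Carlo draws
#'
#' Summaries use equal-tailed 2.5/97.5 percentiles with linear interpolation
#' between order statistics (`stats::quantile` type 7), stated explicitly
#' because percentile conventions differ across environments.
#'
#' @param x Non-empty numeric vector of draws.
#' @return Named numeric vector `c(median, lower, upper)`.
#' @examples
#' summarize_draws(1:1000)   # 500.5, 25.975, 975.025
#' @export
summarize_draws <- function(x) {
  if (!length(x)) stop("cannot summarize an empty draw vector", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lower = q[2], upper = q[3])
}

#' NNT summary by quantile transformation of ARR draws
#'
#' Quantiles are computed on the ARR scale and inverted, exploiting the
#' monotonicity of \eqn{x \mapsto 1/x} on positive values: the NNT median is
#' `1/median(p * arr1)` and the 95% bounds swap roles (the upper ARR quantile
#' gives the lower NNT bound). ARR quantiles at or below zero map to `Inf`
#' bounds, which keeps the summary defined when the posterior mass of ARR
#' touches zero. When all draws are positive the result coincides with
#' direct per-draw `1/ARR` quantiles.
#'
#' @param arr_draws ARR draws at `p = 1` (i.e. \eqn{\pi \cdot RD_h} per
#'   draw).
#' @param p Withholding probability scaling the draws.
#' @return Named vector `c(median, lower, upper)` on the NNT scale.
#' @export
nnt_summary_from_arr <- function(arr_draws, p = 1) {
  if (!length(arr_draws)) stop("empty ARR draws", call. = FALSE)
  .check_unit(p, "p")
  inv <- function(a) if (a > 0) 1 / a else Inf
  q <- summarize_draws(p * arr_draws)
  c(median = inv(q[["median"]]),
    lower  = inv(q[["upper"]]),   # largest ARR -> smallest NNT
    upper  = inv(q[["lower"]]))
}

#' Monte-Carlo sweep of policy metrics over a withholding-probability grid
#'
#' Generates one joint set of posterior rate draws (see [sample_joint()])
#' and evaluates ARR, NNT, reduction fraction and \eqn{NNT_{MRI}} at every
#' `p` in the grid, summarising each as median and 95% equal-tailed credible
#' interval. Draws are generated once and reused across the grid, so the
#' curves over `p` are coherent transformations of the same posterior
#' sample and the exact scaling `NNT(p) = NNT(1)/p` holds identically.
#'
#' @param table A [strat_table()].
#' @param p_grid Ordered probabilities in \eqn{[0, 1]}; default 0 to 1 in
#'   steps of 0.01.
#' @param n_draws Number of posterior draws (default 1e5).
#' @param seed Integer seed for reproducibility.
#' @param k Average additional MRI scans per event.
#' @param pi_mode `"sampled"` or `"fixed"` prevalence (see [sample_joint()]).
#' @param pi_override Optional prevalence override.
#' @return An object of class `sweep_result`: the configuration plus
#'   `summary`, a data.frame with one row per `p` x metric
#'   (`arr`, `nnt`, `reduction`, `nnt_mri`) holding `median`, `lower`,
#'   `upper`.
#' @examples
#' sw <- run_sweep(builtin_table("lecanemab", "any-ARIA-E"),
#'                 p_grid = c(0.25, 0.5, 1), n_draws = 2000, seed = 1)
#' subset(sw$summary, metric == "nnt")
#' @export
run_sweep <- function(table, p_grid = seq(0, 1, by = 0.01), n_draws = 1e5,
                      seed = NULL, k = 1,
                      pi_mode = c("sampled", "fixed"), pi_override = NULL) {
  pi_mode <- match.arg(pi_mode)
  if (!is.numeric(p_grid) || !length(p_grid) ||
      anyNA(p_grid) || any(p_grid < 0 | p_grid > 1)) {
    stop("p_grid values must lie in [0, 1]", call. = FALSE)
  }
  draws <- sample_joint(table, n_draws = n_draws, seed = seed,
                        pi_mode = pi_mode, pi_override = pi_override)
  rd <- risk_differences(draws)
  arr1 <- draws$pi * rd$RD_h                      # ARR at p = 1, per draw
  base <- risk_base(draws$r_hA, draws$r_nA, draws$pi)
  red1 <- arr1 / base                             # reduction at p = 1

  rows <- lapply(p_grid, function(p) {
    s_arr <- summarize_draws(p * arr1)
    s_red <- summarize_draws(p * red1)
    s_nnt <- nnt_summary_from_arr(arr1, p)
    s_mri <- s_nnt / k
    data.frame(p = p,
               metric = c("arr", "nnt", "reduction", "nnt_mri"),
               median = c(s_arr[1], s_nnt[1], s_red[1], s_mri[1]),
               lower  = c(s_arr[2], s_nnt[2], s_red[2], s_mri[2]),
               upper  = c(s_arr[3], s_nnt[3], s_red[3], s_mri[3]),
               stringsAsFactors = FALSE)
  })
  structure(list(drug = table$drug, outcome = table$outcome,
                 p_grid = p_grid, summary = do.call(rbind, rows),
                 n_draws = as.integer(n_draws), seed = seed, k = k,
                 pi_mode = pi_mode),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Policy sweep: %s / %s\n", x$drug, x$outcome))
  cat(sprintf("  %d draws, seed %s, k = %g, pi %s, %d grid points\n",
              x$n_draws, if (is.null(x$seed)) "unset" else x$seed,
              x$k, x$pi_mode, length(x$p_grid)))
  show_p <- intersect(c(0.25, 0.5, 1), x$p_grid)
  if (!length(show_p)) show_p <- utils::tail(x$p_grid, 3)
  print(x$summary[x$summary$p %in% show_p, ], row.names = FALSE)
  invisible(x)
}

#' Write a sweep summary to delimited text
#'
#' One row per `p` x metric with median and 95% CrI bounds. The full
#' configuration (labels, draw count, seed, k, prevalence mode) is carried on
#' leading comment lines so the file regenerates exactly. Infinities are
#' rendered as the locale-independent token `inf`.
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# drug: ", sweep$drug),
    paste0("# outcome: ", sweep$outcome),
    paste0("# n_draws: ", sweep$n_draws),
    paste0("# seed: ", if (is.null(sweep$seed)) "unset" else sweep$seed),
    paste0("# k: ", sweep$k),
    paste0("# pi_mode: ", sweep$pi_mode)), con)
  df <- sweep$summary
  for (col in c("median", "lower", "upper")) {
    df[[col]] <- ifelse(is.infinite(df[[col]]), "inf",
                        format(df[[col]], digits = 10))
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a sweep (NNT and reduction versus p)
#'
#' Optional convenience figure in the style of a two-panel policy plot:
#' median curve with shaded 95% credible band, per metric. Requires ggplot2.
#'
#' @param sweep A `sweep_result`.
#' @param metrics Metrics to panel (default `nnt` and `reduction`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metrics = c("nnt", "reduction")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep requires the ggplot2 package", call. = FALSE)
  }
  df <- sweep$summary[sweep$summary$metric %in% metrics &
                        is.finite(sweep$summary$upper), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "withholding probability p", y = NULL,
                  title = paste(sweep$drug, sweep$outcome, sep = " / "))
}
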