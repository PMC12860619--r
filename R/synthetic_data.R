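#' Specification of a synthetic genotype-stratified trial
#'
#' Defines the generative truth for a synthetic trial: the four stratum
#' event rates, the homozygote prevalence, and the arm sizes. Event counts
#' are later drawn Binomially at these rates, the same sampling model the
#' posterior assumes, so recovery tests probe the inference machinery under
#' correct specification.
#'
#' Two sizing modes are supported, mirroring how real tables arise:
#' \itemize{
#'   \item fixed arm sizes (`n_h_active` ... `n_n_placebo` all given):
#'     stratum denominators are conditioned on, as when transcribing a
#'     published table; only event counts are random.
#'   \item total-N mode (`n_total` given): each arm's patients are assigned
#'     to the homozygote stratum with probability `pi`, randomizing stratum
#'     membership so that \eqn{\pi} recovery can itself be tested.
#' }
#'
#' @param r_hA,r_hP,r_nA,r_nP True stratum event rates in \eqn{[0, 1]}.
#' @param pi True homozygote prevalence in (0, 1).
#' @param n_h_active,n_h_placebo,n_n_active,n_n_placebo Fixed arm sizes
#'   (all four required for fixed mode).
#' @param n_total Total randomized N for total-N mode (split evenly between
#'   active and placebo, then by `pi` into strata).
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(0.33, 0.04, 0.09, 0.01, pi = 0.15,
#'                n_h_active = 141, n_h_placebo = 133,
#'                n_n_active = 757, n_n_placebo = 764)
#' @export
synthetic_spec <- function(r_hA, r_hP, r_nA, r_nP, pi,
                           n_h_active = NULL, n_h_placebo = NULL,
                           n_n_active = NULL, n_n_placebo = NULL,
                           n_total = NULL) {
  for (nm in c("r_hA", "r_hP", "r_nA", "r_nP")) {
    v <- get(nm)
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < 0 || v > 1) {
      stop("true rate '", nm, "' missing or outside [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(pi) || pi <= 0 || pi >= 1) {
    stop("true pi must lie in (0, 1)", call. = FALSE)
  }
  fixed <- c(n_h_active, n_h_placebo, n_n_active, n_n_placebo)
  if (!is.null(n_total)) {
    if (length(fixed)) stop("give arm sizes or n_total, not both",
                            call. = FALSE)
    if (n_total < 4) stop("n_total must be at least 4", call. = FALSE)
    mode <- "total"
  } else {
    if (length(fixed) != 4L || any(fixed < 1)) {
      stop("fixed mode needs all four arm sizes >= 1", call. = FALSE)
    }
    mode <- "fixed"
  }
  structure(list(r_hA = r_hA, r_hP = r_hP, r_nA = r_nA, r_nP = r_nP,
                 pi = pi, mode = mode,
                 n_h_active = n_h_active, n_h_placebo = n_h_placebo,
                 n_n_active = n_n_active, n_n_placebo = n_n_placebo,
                 n_total = n_total),
            class = "synthetic_spec")
}

#' Read a synthetic-trial spec from a YAML config
#'
#' Same structured-config format as [read_trial_table()]'s YAML variant:
#' scalar keys named as in [synthetic_spec()].
#'
#' @param path Path to the YAML file.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("r_hA", "r_hP", "r_nA", "r_nP", "pi")) {
    if (is.null(y[[nm]])) {
      stop("spec file ", path, " is missing field '", nm, "'", call. = FALSE)
    }
  }
  allowed <- c("r_hA", "r_hP", "r_nA", "r_nP", "pi",
               "n_h_active", "n_h_placebo", "n_n_active", "n_n_placebo",
               "n_total")
  do.call(synthetic_spec, y[intersect(allowed, names(y))])
}

#' Generate one synthetic stratified trial table
#'
#' Draws event counts Binomially at the spec's true rates within each
#' stratum-by-arm cell. In total-N mode the stratum denominators are first
#' drawn Binomially at the true prevalence.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; reproducible when given.
#' @param drug,outcome Labels for the generated table.
#' @return A [strat_table()].
#' @examples
#' sp <- synthetic_spec(0.3, 0.05, 0.1, 0.01, pi = 0.15, n_total = 2000)
#' generate_trial(sp, seed = 7)
#' @export
generate_trial <- function(spec, seed = NULL, drug = "synthetic",
                           outcome = "synthetic") {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (spec$mode == "fixed") {
    n <- c(spec$n_h_active, spec$n_h_placebo, spec$n_n_active,
           spec$n_n_placebo)
  } else {
    half <- spec$n_total %/% 2
    n_h_act <- stats::rbinom(1, half, spec$pi)
    n_h_pla <- stats::rbinom(1, spec$n_total - half, spec$pi)
    n <- c(n_h_act, n_h_pla, half - n_h_act,
           (spec$n_total - half) - n_h_pla)
    n <- pmax(n, 1L)  # keep every arm non-empty at finite N
  }
  r <- c(spec$r_hA, spec$r_hP, spec$r_nA, spec$r_nP)
  ev <- stats::rbinom(4, n, r)
  strat_table(ev[1], n[1] - ev[1], ev[2], n[2] - ev[2],
              ev[3], n[3] - ev[3], ev[4], n[4] - ev[4],
              drug = drug, outcome = outcome)
}

#' Parameter-recovery experiment for the posterior NNT pipeline
#'
#' Repeatedly generates synthetic tables at known truth, runs the Jeffreys
#' Beta-Binomial pipeline on each, and records whether the true
#' \eqn{NNT = 1/(p\,\pi_{true}\,RD_{h,true})} falls inside the 95% credible
#' interval. Two independent seed streams are derived from `seed` — one for
#' table generation, one for posterior sampling — so a recovery failure can
#' be attributed to either stage.
#'
#' @param spec A [synthetic_spec()]; its true `RD_h` must be positive when a
#'   finite-NNT coverage check is requested.
#' @param n_replicates Number of synthetic trials (default 200).
#' @param n_draws Posterior draws per replicate (default 4000).
#' @param p Withholding probability at which NNT is evaluated.
#' @param seed Master seed for both streams.
#' @param pi_mode Prevalence mode passed to [sample_joint()].
#' @return A list of class `recovery_report`: `coverage` (fraction of
#'   replicates whose CrI contains the true NNT), `median_bias` (median over
#'   replicates of relative error of the posterior-median NNT),
#'   `true_nnt`, per-replicate `medians`/`covered`, the configuration, and a
#'   `status` field (`"ok"`, or `"skipped"` when `p = 0` makes the true NNT
#'   infinite).
#' @examples
#' sp <- synthetic_spec(0.33, 0.04, 0.09, 0.01, pi = 0.15,
#'                      n_h_active = 141, n_h_placebo = 133,
#'                      n_n_active = 757, n_n_placebo = 764)
#' recovery_experiment(sp, n_replicates = 20, n_draws = 500, seed = 1)
#' @export
recovery_experiment <- function(spec, n_replicates = 200, n_draws = 4000,
                                p = 1, seed = 1,
                                pi_mode = c("sampled", "fixed")) {
  pi_mode <- match.arg(pi_mode)
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  rd_true <- spec$r_hA - spec$r_hP
  cfg <- list(n_replicates = as.integer(n_replicates),
              n_draws = as.integer(n_draws), p = p, seed = seed,
              pi_mode = pi_mode, spec = spec)
  if (p == 0) {
    return(structure(c(list(status = "skipped",
                            reason = "p = 0: true NNT is infinite, no finite coverage target",
                            true_nnt = Inf, coverage = NA_real_,
                            median_bias = NA_real_), cfg),
                     class = "recovery_report"))
  }
  if (rd_true <= 0) {
    stop("true RD_h <= 0: the true NNT is undefined (no events averted); ",
         "choose r_hA > r_hP for a finite-NNT recovery target",
         call. = FALSE)
  }
  true_nnt <- 1 / (p * spec$pi * rd_true)

  # two derived streams: table generation vs posterior sampling
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  table_seeds <- sample.int(.Machine$integer.max, n_replicates)
  post_seeds  <- sample.int(.Machine$integer.max, n_replicates)

  covered <- logical(n_replicates)
  medians <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    tab <- generate_trial(spec, seed = table_seeds[i])
    draws <- sample_joint(tab, n_draws = n_draws, seed = post_seeds[i],
                          pi_mode = pi_mode)
    rd <- risk_differences(draws)
    s <- nnt_summary_from_arr(draws$pi * rd$RD_h, p)
    covered[i] <- s[["lower"]] <= true_nnt && true_nnt <= s[["upper"]]
    medians[i] <- s[["median"]]
  }
  structure(c(list(status = "ok", true_nnt = true_nnt,
                   coverage = mean(covered),
                   median_bias = stats::median(
                     (medians[is.finite(medians)] - true_nnt) / true_nnt),
                   covered = covered, medians = medians,
                   table_seeds = table_seeds, post_seeds = post_seeds),
              cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic-data recovery report\n")
  cat(sprintf("  status: %s | replicates: %d | draws/replicate: %d | p = %g\n",
              x$status, x$n_replicates, x$n_draws, x$p))
  if (identical(x$status, "ok")) {
    cat(sprintf("  true NNT %.3f | 95%% CrI coverage %.3f | median bias %+.3f\n",
                x$true_nnt, x$coverage, x$median_bias))
  } else {
    cat("  ", x$reason, "\n", sep = "")
  }
  invisible(x)
}
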