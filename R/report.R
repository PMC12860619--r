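#' Reporting front end
#'
#' `report_point()`, `report_sweep()` and `report_recovery()` tie the data,
#' sampling and policy modules together, print a human-readable summary, and
#' optionally write a machine-readable file (CSV or JSON). Every written
#' artifact embeds the full configuration — table cells, \eqn{\hat\pi},
#' prior parameters, draw counts, seeds, `k` — so it can be regenerated
#' exactly and any transcription error in the input cells is visible in one
#' place. Infinities are rendered as the locale-independent token `inf`.
#'
#' A thin command-line wrapper over these functions ships at
#' `system.file("cli", "ariannt.R", package = "ariannt")`; run it with
#' `Rscript` and `--help` for usage.
#'
#' @param table A [strat_table()] (e.g. from [builtin_table()] or
#'   [read_trial_table()]).
#' @param p Withholding probabilities to evaluate (point report) .
#' @param k Average additional MRI scans per event.
#' @param file Optional output path; format from `format`.
#' @param format `"csv"` or `"json"`.
#' @param quiet Suppress console output.
#' @return The underlying result object, invisibly.
#' @name reporting
NULL

.fmt_inf <- function(x, digits = 6) {
  ifelse(is.infinite(x), "inf", format(round(x, digits)))
}

.table_header_lines <- function(table) {
  rates <- point_rates(table)
  c(sprintf("# drug: %s", table$drug),
    sprintf("# outcome: %s", table$outcome),
    sprintf("# cells: A_h=%d B_h=%d C_h=%d D_h=%d A_n=%d B_n=%d C_n=%d D_n=%d",
            table$A_h, table$B_h, table$C_h, table$D_h,
            table$A_n, table$B_n, table$C_n, table$D_n),
    sprintf("# pi_hat: %.6f", rates$pi),
    sprintf("# beta_posteriors: r_hA~Beta(%.1f,%.1f) r_hP~Beta(%.1f,%.1f) r_nA~Beta(%.1f,%.1f) r_nP~Beta(%.1f,%.1f)",
            table$A_h + 0.5, table$B_h + 0.5, table$C_h + 0.5,
            table$D_h + 0.5, table$A_n + 0.5, table$B_n + 0.5,
            table$C_n + 0.5, table$D_n + 0.5))
}

#' @rdname reporting
#' @export
report_point <- function(table, p = c(0, 0.25, 0.5, 1), k = 1, file = NULL,
                         format = c("csv", "json"), quiet = FALSE) {
  format <- match.arg(format)
  res <- policy_point(table, p = p, k = k)
  if (!quiet) {
    writeLines(.table_header_lines(table))
    out <- res
    for (col in c("nnt", "nnt_mri")) out[[col]] <- .fmt_inf(out[[col]], 3)
    print(out, row.names = FALSE, digits = 5)
  }
  if (!is.null(file)) {
    if (format == "json") {
      payload <- list(config = list(drug = table$drug,
                                    outcome = table$outcome,
                                    cells = unclass(table)[1:8], k = k),
                      metrics = .jsonify_inf(res))
      jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
    } else {
      con <- file(file, "w")
      on.exit(close(con))
      writeLines(c(.table_header_lines(table), sprintf("# k: %g", k)), con)
      out <- res
      for (col in c("nnt", "nnt_mri")) out[[col]] <- .fmt_inf(out[[col]], 10)
      utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(res)
}

# JSON has no Inf literal; use the "inf" token
.jsonify_inf <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && any(is.infinite(df[[col]]))) {
      df[[col]] <- ifelse(is.infinite(df[[col]]), "inf",
                          as.character(df[[col]]))
    }
  }
  df
}

#' @rdname reporting
#' @param ... Passed on to [run_sweep()] (`p_grid`, `n_draws`, `seed`,
#'   `pi_mode`, ...).
#' @export
report_sweep <- function(table, k = 1, file = NULL, quiet = FALSE, ...) {
  sw <- run_sweep(table, k = k, ...)
  if (!quiet) {
    writeLines(.table_header_lines(table))
    print(sw)
  }
  if (!is.null(file)) write_sweep(sw, file)
  invisible(sw)
}

#' @rdname reporting
#' @param spec A [synthetic_spec()] for the recovery run.
#' @param n_replicates,n_draws,seed Recovery configuration, see
#'   [recovery_experiment()].
#' @export
report_recovery <- function(spec, n_replicates = 200, n_draws = 4000,
                            p = 1, seed = 1, file = NULL, quiet = FALSE) {
  rep <- recovery_experiment(spec, n_replicates = n_replicates,
                             n_draws = n_draws, p = p, seed = seed)
  if (!quiet) print(rep)
  if (!is.null(file)) {
    payload <- list(
      status = rep$status, coverage = rep$coverage,
      median_bias = rep$median_bias,
      true_nnt = if (is.infinite(rep$true_nnt)) "inf" else rep$true_nnt,
      config = list(n_replicates = rep$n_replicates, n_draws = rep$n_draws,
                    p = rep$p, seed = rep$seed, pi_mode = rep$pi_mode,
                    spec = unclass(rep$spec)))
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(rep)
}
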