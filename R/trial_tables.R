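#' Genotype-stratified trial contingency table
#'
#' Constructs a validated 2 (genotype stratum) x 2 (arm) x 2 (event status)
#' contingency table for one adverse-event outcome in one trial. The eight
#' cells follow the usual epidemiological layout: within the APOE
#' \eqn{\epsilon4/\epsilon4} ("e4e4") stratum, `A_h`/`B_h` are active-arm
#' patients with/without the event and `C_h`/`D_h` the placebo arm; `A_n` to
#' `D_n` are the analogous non-homozygote ("non-e4e4") cells.
#'
#' @param A_h,B_h,C_h,D_h Non-negative integer counts for the
#'   \eqn{\epsilon4/\epsilon4} stratum (active with/without event, placebo
#'   with/without event).
#' @param A_n,B_n,C_n,D_n Counts for the non-homozygote stratum, same layout.
#' @param drug Free-text drug label (e.g. `"lecanemab"`).
#' @param outcome Free-text outcome label (e.g. `"any-ARIA-E"`).
#'
#' @return An object of class `strat_table`: a list with the eight counts and
#'   the two labels.
#'
#' @details Every arm total (`A_h + B_h`, `C_h + D_h`, `A_n + B_n`,
#'   `C_n + D_n`) must be strictly positive: an empty arm makes the
#'   corresponding event rate undefined. Counts must be whole numbers; the
#'   aggregate-data model never needs fractional counts.
#'
#' @examples
#' strat_table(46, 95, 5, 128, 67, 690, 10, 754,
#'             drug = "lecanemab", outcome = "any-ARIA-E")
#' @seealso [builtin_tables()], [read_trial_table()], [pi_hat()]
#' @export
strat_table <- function(A_h, B_h, C_h, D_h, A_n, B_n, C_n, D_n,
                        drug = "", outcome = "") {
  counts <- c(A_h = A_h, B_h = B_h, C_h = C_h, D_h = D_h,
              A_n = A_n, B_n = B_n, C_n = C_n, D_n = D_n)
  tab <- structure(
    c(as.list(counts), list(drug = as.character(drug),
                            outcome = as.character(outcome))),
    class = "strat_table")
  validate_strat_table(tab)
}

#' Validate a stratified trial table
#'
#' Checks the `strat_table` invariants: eight non-negative integer counts and
#' four strictly positive arm totals. Called by all constructors and readers.
#'
#' @param x A putative `strat_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending cell or arm.
#' @export
validate_strat_table <- function(x) {
  cells <- c("A_h", "B_h", "C_h", "D_h", "A_n", "B_n", "C_n", "D_n")
  for (cell in cells) {
    v <- x[[cell]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("cell '", cell, "' is missing", call. = FALSE)
    }
    if (!is.numeric(v) || v < 0) {
      stop("cell '", cell, "' must be a non-negative count, got ", v,
           call. = FALSE)
    }
    if (abs(v - round(v)) > 1e-8) {
      stop("cell '", cell, "' must be an integer count, got ", v,
           call. = FALSE)
    }
    x[[cell]] <- as.integer(round(v))
  }
  arms <- list("e4e4/active"     = x$A_h + x$B_h,
               "e4e4/placebo"    = x$C_h + x$D_h,
               "non-e4e4/active" = x$A_n + x$B_n,
               "non-e4e4/placebo"= x$C_n + x$D_n)
  for (nm in names(arms)) {
    if (arms[[nm]] <= 0L) {
      stop("arm '", nm, "' is empty (total 0); every arm total must be > 0",
           call. = FALSE)
    }
  }
  x
}

#' @export
print.strat_table <- function(x, ...) {
  cat("Stratified trial table: ", x$drug,
      if (nzchar(x$outcome)) paste0(" / ", x$outcome), "\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat(sprintf("pi_hat (e4/e4 prevalence) = %.5f\n", pi_hat(x)))
  invisible(x)
}

#' @export
as.data.frame.strat_table <- function(x, ...) {
  data.frame(
    genotype   = c("e4e4", "e4e4", "non-e4e4", "non-e4e4"),
    arm        = c("active", "placebo", "active", "placebo"),
    events     = c(x$A_h, x$C_h, x$A_n, x$C_n),
    non_events = c(x$B_h, x$D_h, x$B_n, x$D_n),
    stringsAsFactors = FALSE)
}

# canonical cell name from (genotype, arm, column)
.cell_name <- function(genotype, arm, what) {
  stratum <- ifelse(genotype == "e4e4", "h", "n")
  letter <- if (what == "events") c(active = "A", placebo = "C")
            else                  c(active = "B", placebo = "D")
  paste0(letter[[arm]], "_", stratum)
}

#' Read a stratified trial table from a text file
#'
#' Accepts two plain-text formats. The delimited format is a CSV with header
#' `genotype,arm,events,non_events`, one row per stratum-by-arm cell pair
#' (`genotype` in `e4e4`/`non-e4e4`, `arm` in `active`/`placebo`), with the
#' drug and outcome labels carried on leading comment lines
#' `# drug: ...` / `# outcome: ...`. The structured-config alternative is a
#' YAML file with scalar keys `drug`, `outcome`, and the eight cells
#' `A_h` ... `D_n`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default; decided from the file extension, `.yml`/
#'   `.yaml` meaning YAML), `"delimited"`, or `"yaml"`.
#' @return A validated [strat_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trial_table(builtin_table("lecanemab", "any-ARIA-E"), f)
#' read_trial_table(f)
#' @export
read_trial_table <- function(path, format = c("auto", "delimited", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml"
              else "delimited"
  }
  if (format == "yaml") return(.read_table_yaml(path))
  .read_table_delim(path)
}

.read_table_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cells <- c("A_h", "B_h", "C_h", "D_h", "A_n", "B_n", "C_n", "D_n")
  missing <- setdiff(cells, names(y))
  if (length(missing)) {
    stop("missing cell(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(strat_table, c(y[cells],
                         list(drug = y$drug %||% "",
                              outcome = y$outcome %||% "")))
}

.read_table_delim <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  grab <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(m)) return("")
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("genotype", "arm", "events", "non_events")
  if (!all(need %in% names(df))) {
    stop("delimited table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- list()
  for (i in seq_len(nrow(df))) {
    g <- df$genotype[i]; a <- df$arm[i]
    if (!g %in% c("e4e4", "non-e4e4") || !a %in% c("active", "placebo")) {
      stop("unrecognised genotype/arm pair '", g, "'/'", a, "' in ", path,
           call. = FALSE)
    }
    counts[[.cell_name(g, a, "events")]]     <- df$events[i]
    counts[[.cell_name(g, a, "non_events")]] <- df$non_events[i]
  }
  cells <- c("A_h", "B_h", "C_h", "D_h", "A_n", "B_n", "C_n", "D_n")
  missing <- setdiff(cells, names(counts))
  if (length(missing)) {
    stop("missing cell(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(strat_table, c(counts[cells],
                         list(drug = grab("drug"), outcome = grab("outcome"))))
}

#' Write a stratified trial table to a text file
#'
#' Inverse of [read_trial_table()]: `read_trial_table(write_trial_table(t))`
#' reproduces `t` exactly.
#'
#' @param table A [strat_table()].
#' @param path Output path; `.yml`/`.yaml` extension selects the YAML format,
#'   anything else the delimited CSV format.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  table <- validate_strat_table(table)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cells <- c("A_h", "B_h", "C_h", "D_h", "A_n", "B_n", "C_n", "D_n")
    y <- c(list(drug = table$drug, outcome = table$outcome),
           lapply(table[cells], as.integer))
    yaml::write_yaml(y, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# drug: ", table$drug),
                 paste0("# outcome: ", table$outcome)), con)
    utils::write.csv(as.data.frame(table), con, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype-stratified ARIA counts as published for the two phase-3 trials.
.BUILTIN_COUNTS <- list(
  lecanemab = list(
    "any-ARIA-E"         = c(46, 95, 5, 128, 67, 690, 10, 754),
    "any-ARIA-H"         = c(55, 86, 28, 105, 100, 657, 53, 711),
    "symptomatic-ARIA-E" = c(13, 128, 0, 133, 12, 745, 0, 764)),
  donanemab = list(
    "any-ARIA-E"         = c(58, 85, 5, 141, 143, 564, 11, 713),
    "any-ARIA-H"         = c(72, 71, 30, 116, 194, 513, 85, 639)))

#' Built-in trial contingency tables
#'
#' The five genotype-stratified ARIA contingency tables published for the two
#' pivotal phase-3 anti-amyloid trials: lecanemab (any ARIA-E, any ARIA-H,
#' symptomatic ARIA-E) and donanemab (any ARIA-E, any ARIA-H). Symptomatic
#' ARIA-E counts by genotype were published only for lecanemab, so the
#' fixture set mirrors that asymmetry.
#'
#' @return A named list of five [strat_table()] objects; names are
#'   `"<drug>/<outcome>"`.
#' @examples
#' names(builtin_tables())
#' builtin_table("donanemab", "any-ARIA-H")
#' @export
builtin_tables <- function() {
  out <- list()
  for (drug in names(.BUILTIN_COUNTS)) {
    for (outcome in names(.BUILTIN_COUNTS[[drug]])) {
      cts <- .BUILTIN_COUNTS[[drug]][[outcome]]
      out[[paste0(drug, "/", outcome)]] <-
        strat_table(cts[1], cts[2], cts[3], cts[4],
                    cts[5], cts[6], cts[7], cts[8],
                    drug = drug, outcome = outcome)
    }
  }
  out
}

#' @rdname builtin_tables
#' @param drug,outcome Labels selecting one built-in table.
#' @export
builtin_table <- function(drug, outcome) {
  key <- paste0(drug, "/", outcome)
  tabs <- builtin_tables()
  if (!key %in% names(tabs)) {
    stop("no built-in table '", key, "'; available: ",
         paste(names(tabs), collapse = ", "), call. = FALSE)
  }
  tabs[[key]]
}

#' Observed prevalence of the e4/e4 stratum
#'
#' \eqn{\hat\pi}, the proportion of all randomized patients that fall in the
#' \eqn{\epsilon4/\epsilon4} stratum:
#' \eqn{\pi = (A_h + B_h + C_h + D_h) / N_{total}}. Because ARR is
#' proportional to \eqn{\pi}, an `override` is accepted for site-specific
#' recalibration when local homozygote prevalence differs from the trial.
#'
#' @param table A [strat_table()].
#' @param override Optional externally supplied prevalence in (0, 1);
#'   returned as-is after a range check.
#' @return A proportion in (0, 1).
#' @examples
#' pi_hat(builtin_table("lecanemab", "any-ARIA-E"))  # 274/1795
#' @export
pi_hat <- function(table, override = NULL) {
  if (!is.null(override)) {
    if (!is.numeric(override) || override <= 0 || override >= 1) {
      stop("override prevalence must lie in (0, 1)", call. = FALSE)
    }
    return(override)
  }
  table <- validate_strat_table(table)
  n_h <- table$A_h + table$B_h + table$C_h + table$D_h
  n_n <- table$A_n + table$B_n + table$C_n + table$D_n
  n_h / (n_h + n_n)
}

# stratum sizes (homozygote, non-homozygote); used by the pi posterior
.stratum_totals <- function(table) {
  c(n_h = table$A_h + table$B_h + table$C_h + table$D_h,
    n_n = table$A_n + table$B_n + table$C_n + table$D_n)
}
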