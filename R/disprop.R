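#' Build a 2x2 contingency table for a drug-event pair
#'
#' Counts reports (the unit is always the report, never the entry) into the
#' classic disproportionality table: `a` = reports with the drug of
#' interest and the event, `b` = drug without event, `c` = event without
#' drug, `d` = neither, within the comparator scope. The drug of interest's
#' reports are those listing it as suspected or interacting; comparator
#' reports are all remaining in-scope reports regardless of role. With
#' `scope = "opioids"` the comparator is restricted to reports containing a
#' drug with ATC code `N02A*` or `N01AH*`, by default excluding the index
#' drug's own entries.
#'
#' @param db an [icsr_db].
#' @param drug drug of interest.
#' @param event_terms character vector of preferred terms, or an
#'   [smq_definition] (its full term set defines event presence; a report
#'   carrying several terms still counts once).
#' @param scope `"full_database"` or `"opioids"`.
#' @param exclude_index_from_comparator drop the index drug when deciding
#'   opioid-comparator membership (default `TRUE`).
#' @return An object of class `contingency_table` with fields `a`, `b`,
#'   `c`, `d`, `scope`, `drug`, `event`.
#' @export
contingency_table <- function(db, drug, event_terms,
                              scope = c("full_database", "opioids"),
                              exclude_index_from_comparator = TRUE) {
  stopifnot(inherits(db, "icsr_db"))
  scope <- match.arg(scope)
  if (inherits(event_terms, "smq_definition")) {
    ev_name <- event_terms$name
    terms <- event_terms$terms
  } else {
    terms <- unique(canon(event_terms))
    ev_name <- paste(terms, collapse = "|")
  }
  .assert(length(terms) > 0, "event_terms must be non-empty")
  drug <- canon(drug)

  drug_ids  <- drug_report_ids(db, drug, c("suspected", "interacting"))
  event_ids <- unique(db$events$report_id[db$events$pt %in% terms])
  comp_ids <- if (scope == "full_database") {
    setdiff(db$reports$report_id, drug_ids)
  } else {
    setdiff(opioid_report_ids(
      db, if (exclude_index_from_comparator) drug else NULL), drug_ids)
  }

  a <- length(intersect(drug_ids, event_ids))
  b <- length(drug_ids) - a
  cc <- length(intersect(comp_ids, event_ids))
  d <- length(comp_ids) - cc

  new_contingency(a, b, cc, d, scope, drug, ev_name)
}

new_contingency <- function(a, b, c, d, scope = "full_database",
                            drug = "", event = "") {
  # doubles: cell products (e.g. Ndrug * Neffect) overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  .assert(a >= 0 && b >= 0 && c >= 0 && d >= 0,
          "contingency cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, scope = scope, drug = drug,
                 event = event),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table (%s scope) drug='%s' event='%s'\n",
              x$scope, x$drug, x$event))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "comparator"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Proportional reporting ratio
#'
#' `PRR = [A/(A+B)] / [C/(C+D)]` with a 95% Wald confidence interval on the
#' log scale, `SE = sqrt(1/A - 1/(A+B) + 1/C - 1/(C+D))`. The estimate is
#' reported as `NA` when `A = 0` or `C = 0` (no information on the ratio).
#'
#' @param t a `contingency_table`.
#' @return Named numeric vector `c(estimate, ci_low, ci_high)`.
#' @export
prr <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  .assert(t$a + t$b > 0, "PRR undefined: no reports for the drug")
  if (t$c == 0 || t$a == 0)
    return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  est <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  ci <- est * exp(c(-1, 1) * stats::qnorm(0.975) * se)
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Reporting odds ratio
#'
#' `ROR = (A/B) / (C/D)` with a 95% Wald confidence interval on the log
#' scale, `SE = sqrt(1/A + 1/B + 1/C + 1/D)`. When any cell is zero, 0.5 is
#' added to every cell for the interval (Haldane correction); the point
#' estimate is reported as `NA` when `A = 0` or `B*C*D = 0`.
#'
#' @param t a `contingency_table`.
#' @return Named numeric vector `c(estimate, ci_low, ci_high)`.
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  .assert(t$a + t$b > 0, "ROR undefined: no reports for the drug")
  cells <- as.numeric(c(t$a, t$b, t$c, t$d))
  est <- if (cells[1] == 0 || prod(cells[2:4]) == 0) NA_real_ else
    (t$a / t$b) / (t$c / t$d)
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  point_cc <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  se <- sqrt(sum(1 / cc))
  ci <- point_cc * exp(c(-1, 1) * stats::qnorm(0.975) * se)
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Bayesian information component
#'
#' `IC = log2((Nobserved + 0.5) / (Nexpected + 0.5))` with `Nobserved = A`,
#' `Nexpected = Ndrug * Neffect / Ntotal`, `Ndrug = A+B`, `Neffect = A+C`,
#' `Ntotal = A+B+C+D`. The `+0.5` offsets keep the IC finite for `A = 0`.
#' The lower 95% credibility bound `IC025` uses by default the closed-form
#' approximation `IC - 3.3*(A+0.5)^(-1/2) - 2.0*(A+0.5)^(-3/2)`; method
#' `"gamma"` instead takes the 2.5% quantile of the
#' `Gamma(A + 0.5, Nexpected + 0.5)` posterior on the observed-to-expected
#' ratio.
#'
#' @param t a `contingency_table`.
#' @param method `"approx"` (default) or `"gamma"`.
#' @return Named numeric vector `c(ic, ic025, n_expected)`.
#' @export
ic <- function(t, method = c("approx", "gamma")) {
  stopifnot(inherits(t, "contingency_table"))
  method <- match.arg(method)
  a <- t$a
  n_drug <- t$a + t$b
  n_effect <- t$a + t$c
  n_total <- t$a + t$b + t$c + t$d
  n_exp <- if (n_total > 0) n_drug * n_effect / n_total else 0
  ic_val <- log2((a + 0.5) / (n_exp + 0.5))
  ic025 <- if (method == "approx") {
    ic_val - 3.3 * (a + 0.5)^(-1 / 2) - 2.0 * (a + 0.5)^(-3 / 2)
  } else {
    log2(stats::qgamma(0.025, shape = a + 0.5, rate = n_exp + 0.5))
  }
  c(ic = ic_val, ic025 = ic025, n_expected = n_exp)
}

#' Composite signal criteria
#'
#' The conventional conjunction: at least `min_reports` co-reports, PRR and
#' ROR at least 2, and the lower IC credibility bound at least 0. All
#' criteria must hold; pairs with fewer than `min_reports` reports are
#' still listed but can never be signals.
#'
#' @param min_reports minimum observed count `A` (default 3).
#' @param prr_min PRR threshold (default 2).
#' @param ror_min ROR threshold (default 2).
#' @param ic025_min IC025 threshold (default 0).
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3, prr_min = 2, ror_min = 2,
                            ic025_min = 0) {
  .assert(min_reports >= 0 && prr_min >= 0 && ror_min >= 0,
          "criteria thresholds must be >= 0")
  structure(list(min_reports = min_reports, prr_min = prr_min,
                 ror_min = ror_min, ic025_min = ic025_min),
            class = "signal_criteria")
}

# assemble one result row from a table
disprop_row <- function(t, criteria, ic_method = "approx") {
  if (t$a + t$b == 0) {
    # drug absent from the database: reportable, never a signal
    i <- ic(t, ic_method)
    return(data.frame(term = t$event, scope = t$scope, a = 0L, b = 0L,
                      c = t$c, d = t$d, n_expected = i[["n_expected"]],
                      prr = NA_real_, prr_low = NA_real_,
                      prr_high = NA_real_, ror = NA_real_,
                      ror_low = NA_real_, ror_high = NA_real_,
                      ic = i[["ic"]], ic025 = i[["ic025"]], signal = FALSE,
                      stringsAsFactors = FALSE))
  }
  p <- prr(t); r <- ror(t); i <- ic(t, ic_method)
  sig <- isTRUE(t$a >= criteria$min_reports &&
                  !is.na(p[["estimate"]]) &&
                  p[["estimate"]] >= criteria$prr_min &&
                  !is.na(r[["estimate"]]) &&
                  r[["estimate"]] >= criteria$ror_min &&
                  i[["ic025"]] >= criteria$ic025_min)
  data.frame(term = t$event, scope = t$scope, a = t$a, b = t$b, c = t$c,
             d = t$d, n_expected = i[["n_expected"]],
             prr = p[["estimate"]], prr_low = p[["ci_low"]],
             prr_high = p[["ci_high"]], ror = r[["estimate"]],
             ror_low = r[["ci_low"]], ror_high = r[["ci_high"]],
             ic = i[["ic"]], ic025 = i[["ic025"]], signal = sig,
             stringsAsFactors = FALSE)
}

#' Screen a drug against a set of event terms
#'
#' Builds one contingency table per preferred term (and, when `terms` is an
#' SMQ, one pooled table over the whole term set with report-level
#' deduplication) and evaluates PRR, ROR, IC and the composite signal rule
#' for each.
#'
#' @param db an [icsr_db].
#' @param drug drug of interest.
#' @param terms character vector of preferred terms or an
#'   [smq_definition].
#' @param scope `"full_database"` or `"opioids"`.
#' @param criteria a [signal_criteria].
#' @param ic_method `"approx"` or `"gamma"` (see [ic()]).
#' @param pooled include the pooled SMQ-level row (default: `TRUE` when
#'   `terms` is an SMQ).
#' @return A data.frame of class `disprop_screen`, one row per term (the
#'   pooled SMQ row, if any, is flagged in column `pooled`).
#' @export
detect_signals <- function(db, drug, terms,
                           scope = c("full_database", "opioids"),
                           criteria = signal_criteria(),
                           ic_method = c("approx", "gamma"),
                           pooled = inherits(terms, "smq_definition")) {
  stopifnot(inherits(db, "icsr_db"), inherits(criteria, "signal_criteria"))
  scope <- match.arg(scope)
  ic_method <- match.arg(ic_method)
  is_smq <- inherits(terms, "smq_definition")
  term_vec <- if (is_smq) terms$terms else unique(canon(terms))

  rows <- lapply(term_vec, function(tt) {
    cbind(disprop_row(contingency_table(db, drug, tt, scope),
                      criteria, ic_method), pooled = FALSE)
  })
  if (is_smq && pooled) {
    rows <- c(rows, list(
      cbind(disprop_row(contingency_table(db, drug, terms, scope),
                        criteria, ic_method), pooled = TRUE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "drug") <- canon(drug)
  attr(out, "criteria") <- criteria
  class(out) <- c("disprop_screen", "data.frame")
  out
}

#' Age-stratified signal screen
#'
#' Runs [detect_signals()] on the sub-database of reports whose age group
#' falls in the stratum; reports with unknown age are excluded from every
#' stratum. An empty stratum yields an empty result with a warning.
#'
#' @param db an [icsr_db].
#' @param drug drug of interest.
#' @param terms preferred terms or an [smq_definition].
#' @param age_groups character subset of the age bands (e.g.
#'   `c("le11", "a12_17")` for under-18).
#' @param ... passed to [detect_signals()].
#' @return A `disprop_screen` (possibly with zero rows).
#' @export
stratified_signals <- function(db, drug, terms,
                               age_groups = c("le11", "a12_17"), ...) {
  stopifnot(inherits(db, "icsr_db"))
  age_groups <- setdiff(intersect(age_groups, .age_levels), "unknown")
  .assert(length(age_groups) > 0, "age_groups must name at least one band")
  ids <- db$reports$report_id[db$reports$age_group %in% age_groups]
  if (length(ids) == 0) {
    warning("age stratum is empty; returning no results")
    out <- detect_signals(db, drug, terms, ...)[0, , drop = FALSE]
    class(out) <- c("disprop_screen", "data.frame")
    return(out)
  }
  detect_signals(subset_db(db, ids), drug, terms, ...)
}

#' @export
print.disprop_screen <- function(x, digits = 2, ...) {
  cat(sprintf("Disproportionality screen for '%s' (%d terms, %d signals)\n",
              attr(x, "drug") %||% "?", nrow(x), sum(x$signal)))
  if (nrow(x) == 0) return(invisible(x))
  fmt_ci <- function(e, lo, hi) ifelse(
    is.na(e), "-", sprintf("%.2f (%.2f-%.2f)",
                           round_half_up(e, digits),
                           round_half_up(lo, digits),
                           round_half_up(hi, digits)))
  show <- data.frame(
    term = x$term, n = x$a,
    PRR = fmt_ci(x$prr, x$prr_low, x$prr_high),
    ROR = fmt_ci(x$ror, x$ror_low, x$ror_high),
    IC025 = round_half_up(x$ic025, ifelse(abs(x$ic025) < 1, 3, 2)),
    signal = ifelse(x$signal, "*", ""))
  print(show, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.disprop_screen <- function(object, ...) {
  structure(list(
    drug = attr(object, "drug"),
    n_terms = sum(!object$pooled),
    signals = object$term[object$signal & !object$pooled],
    total_signal_reports = sum(object$a[object$signal & !object$pooled])),
    class = "summary.disprop_screen")
}

#' @export
print.summary.disprop_screen <- function(x, ...) {
  cat(sprintf("'%s': %d/%d terms are signals (%d reports in signal terms)\n",
              x$drug, length(x$signals), x$n_terms,
              x$total_signal_reports))
  if (length(x$signals))
    cat("  signals:", paste(x$signals, collapse = ", "), "\n")
  invisible(x)
}
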