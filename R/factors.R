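#' Cross-tabulate SMQ case status against a candidate factor
#'
#' Restricts the database to the index drug's suspect/interacting reports,
#' splits them into SMQ cases and non-cases, and cross-tabulates against a
#' factor. Demographic factors drop reports with an unknown category (the
#' dropped count is kept in `excluded_unknown`); derived factors (death,
#' abuse, concomitant drug-class use) are defined for every report. The
#' `"age"` factor collapses the reporting age bands to the three analysis
#' strata (<=17, 18-64, >=65). The Pearson chi-square test (no continuity
#' correction) and, for factors with at least three categories, post hoc
#' adjusted standardized residuals are computed on construction.
#'
#' @param db an [icsr_db].
#' @param index_drug the analysed drug.
#' @param smq the case-defining [smq_definition].
#' @param factor one of `"sex"`, `"age"`, `"region"`, `"reporter"`,
#'   `"death"`; or a [drug_class] (concomitant-user factor); or an
#'   [smq_definition] (event-defined flag such as drug abuse).
#' @param alpha significance level for the post hoc flags (default 0.05,
#'   Bonferroni-adjusted over categories).
#' @return An object of class `factor_table`: `factor_name`, `categories`,
#'   `counts` (2 x k matrix, rows `case`/`noncase`), `excluded_unknown`,
#'   `chi2`, `df`, `p_value`, `posthoc`.
#' @export
build_factor_table <- function(db, index_drug, smq, factor, alpha = 0.05) {
  stopifnot(inherits(db, "icsr_db"), inherits(smq, "smq_definition"))
  sub <- filter_reports(db, index_drug, c("suspected", "interacting"))
  case <- is_case(sub, smq)

  if (inherits(factor, "drug_class")) {
    fname <- paste0(factor$class_name, "_user")
    val <- ifelse(is_class_user(sub, factor, index_drug), "user", "non_user")
    lv <- c("user", "non_user")
  } else if (inherits(factor, "smq_definition")) {
    fname <- factor$name
    val <- ifelse(is_case(sub, factor), "flagged", "not_flagged")
    lv <- c("flagged", "not_flagged")
  } else {
    fname <- match.arg(factor, c("sex", "age", "region", "reporter",
                                 "death"))
    val <- switch(fname,
      sex = sub$reports$sex,
      age = c(le11 = "le17", a12_17 = "le17", a18_44 = "a18_64",
              a45_64 = "a18_64", a65_74 = "ge65", ge75 = "ge65",
              unknown = "unknown")[sub$reports$age_group],
      region = sub$reports$region,
      reporter = sub$reports$reporter,
      death = ifelse(sub$reports$death, "death", "survival"))
    lv <- switch(fname,
      sex = c("male", "female"),
      age = c("le17", "a18_64", "ge65"),
      region = setdiff(.region_levels, "unknown"),
      reporter = setdiff(.reporter_levels, "unknown"),
      death = c("death", "survival"))
  }

  keep <- val %in% lv
  excluded <- sum(!keep)
  counts <- rbind(
    case = table(factor(val[keep & case], levels = lv)),
    noncase = table(factor(val[keep & !case], levels = lv)))
  nonempty <- colSums(counts) > 0
  .assert(sum(nonempty) >= 2,
          "degenerate table: factor '%s' has fewer than 2 non-empty categories",
          fname)
  counts <- counts[, nonempty, drop = FALSE]

  ft <- structure(list(
    factor_name = fname, categories = colnames(counts), counts = counts,
    excluded_unknown = excluded, chi2 = NA_real_, df = NA_integer_,
    p_value = NA_real_, posthoc = NULL), class = "factor_table")
  ct <- chi_square(ft)
  ft$chi2 <- ct[["chi2"]]; ft$df <- as.integer(ct[["df"]])
  ft$p_value <- ct[["p_value"]]
  ft$posthoc <- posthoc(ft, alpha = alpha)
  ft
}

#' Build a factor table directly from a 2 x k count matrix
#'
#' Useful for analysing published cross-tabulations where only the counts
#' are available (row 1 = cases, row 2 = non-cases).
#'
#' @param counts 2 x k matrix of counts.
#' @param factor_name label for the factor.
#' @param alpha post hoc significance level.
#' @return A `factor_table`.
#' @export
factor_table_from_counts <- function(counts, factor_name = "factor",
                                     alpha = 0.05) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == 2, "counts must have 2 rows (case / noncase)")
  rownames(counts) <- c("case", "noncase")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cat", seq_len(ncol(counts)))
  ft <- structure(list(
    factor_name = factor_name, categories = colnames(counts),
    counts = counts, excluded_unknown = 0L, chi2 = NA_real_,
    df = NA_integer_, p_value = NA_real_, posthoc = NULL),
    class = "factor_table")
  ct <- chi_square(ft)
  ft$chi2 <- ct[["chi2"]]; ft$df <- as.integer(ct[["df"]])
  ft$p_value <- ct[["p_value"]]
  ft$posthoc <- posthoc(ft, alpha = alpha)
  ft
}

#' Pearson chi-square test of a factor table
#'
#' Plain Pearson chi-square without continuity correction, expected counts
#' from the row/column margins. Errors on a zero margin or a zero expected
#' cell.
#'
#' @param t a `factor_table` (or a 2 x k matrix).
#' @return Named vector `c(chi2, df, p_value)`.
#' @export
chi_square <- function(t) {
  m <- if (inherits(t, "factor_table")) t$counts else as.matrix(t)
  .assert(all(rowSums(m) > 0) && all(colSums(m) > 0),
          "degenerate table: zero row or column margin")
  exp_c <- outer(rowSums(m), colSums(m)) / sum(m)
  .assert(all(exp_c > 0), "degenerate table: zero expected cell")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  c(chi2 = unname(res$statistic), df = unname(res$parameter),
    p_value = unname(res$p.value))
}

#' Post hoc residual diagnostics for a factor table
#'
#' Adjusted standardized Pearson residuals per category,
#' `r = (O - E) / sqrt(E (1 - rowsum/n) (1 - colsum/n))`, tested two-sided
#' against a Bonferroni-corrected critical value `z = qnorm(1 - alpha/(2k))`
#' for `k` categories. Applied when the factor has at least three
#' categories; for two-level factors the chi-square itself already
#' localizes the effect, so a not-applicable marker (`NULL`) is returned.
#'
#' The residual reported per category is the one of the case row; the
#' non-case row residual is its negative in a 2 x k table.
#'
#' @param t a `factor_table`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame `category`, `residual`, `significant`, `direction`
#'   (`"over"`/`"under"`-represented among cases), or `NULL` when k < 3.
#' @export
posthoc <- function(t, alpha = 0.05) {
  m <- if (inherits(t, "factor_table")) t$counts else as.matrix(t)
  k <- ncol(m)
  if (k < 3) return(NULL)
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  exp_c <- outer(rs, cs) / n
  adj <- (m - exp_c) / sqrt(exp_c * outer(1 - rs / n, 1 - cs / n))
  r <- adj[1, ]
  crit <- stats::qnorm(1 - alpha / (2 * k))
  data.frame(category = colnames(m), residual = unname(r),
             significant = unname(abs(r) > crit),
             direction = ifelse(r > 0, "over", "under"),
             stringsAsFactors = FALSE)
}

#' Summarize a factor table as proportions and ratios
#'
#' Per-category proportions among cases and non-cases (using the case and
#' non-case totals as denominators), the case/non-case proportion ratio,
#' and for two-level factors the odds ratio with a 95% Wald log-scale
#' confidence interval.
#'
#' @param t a `factor_table`.
#' @return A data.frame of class `factor_summary`: `category`, `n_case`,
#'   `n_noncase`, `prop_case`, `prop_noncase`, `proportion_ratio`, and (for
#'   2-level factors, on the first category) `odds_ratio`, `or_low`,
#'   `or_high`.
#' @export
summarize_factor <- function(t) {
  stopifnot(inherits(t, "factor_table"))
  m <- t$counts
  tot <- rowSums(m)
  pc <- m[1, ] / tot[1]
  pn <- m[2, ] / tot[2]
  ratio <- ifelse(pn > 0, pc / pn, NA_real_)
  out <- data.frame(category = colnames(m), n_case = unname(m[1, ]),
                    n_noncase = unname(m[2, ]), prop_case = unname(pc),
                    prop_noncase = unname(pn),
                    proportion_ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  if (ncol(m) == 2) {
    or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    if (!is.finite(or)) or <- NA_real_
    se <- sqrt(sum(1 / pmax(m, 0.5)))
    out$odds_ratio <- c(or, NA_real_)
    out$or_low <- c(or * exp(-stats::qnorm(0.975) * se), NA_real_)
    out$or_high <- c(or * exp(stats::qnorm(0.975) * se), NA_real_)
  }
  class(out) <- c("factor_summary", "data.frame")
  out
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("Factor '%s' vs case status (chi2 = %.3f, df = %d, p %s)\n",
              x$factor_name, x$chi2, x$df,
              if (x$p_value < 1e-4) "< 0.0001" else
                sprintf("= %.4f", round_half_up(x$p_value, 4))))
  if (x$excluded_unknown > 0)
    cat(sprintf("  (%d reports with unknown category excluded)\n",
                x$excluded_unknown))
  s <- summarize_factor(x)
  disp <- data.frame(
    category = s$category,
    cases = sprintf("%d (%.1f%%)", s$n_case,
                    round_half_up(100 * s$prop_case, 1)),
    noncases = sprintf("%d (%.1f%%)", s$n_noncase,
                       round_half_up(100 * s$prop_noncase, 1)))
  if (!is.null(x$posthoc))
    disp$posthoc <- ifelse(x$posthoc$significant,
                           paste0(x$posthoc$direction, "*"), "")
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}
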