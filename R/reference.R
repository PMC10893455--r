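#' Published reference tables for the tramadol respiratory-depression study
#'
#' Summary counts as printed in a published global pharmacovigilance
#' analysis of tramadol-related acute central respiratory depression (ACRD)
#' on the WHO global ICSR database (23,811,236 reports through January
#' 2021; 140,721 tramadol and 51,401 tramadol/paracetamol suspect or
#' interacting reports). The underlying report-level data are
#' access-restricted, so these printed margins are the inputs for
#' reconstruction-based consistency checks: the comparator cell of each
#' 2x2 table can be back-solved from the printed report count and PRR via
#' [reconstruct_contingency()].
#'
#' @return `reference_totals()`: named list of the database and drug report
#'   totals.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_totals <- function() {
  list(n_total = 23811236,
       n_tramadol = 140721,
       n_combo = 51401,
       n_acrd_tramadol = 1126,
       n_acrd_combo = 108)
}

#' @rdname reference_tables
#' @return `reference_demographics()`: data.frame `section`, `stratum`,
#'   `tramadol_all`, `tramadol_acrd`, `combo_all`, `combo_acrd` (printed
#'   counts; the reporter counts for all tramadol reports are internally
#'   inconsistent in the source and are stored verbatim).
#' @export
reference_demographics <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
section stratum tramadol_all tramadol_acrd combo_all combo_acrd
sex male 50077 438 15571 44
sex female 85677 589 34781 60
sex unknown 4967 99 1049 4
age le11 1172 67 142 0
age a12_17 2650 44 464 5
age a18_44 38203 350 8734 27
age a45_64 45481 274 18596 22
age a65_74 19300 96 10071 18
age ge75 16896 117 9069 20
age unknown 17019 178 4325 16
reporter consumer 17818 113 11483 9
reporter physician 37733 498 10458 64
reporter other_hcp 44831 232 16375 15
reporter pharmacist 15237 160 11794 16
reporter lawyer 721 13 15 0
reporter unknown 14381 110 1276 4
serious serious 25562 938 5047 94
region americas 25061 567 1319 34
region europe 25994 437 7018 42
region asia 86202 86 42846 31
region oceania 2363 31 6 0
region africa 1101 5 212 1
year le2013 35328 502 7515 36
year 2014 12671 127 4640 22
year 2015 13902 79 5437 7
year 2016 11554 70 3517 14
year 2017 15894 56 7925 9
year 2018 15590 105 7310 8
year 2019 15615 89 6594 8
year ge2020 20167 98 8463 4
")
  df
}

#' @rdname reference_tables
#' @param drug `"tramadol"` or `"tramadol/paracetamol"`.
#' @return `reference_disprop()`: data.frame of the printed full-database
#'   disproportionality results per preferred term: `term`, `n` (reports
#'   with the drug and term), `prr`, `prr_low`, `prr_high`, `ror`,
#'   `ror_low`, `ror_high`, `ic025`. Terms with zero reports for the drug
#'   are omitted (printed as dashes in the source).
#' @export
reference_disprop <- function(drug = c("tramadol", "tramadol/paracetamol")) {
  drug <- match.arg(drug)
  if (drug == "tramadol") {
    utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
term n prr prr_low prr_high ror ror_low ror_high ic025
'respiratory arrest' 358 2.91 2.62 3.23 2.92 2.63 3.24 1.37
'respiratory depression' 357 5.52 4.97 6.13 5.53 4.98 6.15 2.26
'respiratory failure' 129 0.56 0.47 0.67 0.56 0.47 0.67 -1.08
'bradypnoea' 73 8.93 7.06 11.3 8.93 7.06 11.3 2.67
'apnoea' 69 0.62 0.49 0.78 0.62 0.49 0.78 -1.05
'hypoventilation' 60 2.19 1.70 2.83 2.19 1.70 2.83 0.72
'respiratory rate decreased' 34 2.22 1.58 3.11 2.22 1.58 3.11 0.59
'acute respiratory failure' 33 0.68 0.48 0.96 0.68 0.48 0.96 -1.08
'hypopnoea' 29 1.91 1.32 2.75 1.91 1.32 2.75 0.33
'acute respiratory distress syndrome' 24 0.47 0.31 0.70 0.47 0.31 0.70 -1.70
'apnoeic attack' 6 1.74 0.78 3.88 1.74 0.78 3.88 -0.66
'breath holding' 6 1.18 0.53 2.63 1.18 0.53 2.63 -1.16
'infantile apnoea' 6 1.15 0.51 2.56 1.15 0.51 2.56 -1.20
'breath sounds abnormal' 5 0.28 0.16 0.67 0.28 0.16 0.67 -3.27
'neonatal respiratory depression' 4 1.86 0.70 4.99 1.86 0.70 4.99 -0.98
'apparent life threatening event' 2 0.50 0.13 2.01 0.50 0.13 2.01 -3.43
'neonatal respiratory arrest' 1 1.77 0.25 12.7 1.77 0.25 12.7 -3.31
'respiratory depth decreased' 1 2.37 0.33 17.1 2.37 0.33 17.1 -3.10
'respiratory paralysis' 1 1.09 0.15 7.80 1.09 0.15 7.80 -3.71
")
  } else {
    utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
term n prr prr_low prr_high ror ror_low ror_high ic025
'respiratory arrest' 13 0.29 0.17 0.49 0.29 0.17 0.49 -2.66
'respiratory depression' 35 1.44 1.04 2.01 1.45 1.04 2.01 0.003
'respiratory failure' 20 0.24 0.15 0.37 0.24 0.15 0.37 -2.73
'bradypnoea' 10 3.21 1.73 5.99 3.21 1.73 5.99 0.50
'apnoea' 6 0.15 0.04 0.33 0.15 0.04 0.33 -4.04
'hypoventilation' 4 0.40 0.15 1.06 0.40 0.15 1.06 -2.97
'respiratory rate decreased' 7 1.24 0.59 2.61 1.24 0.59 2.61 -0.97
'acute respiratory failure' 7 0.39 0.19 0.83 0.39 0.19 0.83 -2.54
'hypopnoea' 4 0.72 0.27 1.91 0.72 0.27 1.91 -2.17
'acute respiratory distress syndrome' 3 0.16 0.05 0.50 0.16 0.05 0.50 -4.50
'breath holding' 1 0.54 0.08 3.81 0.54 0.08 3.81 -4.45
'breath sounds abnormal' 2 0.30 0.08 1.22 0.30 0.08 1.22 -4.08
")
  }
}

#' @rdname reference_tables
#' @return `reference_factors()`: data.frame of the printed factor
#'   cross-tabulation for tramadol: `factor`, `category`, `acrd`,
#'   `non_acrd` (counts after exclusion of unknown sex/age/reporter) and
#'   the printed percentages `pct_acrd`, `pct_non_acrd`. The printed
#'   non-case reporter percentages use the unexcluded total (139,595) as
#'   denominator while the case column uses the after-exclusion total, an
#'   inconsistency of the source preserved verbatim here.
#' @export
reference_factors <- function() {
  utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
factor category acrd non_acrd pct_acrd pct_non_acrd
sex male 438 49639 42.7 36.8
sex female 589 85088 57.4 63.2
age le17 111 3711 11.7 3.0
age a18_64 624 83060 65.8 67.7
age ge65 213 35983 22.5 29.3
region americas 567 24494 50.4 17.6
region europe 437 25557 38.8 18.3
region asia 86 86116 7.6 61.7
region oceania 31 2332 2.8 1.7
region africa 5 1096 0.4 0.8
reporter physician 498 36337 49.0 26.0
reporter pharmacist 160 14414 15.8 10.3
reporter other_hcp 232 31545 22.8 22.6
reporter consumer 113 42305 11.1 30.3
reporter lawyer 13 708 1.3 0.5
cyp2d6_inhibitors user 136 5063 12.1 3.6
cyp2d6_inhibitors non_user 990 134532 87.9 96.4
opioids user 350 9340 31.1 6.7
opioids non_user 776 130255 68.9 93.3
benzodiazepines user 223 3919 19.8 2.8
benzodiazepines non_user 903 135676 80.2 97.2
antidepressants user 226 6403 20.1 4.6
antidepressants non_user 900 133192 79.9 95.4
drug_abuse flagged 142 3248 12.6 2.3
drug_abuse not_flagged 984 136347 87.4 97.7
lethality death 233 3377 20.7 2.4
lethality survival 893 136218 79.3 97.6
")
}

#' Reconstruct a 2x2 table from printed margins
#'
#' Back-solves the comparator cell `C` from a printed report count and PRR
#' given the drug and database totals:
#' `C = round(A / Ndrug * (Ntotal - Ndrug) / PRR)`, with `B = Ndrug - A`
#' and `D = Ntotal - Ndrug - C`. This lets the full statistics (PRR, ROR,
#' IC and bounds, signal verdict) be recomputed from a published summary
#' table when the report-level database is not available.
#'
#' @param n printed report count `A` (> 0).
#' @param prr printed PRR (> 0).
#' @param n_drug total reports for the drug.
#' @param n_total total reports in the database.
#' @param drug,event labels carried on the table.
#' @return A `contingency_table`.
#' @export
reconstruct_contingency <- function(n, prr, n_drug, n_total,
                                    drug = "", event = "") {
  .assert(n > 0 && prr > 0, "need a positive report count and PRR")
  .assert(n_drug >= n && n_total > n_drug, "inconsistent totals")
  cc <- round(n / n_drug * (n_total - n_drug) / prr)
  new_contingency(n, n_drug - n, cc, n_total - n_drug - cc,
                  scope = "full_database", drug = drug, event = event)
}

#' Recompute a published disproportionality screen by reconstruction
#'
#' Applies [reconstruct_contingency()] to every printed term of
#' [reference_disprop()] and re-runs the full statistics and composite
#' signal rule on the reconstructed tables.
#'
#' @inheritParams reference_disprop
#' @param criteria a [signal_criteria].
#' @return A `disprop_screen` with one row per printed term.
#' @export
reconstruct_reference_screen <- function(drug = c("tramadol",
                                                  "tramadol/paracetamol"),
                                         criteria = signal_criteria()) {
  drug <- match.arg(drug)
  ref <- reference_disprop(drug)
  tot <- reference_totals()
  n_drug <- if (drug == "tramadol") tot$n_tramadol else tot$n_combo
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    t <- reconstruct_contingency(ref$n[i], ref$prr[i], n_drug, tot$n_total,
                                 drug = drug, event = ref$term[i])
    cbind(disprop_row(t, criteria), pooled = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "drug") <- drug
  attr(out, "criteria") <- criteria
  class(out) <- c("disprop_screen", "data.frame")
  out
}
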