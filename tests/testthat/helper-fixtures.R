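# Fixtures built in code and brute-force oracles used across test files.

# a small hand-written database: 6 reports covering the corner cases
toy_db <- function() {
  reports <- data.frame(
    report_id = sprintf("t%02d", 1:6),
    sex = c("male", "female", "female", "unknown", "male", "female"),
    age_group = c("le11", "a12_17", "a18_44", "a45_64", "ge75", "unknown"),
    region = c("americas", "europe", "asia", "asia", "europe", "oceania"),
    reporter = c("physician", "consumer", "physician", "other_hcp",
                 "pharmacist", "unknown"),
    year = c(2013L, 2016L, 2018L, NA, 2020L, 2021L),
    serious = c("true", "true", "false", "unknown", "true", "false"),
    death = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    report_id = c("t01", "t01", "t02", "t03", "t04", "t04", "t05", "t06"),
    drug_name = c("tramadol", "diazepam", "tramadol", "tramadol",
                  "morphine", "tramadol", "ibuprofen", "Tramadol"),
    atc_code = c("N02AX02", "N05BA01", "N02AX02", "N02AX02", "N02AA01",
                 "N02AX02", "M01AE01", "N02AX02"),
    role = c("suspected", "concomitant", "suspected", "interacting",
             "suspected", "concomitant", "suspected", "suspected"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    report_id = c("t01", "t01", "t02", "t03", "t04", "t05", "t06"),
    pt = c("Respiratory arrest", "bradypnoea", "respiratory depression",
           "nausea", "respiratory depression", "nausea", "dizziness"),
    stringsAsFactors = FALSE)
  icsr_db(reports, drugs, events)
}

# small generator configuration for oracle / calibration tests; a common
# filler drug and event emulate the bulk of a reporting database and keep
# the >=1-drug / >=1-event fallbacks rare
test_config <- function(n_reports, seed, n_drugs = 6, n_events = 8,
                        p_drug = 0.08, p_event = 0.03,
                        signal_injections = NULL, co_medication = NULL) {
  drug_catalog <- data.frame(
    drug_name = c(paste0("drug", seq_len(n_drugs)), "fillerdrug"),
    atc_code = c(c("N02AX02", "N02AA01", "N05BA01", "M01AE01", "N01AH01",
                   "A02BC01", "N06AB06", "N02AB03")[seq_len(n_drugs)], ""),
    prob = c(rep(p_drug, n_drugs), 0.95), stringsAsFactors = FALSE)
  event_catalog <- data.frame(
    pt = paste0("event", seq_len(n_events)),
    prob = rep(p_event, n_events), stringsAsFactors = FALSE)
  event_catalog$prob[1] <- 0.97
  generator_config(
    n_reports = n_reports, seed = seed, drug_catalog = drug_catalog,
    event_catalog = event_catalog, signal_injections = signal_injections,
    co_medication = co_medication)
}

# brute-force per-report 2x2 counter (independent of contingency_table)
brute_cells <- function(db, drug, terms, scope = "full_database",
                        exclude_index = TRUE) {
  drug <- tolower(drug); terms <- tolower(terms)
  drugs_by <- split(db$drugs[c("drug_name", "role", "atc_code")],
                    db$drugs$report_id)
  events_by <- split(db$events$pt, db$events$report_id)
  a <- b <- cc <- d <- 0
  for (id in db$reports$report_id) {
    dd <- drugs_by[[id]]
    ee <- events_by[[id]]
    has_drug <- any(dd$drug_name == drug &
                      dd$role %in% c("suspected", "interacting"))
    has_event <- any(ee %in% terms)
    if (has_drug) {
      if (has_event) a <- a + 1 else b <- b + 1
    } else {
      in_comp <- if (scope == "full_database") TRUE else {
        opi <- startsWith(dd$atc_code, "N02A") |
          startsWith(dd$atc_code, "N01AH")
        if (exclude_index) opi <- opi & dd$drug_name != drug
        any(opi)
      }
      if (in_comp) {
        if (has_event) cc <- cc + 1 else d <- d + 1
      }
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# brute-force SMQ case count (per-report loop)
brute_smq_cases <- function(db, smq) {
  events_by <- split(db$events$pt, db$events$report_id)
  sum(vapply(db$reports$report_id,
             function(id) any(events_by[[id]] %in% smq$terms), logical(1)))
}

# brute-force Pearson chi-square
brute_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
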