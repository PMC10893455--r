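#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a generative model for a spontaneous-reporting database:
#' reports are drawn independently; each drug has a marginal exposure
#' probability; each preferred term has a marginal reporting probability
#' which, on reports carrying an injected drug, is multiplied by the
#' configured relative risk (capped at 1). Demographics are sampled from
#' categorical marginals independently of drugs unless a conditional boost
#' is supplied. Death is generated from a multiplicative odds model tied to
#' the preferred terms present on the report, so downstream lethality
#' analyses have a recoverable association.
#'
#' @param n_reports number of reports to draw (>= 1).
#' @param seed integer seed; generation is a pure function of the config
#'   including this seed.
#' @param drug_catalog data.frame `drug_name`, `atc_code`, `prob` (marginal
#'   exposure probability per report).
#' @param event_catalog data.frame `pt`, `prob` (marginal probability).
#' @param signal_injections data.frame `drug_name`, `pt`, `rr` (relative
#'   risk >= 0) or `NULL`.
#' @param demographic_marginals named list with elements `sex`, `age_group`,
#'   `region`, `reporter`, `year`, `serious`; each a named probability
#'   vector summing to 1 (year names are calendar years or `"NA"`).
#' @param co_medication data.frame `index_drug`, `co_drug`, `prob`: extra
#'   probability of `co_drug` on reports carrying `index_drug` (combined
#'   with the marginal draw by union), or `NULL`.
#' @param death_model list `baseline` (probability) and `pt_multipliers`
#'   (named odds multipliers per preferred term); death forces
#'   `serious = "true"`.
#' @param role_probabilities named list of probability vectors over
#'   `c(suspected, interacting, concomitant)`; element `default` plus
#'   optional per-drug overrides.
#' @param conditional_event_boost optional list `age_groups`, `drug_name`,
#'   `pts`, `multiplier`: multiplies the probabilities of `pts` on reports
#'   in the given age groups that carry `drug_name` (used for paediatric
#'   enrichment of respiratory-depression terms).
#' @return An object of class `generator_config`.
#' @seealso [generate_reports()], [tramadol_study_preset()]
#' @export
generator_config <- function(n_reports, seed, drug_catalog, event_catalog,
                             signal_injections = NULL,
                             demographic_marginals = default_marginals(),
                             co_medication = NULL,
                             death_model = list(baseline = 0.01,
                                                pt_multipliers = c()),
                             role_probabilities = list(
                               default = c(suspected = 0.6,
                                           interacting = 0.05,
                                           concomitant = 0.35)),
                             conditional_event_boost = NULL) {
  cfg <- structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drug_catalog = as.data.frame(drug_catalog, stringsAsFactors = FALSE),
    event_catalog = as.data.frame(event_catalog, stringsAsFactors = FALSE),
    signal_injections = if (!is.null(signal_injections))
      as.data.frame(signal_injections, stringsAsFactors = FALSE),
    demographic_marginals = demographic_marginals,
    co_medication = if (!is.null(co_medication))
      as.data.frame(co_medication, stringsAsFactors = FALSE),
    death_model = death_model,
    role_probabilities = role_probabilities,
    conditional_event_boost = conditional_event_boost
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks all model invariants (probabilities in `[0,1]`, categorical
#' marginals summing to 1 within 1e-9, relative risks >= 0, `n_reports >=
#' 1`) and errors before any sampling when one fails.
#'
#' @param cfg a [generator_config].
#' @return Invisibly `TRUE`.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  .assert(length(cfg$n_reports) == 1 && !is.na(cfg$n_reports) &&
            cfg$n_reports >= 1, "n_reports must be >= 1")
  .assert(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be set")
  dc <- cfg$drug_catalog
  .assert(nrow(dc) > 0 &&
            all(c("drug_name", "atc_code", "prob") %in% names(dc)),
          "drug_catalog needs columns drug_name, atc_code, prob")
  .assert(all(dc$prob >= 0 & dc$prob <= 1), "drug probabilities in [0,1]")
  .assert(!anyDuplicated(canon(dc$drug_name)), "duplicate drug in catalog")
  ec <- cfg$event_catalog
  .assert(nrow(ec) > 0 && all(c("pt", "prob") %in% names(ec)),
          "event_catalog needs columns pt, prob")
  .assert(all(ec$prob >= 0 & ec$prob <= 1), "event probabilities in [0,1]")
  .assert(!anyDuplicated(canon(ec$pt)), "duplicate preferred term in catalog")
  if (!is.null(cfg$signal_injections)) {
    si <- cfg$signal_injections
    .assert(all(c("drug_name", "pt", "rr") %in% names(si)),
            "signal_injections needs drug_name, pt, rr")
    .assert(all(si$rr >= 0), "relative risks must be >= 0")
    .assert(all(canon(si$drug_name) %in% canon(dc$drug_name)),
            "injected drug not in catalog")
    .assert(all(canon(si$pt) %in% canon(ec$pt)),
            "injected preferred term not in catalog")
  }
  dm <- cfg$demographic_marginals
  .assert(all(c("sex", "age_group", "region", "reporter", "year",
                "serious") %in% names(dm)),
          "demographic_marginals must cover sex, age_group, region, reporter, year, serious")
  for (f in names(dm)) {
    p <- dm[[f]]
    .assert(!is.null(names(p)) && all(p >= 0),
            "marginal '%s' must be a named non-negative vector", f)
    .assert(abs(sum(p) - 1) < 1e-9, "marginal '%s' must sum to 1", f)
    lv <- switch(f, sex = .sex_levels, age_group = .age_levels,
                 region = .region_levels, reporter = .reporter_levels,
                 serious = .serious_levels, year = NULL)
    if (!is.null(lv))
      .assert(all(names(p) %in% lv), "marginal '%s' has invalid levels", f)
  }
  if (!is.null(cfg$co_medication)) {
    cm <- cfg$co_medication
    .assert(all(c("index_drug", "co_drug", "prob") %in% names(cm)),
            "co_medication needs index_drug, co_drug, prob")
    .assert(all(cm$prob >= 0 & cm$prob <= 1),
            "co-medication probabilities in [0,1]")
  }
  .assert(cfg$death_model$baseline >= 0 && cfg$death_model$baseline < 1,
          "death baseline must be a probability < 1")
  for (rp in cfg$role_probabilities) {
    .assert(all(sort(names(rp)) == sort(.role_levels)) &&
              abs(sum(rp) - 1) < 1e-9 && all(rp >= 0),
            "role probabilities must be named over the three roles and sum to 1")
  }
  .assert("default" %in% names(cfg$role_probabilities),
          "role_probabilities must contain a 'default' element")
  invisible(TRUE)
}

# uniform default marginals used when a config does not care about them
default_marginals <- function() {
  list(
    sex = c(male = 0.45, female = 0.5, unknown = 0.05),
    age_group = c(le11 = 0.02, a12_17 = 0.03, a18_44 = 0.3, a45_64 = 0.3,
                  a65_74 = 0.15, ge75 = 0.12, unknown = 0.08),
    region = c(americas = 0.3, europe = 0.3, asia = 0.3, oceania = 0.05,
               africa = 0.05),
    reporter = c(consumer = 0.2, physician = 0.3, other_hcp = 0.3,
                 pharmacist = 0.1, lawyer = 0.01, unknown = 0.09),
    year = c("2016" = 0.2, "2017" = 0.2, "2018" = 0.2, "2019" = 0.2,
             "2020" = 0.15, "NA" = 0.05),
    serious = c(true = 0.4, false = 0.5, unknown = 0.1)
  )
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `cfg$n_reports` independent reports under the configured model.
#' The generator is deterministic: the same configuration (including its
#' seed) always produces the same database, and hence byte-identical line
#' listings. Sampling is fully vectorised from one seeded stream with a
#' fixed draw order (demographics, drug exposures, co-medication, events,
#' roles, death).
#'
#' Reports left with no drug (or no event) by the Bernoulli draws receive
#' one fallback entry sampled proportionally to the catalog probabilities,
#' so every report has at least one drug and one event.
#'
#' @param cfg a [generator_config].
#' @param seed optional override of `cfg$seed`.
#' @return A list with elements `db` (an [icsr_db]) and `ledger` (a
#'   `generation_ledger`: per injected pair the configured relative risk and
#'   the expected report counts implied by the model, plus the fallback
#'   bookkeeping used by oracle tests).
#' @export
generate_reports <- function(cfg, seed = NULL) {
  validate_generator_config(cfg)
  n <- cfg$n_reports
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))

  dm <- cfg$demographic_marginals
  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  sex      <- draw_cat(dm$sex)
  age      <- draw_cat(dm$age_group)
  region   <- draw_cat(dm$region)
  reporter <- draw_cat(dm$reporter)
  yeartok  <- draw_cat(dm$year)
  serious  <- draw_cat(dm$serious)

  dnames <- canon(cfg$drug_catalog$drug_name)
  dprob  <- cfg$drug_catalog$prob
  nd <- length(dnames)
  # n x nd exposure matrix, drawn column by column to avoid big temporaries
  drug_m <- matrix(FALSE, n, nd)
  for (j in seq_len(nd)) drug_m[, j] <- stats::runif(n) < dprob[j]

  forced_drug <- which(rowSums(drug_m) == 0)
  if (length(forced_drug)) {
    pick <- sample.int(nd, length(forced_drug), replace = TRUE,
                       prob = if (sum(dprob) > 0) dprob else NULL)
    drug_m[cbind(forced_drug, pick)] <- TRUE
  }

  if (!is.null(cfg$co_medication)) {
    cm <- cfg$co_medication
    for (i in seq_len(nrow(cm))) {
      ii <- match(canon(cm$index_drug[i]), dnames)
      jj <- match(canon(cm$co_drug[i]), dnames)
      .assert(!is.na(ii) && !is.na(jj),
              "co_medication references a drug outside the catalog")
      on <- which(drug_m[, ii])
      if (length(on))
        drug_m[on, jj] <- drug_m[on, jj] |
          (stats::runif(length(on)) < cm$prob[i])
    }
  }

  enames <- canon(cfg$event_catalog$pt)
  ne <- length(enames)
  si <- cfg$signal_injections
  if (!is.null(si)) {
    si$.drug <- match(canon(si$drug_name), dnames)
    si$.pt <- match(canon(si$pt), enames)
  }
  cb <- cfg$conditional_event_boost
  if (!is.null(cb)) {
    cb$.drug <- match(canon(cb$drug_name), dnames)
    cb$.pt <- match(canon(cb$pts), enames)
    .assert(!is.na(cb$.drug) && !anyNA(cb$.pt),
            "conditional_event_boost references unknown drug or term")
  }
  # per-PT probability vectors with injected relative risks, column-wise
  event_m <- matrix(FALSE, n, ne)
  for (j in seq_len(ne)) {
    pj <- rep(cfg$event_catalog$prob[j], n)
    if (!is.null(si)) {
      for (i in which(si$.pt == j)) {
        on <- drug_m[, si$.drug[i]]
        pj[on] <- pj[on] * si$rr[i]
      }
    }
    if (!is.null(cb) && j %in% cb$.pt) {
      on <- drug_m[, cb$.drug] & age %in% cb$age_groups
      pj[on] <- pj[on] * cb$multiplier
    }
    event_m[, j] <- stats::runif(n) < pmin(pj, 1)
  }

  forced_event <- which(rowSums(event_m) == 0)
  if (length(forced_event)) {
    ep <- cfg$event_catalog$prob
    pick <- sample.int(ne, length(forced_event), replace = TRUE,
                       prob = if (sum(ep) > 0) ep else NULL)
    event_m[cbind(forced_event, pick)] <- TRUE
  }

  report_id <- sprintf("r%07d", seq_len(n))

  # long drug table + roles
  didx <- which(drug_m, arr.ind = TRUE)
  didx <- didx[order(didx[, 1], didx[, 2]), , drop = FALSE]
  role <- character(nrow(didx))
  rp <- cfg$role_probabilities
  for (j in seq_len(nd)) {
    rows <- which(didx[, 2] == j)
    if (!length(rows)) next
    p <- rp[[dnames[j]]] %||% rp$default
    role[rows] <- sample(.role_levels, length(rows), replace = TRUE,
                         prob = p[.role_levels])
  }
  drugs <- data.frame(
    report_id = report_id[didx[, 1]],
    drug_name = dnames[didx[, 2]],
    atc_code = toupper(trimws(cfg$drug_catalog$atc_code))[didx[, 2]],
    role = role, stringsAsFactors = FALSE)

  eidx <- which(event_m, arr.ind = TRUE)
  eidx <- eidx[order(eidx[, 1], eidx[, 2]), , drop = FALSE]
  events <- data.frame(report_id = report_id[eidx[, 1]],
                       pt = enames[eidx[, 2]], stringsAsFactors = FALSE)

  # death: odds = baseline odds * product of multipliers of present PTs
  b <- cfg$death_model$baseline
  log_odds <- rep(log(b / (1 - b)), n)
  pm <- cfg$death_model$pt_multipliers
  if (length(pm)) {
    names(pm) <- canon(names(pm))
    for (t in names(pm)) {
      jj <- match(t, enames)
      if (!is.na(jj)) log_odds[event_m[, jj]] <-
          log_odds[event_m[, jj]] + log(pm[[t]])
    }
  }
  death <- stats::runif(n) < stats::plogis(log_odds)
  serious[death & serious == "false"] <- "true"

  reports <- data.frame(
    report_id = report_id, sex = sex, age_group = age, region = region,
    reporter = reporter,
    year = suppressWarnings(as.integer(ifelse(yeartok == "NA", NA, yeartok))),
    serious = serious, death = death, stringsAsFactors = FALSE)

  db <- icsr_db(reports, drugs, events, .fast = TRUE)

  pairs <- NULL
  if (!is.null(cfg$signal_injections)) {
    si <- cfg$signal_injections
    p_drug <- dprob[match(canon(si$drug_name), dnames)]
    p_ev <- cfg$event_catalog$prob[match(canon(si$pt), enames)]
    rsh <- vapply(canon(si$drug_name), function(d) {
      p <- rp[[d]] %||% rp$default
      unname(p["suspected"] + p["interacting"])
    }, numeric(1))
    pairs <- data.frame(
      drug_name = canon(si$drug_name), pt = canon(si$pt), rr = si$rr,
      expected_reports = n * p_drug * pmin(1, p_ev * si$rr),
      expected_suspected = n * p_drug * pmin(1, p_ev * si$rr) * rsh,
      stringsAsFactors = FALSE)
  }
  ledger <- structure(list(
    pairs = pairs,
    forced_drug_reports = report_id[forced_drug],
    forced_event_reports = report_id[forced_event]),
    class = "generation_ledger")

  list(db = db, ledger = ledger)
}

#' @export
print.generation_ledger <- function(x, ...) {
  cat(sprintf("generation ledger: %d injected pairs, %d forced drug / %d forced event fallbacks\n",
              if (is.null(x$pairs)) 0L else nrow(x$pairs),
              length(x$forced_drug_reports), length(x$forced_event_reports)))
  invisible(x)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file mirrors the fields of [generator_config()]; tabular fields
#' (`drug_catalog`, `event_catalog`, `signal_injections`, `co_medication`)
#' are lists of records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [generator_config].
#' @export
read_generator_config <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_df <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    out <- if (is.data.frame(x)) {
      x
    } else if (!is.null(names(x))) {  # column-wise map (YAML data.frame form)
      as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    } else {                          # list of records (JSON form)
      do.call(rbind, lapply(x, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
    if (is.null(out) || nrow(out) == 0) NULL else out
  }
  dm <- lapply(raw$demographic_marginals, unlist)
  rp <- lapply(raw$role_probabilities, unlist)
  pm <- raw$death_model$pt_multipliers
  generator_config(
    n_reports = raw$n_reports, seed = raw$seed,
    drug_catalog = as_df(raw$drug_catalog),
    event_catalog = as_df(raw$event_catalog),
    signal_injections = as_df(raw$signal_injections),
    demographic_marginals = dm,
    co_medication = as_df(raw$co_medication),
    death_model = list(baseline = raw$death_model$baseline,
                       pt_multipliers = unlist(pm) %||% c()),
    role_probabilities = rp,
    conditional_event_boost = if (length(raw$conditional_event_boost))
      raw$conditional_event_boost)
}

#' Preset emulating the tramadol respiratory-depression study conditions
#'
#' A generator configuration whose demographic marginals follow the
#' published strata of the tramadol safety-report population (women 60.9%,
#' Asia 61.3%, and so on), at reduced scale: 100,000 reports by default with
#' tramadol on about 0.6% of them. The 19 narrow-scope
#' respiratory-depression preferred terms are carried at background rates
#' derived from the published comparator counts, with relative risks
#' injected on the tramadol pairs at the published disproportionality
#' levels (all five signal terms at RR >= 2), an under-18 enrichment of the
#' respiratory terms, co-medication structure for the four factor drug
#' classes (with their own respiratory-depression risk so the opioid-scope
#' comparison and the factor analysis have signal to recover), abuse-related
#' terms, and a death model tied to the respiratory terms.
#'
#' @param n_reports database size (default 100000).
#' @param seed integer seed stored in the config (default 1).
#' @return A [generator_config].
#' @export
tramadol_study_preset <- function(n_reports = 100000, seed = 1) {
  acrd <- builtin_acrd_smq()$terms
  # background per-report rates for the 19 respiratory terms, from the
  # published comparator counts over the full database scale
  bg <- c(
    "acute respiratory distress syndrome" = 3.6e-4,
    "acute respiratory failure"           = 3.4e-4,
    "apnoea"                              = 7.9e-4,
    "apnoeic attack"                      = 2.4e-5,
    "apparent life threatening event"     = 2.8e-5,
    "bradypnoea"                          = 5.8e-5,
    "breath holding"                      = 3.6e-5,
    "breath sounds abnormal"              = 1.3e-4,
    "hypopnoea"                           = 1.1e-4,
    "hypoventilation"                     = 1.9e-4,
    "infantile apnoea"                    = 3.7e-5,
    "neonatal respiratory arrest"         = 4.0e-6,
    "neonatal respiratory depression"     = 1.5e-5,
    "respiratory arrest"                  = 8.7e-4,
    "respiratory depression"              = 4.6e-4,
    "respiratory depth decreased"         = 3.0e-6,
    "respiratory failure"                 = 1.6e-3,
    "respiratory paralysis"               = 6.5e-6,
    "respiratory rate decreased"          = 1.1e-4)
  stopifnot(setequal(names(bg), acrd))
  # published full-database disproportionality levels for the tramadol pairs
  rr_tram <- c(
    "respiratory arrest" = 2.91, "respiratory depression" = 5.52,
    "respiratory failure" = 0.56, "bradypnoea" = 8.93, "apnoea" = 0.62,
    "hypoventilation" = 2.19, "respiratory rate decreased" = 2.22,
    "acute respiratory failure" = 0.68, "hypopnoea" = 1.91,
    "acute respiratory distress syndrome" = 0.47, "apnoeic attack" = 1.74,
    "breath holding" = 1.18, "infantile apnoea" = 1.15,
    "breath sounds abnormal" = 0.28, "neonatal respiratory depression" = 1.86,
    "apparent life threatening event" = 0.50,
    "neonatal respiratory arrest" = 1.77,
    "respiratory depth decreased" = 2.37, "respiratory paralysis" = 1.09)
  rr_combo <- c(
    "respiratory arrest" = 0.29, "respiratory depression" = 1.44,
    "respiratory failure" = 0.24, "bradypnoea" = 3.21, "apnoea" = 0.15,
    "hypoventilation" = 0.40, "respiratory rate decreased" = 1.24,
    "acute respiratory failure" = 0.39, "hypopnoea" = 0.72,
    "acute respiratory distress syndrome" = 0.16, "breath holding" = 0.54,
    "breath sounds abnormal" = 0.30)

  common <- c("nausea" = 0.06, "vomiting" = 0.04, "dizziness" = 0.035,
              "headache" = 0.03, "drug ineffective" = 0.05,
              "pruritus" = 0.02, "constipation" = 0.02,
              "somnolence" = 0.015, "hyperhidrosis" = 0.01,
              "seizure" = 0.005, "serotonin syndrome" = 0.0005)
  abuse <- c("drug abuse" = 0.004, "drug dependence" = 0.003,
             "intentional overdose" = 0.002, "overdose" = 0.004)

  event_catalog <- data.frame(
    pt = c(names(bg), names(common), names(abuse)),
    prob = c(unname(bg), unname(common), unname(abuse)),
    stringsAsFactors = FALSE)

  drug_catalog <- data.frame(
    drug_name = c("tramadol", "tramadol/paracetamol",
                  "morphine", "oxycodone", "fentanyl", "codeine",
                  "diazepam", "lorazepam", "alprazolam",
                  "sertraline", "amitriptyline", "venlafaxine",
                  "fluoxetine", "paroxetine", "bupropion", "mirtazapine",
                  "paracetamol", "ibuprofen", "metformin", "omeprazole"),
    atc_code = c("N02AX02", "N02AJ13",
                 "N02AA01", "N02AA05", "N02AB03", "R05DA04",
                 "N05BA01", "N05BA06", "N05BA12",
                 "N06AB06", "N06AA09", "N06AX16",
                 "N06AB03", "N06AB05", "N06AX12", "N06AX11",
                 "N02BE01", "M01AE01", "A10BA02", "A02BC01"),
    prob = c(0.006, 0.0022,
             0.010, 0.008, 0.006, 0.004,
             0.008, 0.005, 0.004,
             0.010, 0.008, 0.006,
             0.008, 0.006, 0.003, 0.004,
             0.030, 0.025, 0.020, 0.020),
    stringsAsFactors = FALSE)

  inj <- rbind(
    data.frame(drug_name = "tramadol", pt = names(rr_tram),
               rr = unname(rr_tram), stringsAsFactors = FALSE),
    data.frame(drug_name = "tramadol/paracetamol", pt = names(rr_combo),
               rr = unname(rr_combo), stringsAsFactors = FALSE),
    # stronger opioids carry higher respiratory-depression risk, so the
    # opioid-scope comparison for tramadol stays below the signal threshold
    data.frame(
      drug_name = rep(c("morphine", "oxycodone", "fentanyl", "codeine"),
                      each = 2),
      pt = rep(c("respiratory depression", "respiratory arrest"), 4),
      rr = c(16, 12, 14, 10, 20, 16, 8, 6), stringsAsFactors = FALSE),
    # sedative co-medication raises respiratory-depression reporting
    data.frame(drug_name = c("diazepam", "lorazepam", "alprazolam",
                             "sertraline", "venlafaxine", "amitriptyline"),
               pt = "respiratory depression",
               rr = c(6, 6, 5, 3, 3, 3), stringsAsFactors = FALSE),
    # abuse-related reporting is elevated on tramadol reports
    data.frame(drug_name = "tramadol",
               pt = c("drug abuse", "drug dependence",
                      "intentional overdose", "overdose"),
               rr = c(4, 4, 3, 3), stringsAsFactors = FALSE))

  co <- expand.grid(
    index_drug = c("tramadol", "tramadol/paracetamol"),
    co_drug = c("morphine", "oxycodone", "fentanyl", "codeine",
                "diazepam", "lorazepam", "alprazolam",
                "sertraline", "amitriptyline", "venlafaxine",
                "fluoxetine", "paroxetine", "bupropion", "mirtazapine"),
    stringsAsFactors = FALSE)
  co$prob <- rep(c(0.020, 0.015, 0.010, 0.008,
                   0.020, 0.012, 0.010,
                   0.018, 0.015, 0.010,
                   0.012, 0.010, 0.005, 0.008), each = 2)

  marg <- list(
    sex = c(male = 0.356, female = 0.609, unknown = 0.035),
    age_group = c(le11 = 0.008, a12_17 = 0.019, a18_44 = 0.272,
                  a45_64 = 0.323, a65_74 = 0.137, ge75 = 0.120,
                  unknown = 0.121),
    region = c(americas = 0.178, europe = 0.185, asia = 0.613,
               oceania = 0.017, africa = 0.008),
    reporter = c(consumer = 0.198, physician = 0.268, other_hcp = 0.319,
                 pharmacist = 0.108, lawyer = 0.005, unknown = 0.102),
    year = c("2013" = 0.251, "2014" = 0.090, "2015" = 0.099,
             "2016" = 0.082, "2017" = 0.113, "2018" = 0.111,
             "2019" = 0.111, "2020" = 0.143),
    serious = c(true = 0.45, false = 0.45, unknown = 0.10))
  marg <- lapply(marg, function(p) p / sum(p))

  role_probabilities <- list(
    default = c(suspected = 0.55, interacting = 0.05, concomitant = 0.40),
    "tramadol" = c(suspected = 0.85, interacting = 0.05, concomitant = 0.10),
    "tramadol/paracetamol" = c(suspected = 0.85, interacting = 0.05,
                               concomitant = 0.10))

  death_model <- list(
    baseline = 0.008,
    pt_multipliers = c(
      "respiratory arrest" = 30, "respiratory depression" = 8,
      "respiratory failure" = 10, "apnoea" = 4, "bradypnoea" = 6,
      "hypoventilation" = 6, "respiratory rate decreased" = 6,
      "acute respiratory failure" = 10,
      "acute respiratory distress syndrome" = 10,
      "intentional overdose" = 6, "overdose" = 4))

  generator_config(
    n_reports = n_reports, seed = seed,
    drug_catalog = drug_catalog, event_catalog = event_catalog,
    signal_injections = inj, demographic_marginals = marg,
    co_medication = co, death_model = death_model,
    role_probabilities = role_probabilities,
    conditional_event_boost = list(
      age_groups = c("le11", "a12_17"), drug_name = "tramadol",
      pts = c("respiratory arrest", "respiratory depression", "bradypnoea",
              "hypoventilation", "respiratory rate decreased", "apnoea"),
      multiplier = 3))
}
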