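#' Demographics table for a drug and its SMQ cases
#'
#' Counts and half-up one-decimal percentages per stratum of sex, age
#' group, reporter, region and reporting year, plus a serious-case row and
#' totals, for all suspect/interacting reports of the index drug and for
#' its SMQ cases. Percentages use the column total (including unknown
#' strata) as denominator.
#'
#' @param db an [icsr_db].
#' @param index_drug the analysed drug.
#' @param smq the case-defining [smq_definition].
#' @return data.frame `section`, `stratum`, `n_all`, `pct_all`, `n_case`,
#'   `pct_case`.
#' @export
render_demographics <- function(db, index_drug, smq) {
  stopifnot(inherits(db, "icsr_db"), inherits(smq, "smq_definition"))
  sub <- filter_reports(db, index_drug, c("suspected", "interacting"))
  case <- is_case(sub, smq)
  r <- sub$reports
  n_all <- nrow(r); n_case <- sum(case)
  pct <- function(x, n) if (n > 0) round_half_up(100 * x / n, 1) else 0

  year_band <- function(y) ifelse(is.na(y), "unknown",
                           ifelse(y <= 2013, "le2013",
                           ifelse(y >= 2020, "ge2020", as.character(y))))
  strata <- list(
    sex = list(r$sex, .sex_levels),
    age = list(r$age_group, .age_levels),
    reporter = list(r$reporter, .reporter_levels),
    region = list(r$region, .region_levels),
    year = list(year_band(r$year),
                c("le2013", as.character(2014:2019), "ge2020", "unknown")))

  rows <- list(data.frame(section = "total", stratum = "reports",
                          n_all = n_all, pct_all = pct(n_all, n_all),
                          n_case = n_case, pct_case = pct(n_case, n_case),
                          stringsAsFactors = FALSE))
  for (sec in names(strata)) {
    v <- strata[[sec]][[1]]; lv <- strata[[sec]][[2]]
    ta <- table(factor(v, lv)); tc <- table(factor(v[case], lv))
    rows[[length(rows) + 1]] <- data.frame(
      section = sec, stratum = lv, n_all = as.integer(ta),
      pct_all = pct(as.integer(ta), n_all), n_case = as.integer(tc),
      pct_case = pct(as.integer(tc), n_case), stringsAsFactors = FALSE)
  }
  sa <- sum(r$serious == "true"); sc <- sum(r$serious[case] == "true")
  rows[[length(rows) + 1]] <- data.frame(
    section = "serious", stratum = "serious", n_all = sa,
    pct_all = pct(sa, n_all), n_case = sc, pct_case = pct(sc, n_case),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' Describes one end-to-end run: the input (an existing line listing or a
#' generator configuration), the index drugs, the case-defining SMQ, the
#' comparator scopes, signal criteria, factor list and output directory.
#'
#' @param out_dir output directory (created if needed).
#' @param listing path to a line-listing TSV, or `NULL` to simulate.
#' @param generator a [generator_config] used when `listing` is `NULL`.
#' @param index_drugs character vector of analysed drugs.
#' @param smq case-defining [smq_definition].
#' @param abuse_smq [smq_definition] for the drug-abuse factor.
#' @param drug_classes named list of [drug_class] objects for the
#'   concomitant-medication factors.
#' @param scopes subset of `c("full_database", "opioids")`.
#' @param criteria a [signal_criteria].
#' @param factors character vector from `c("sex", "age", "region",
#'   "reporter", "death", "abuse", "classes")`.
#' @param min_concomitant_cases strict co-report threshold for class
#'   members entering the factor analysis (default 20).
#' @param seed integer seed for simulation.
#' @param quiet suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, listing = NULL, generator = NULL,
                       index_drugs = c("tramadol", "tramadol/paracetamol"),
                       smq = builtin_acrd_smq(),
                       abuse_smq = default_abuse_smq(),
                       drug_classes = default_drug_classes(),
                       scopes = c("full_database", "opioids"),
                       criteria = signal_criteria(),
                       factors = c("sex", "age", "region", "reporter",
                                   "death", "abuse", "classes"),
                       min_concomitant_cases = 20, seed = 1,
                       quiet = FALSE) {
  .assert(length(index_drugs) >= 1, "need at least one index drug")
  .assert(!is.null(listing) || !is.null(generator),
          "either a listing path or a generator config is required")
  structure(list(out_dir = out_dir, listing = listing,
                 generator = generator, index_drugs = canon(index_drugs),
                 smq = smq, abuse_smq = abuse_smq,
                 drug_classes = drug_classes,
                 scopes = match.arg(scopes, c("full_database", "opioids"),
                                    several.ok = TRUE),
                 criteria = criteria, factors = factors,
                 min_concomitant_cases = min_concomitant_cases,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "run_config")
}

# versioned, diff-able TSV output
write_tsv_versioned <- function(df, path, name) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# pvsignal-table\t1\t%s", name), con, useBytes = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) ifelse(is.na(x), "NA", format(x, digits = 10,
                                                       trim = TRUE,
                                                       scientific = FALSE))
      else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> demographics -> disproportionality
#' screens per drug and scope -> under-18 stratified screen -> factor
#' analysis, writing diff-able TSV tables plus a machine-readable
#' `summary.json` to the output directory. The same configuration and seed
#' always produce byte-identical outputs. Stage progress is logged to
#' stderr with the stage name, seed and input checksum; any stage error
#' aborts with a stage-tagged message. An empty database yields zero-count
#' demographics and no signals, and the factor stage is skipped with a
#' warning.
#'
#' @param cfg a [run_config].
#' @return Invisibly, a list of class `report_bundle`: `db`, per-drug
#'   results, `summary` and the written file paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(stage, fmt, ...) {
    if (!cfg$quiet)
      message(sprintf("[pvsignal:%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, file, name) {
    p <- file.path(cfg$out_dir, file)
    write_tsv_versioned(df, p, name)
    paths <<- c(paths, p)
    p
  }

  db <- stage("input", {
    if (!is.null(cfg$listing)) {
      say("input", "reading listing %s (md5 %s)", cfg$listing,
          unname(tools::md5sum(cfg$listing)))
      read_line_listing(cfg$listing)
    } else {
      say("input", "simulating %d reports (seed %d)",
          cfg$generator$n_reports, cfg$seed)
      gen <- generate_reports(cfg$generator, seed = cfg$seed)
      p <- file.path(cfg$out_dir, "listing.tsv")
      write_line_listing(gen$db, p)
      say("input", "wrote %s (md5 %s)", p, unname(tools::md5sum(p)))
      paths <- c(paths, p)
      gen$db
    }
  })

  summary_out <- list(n_total = db$n_total, seed = cfg$seed, drugs = list())
  results <- list()

  for (drug in cfg$index_drugs) {
    dtag <- gsub("[^a-z0-9]+", "_", drug)
    res <- list()

    res$demographics <- stage("demographics", {
      say("demographics", "drug '%s'", drug)
      render_demographics(db, drug, cfg$smq)
    })
    emit(res$demographics, sprintf("demographics_%s.tsv", dtag),
         sprintf("demographics %s", drug))

    res$screens <- list()
    for (sc in cfg$scopes) {
      scr <- stage("signals", {
        say("signals", "drug '%s', scope %s", drug, sc)
        detect_signals(db, drug, cfg$smq, scope = sc,
                       criteria = cfg$criteria)
      })
      res$screens[[sc]] <- scr
      emit(as.data.frame(scr), sprintf("signals_%s_%s.tsv", dtag, sc),
           sprintf("signals %s %s", drug, sc))
    }

    res$under18 <- stage("stratified", {
      say("stratified", "drug '%s', under-18 stratum", drug)
      suppressWarnings(stratified_signals(db, drug, cfg$smq,
                                          criteria = cfg$criteria))
    })
    emit(as.data.frame(res$under18), sprintf("signals_%s_under18.tsv", dtag),
         sprintf("under-18 signals %s", drug))

    n_drug_reports <-
      filter_reports(db, drug, c("suspected", "interacting"))$n_total
    res$factors <- list()
    if (n_drug_reports == 0 || db$n_total == 0) {
      warning(sprintf("factor stage skipped for '%s': no reports", drug))
    } else {
      say("factors", "drug '%s'", drug)
      fspecs <- list()
      for (f in intersect(cfg$factors, c("sex", "age", "region",
                                         "reporter", "death")))
        fspecs[[f]] <- f
      if ("abuse" %in% cfg$factors) fspecs[["abuse"]] <- cfg$abuse_smq
      if ("classes" %in% cfg$factors) {
        elig <- eligible_concomitants(db, drug, cfg$min_concomitant_cases)
        for (nm in names(cfg$drug_classes)) {
          cl <- cfg$drug_classes[[nm]]
          members <- intersect(cl$members, elig)
          if (length(members))
            fspecs[[nm]] <- drug_class(cl$class_name, members)
        }
      }
      for (nm in names(fspecs)) {
        ft <- tryCatch(
          build_factor_table(db, drug, cfg$smq, fspecs[[nm]]),
          error = function(e) {
            warning(sprintf("factor '%s' skipped for '%s': %s", nm, drug,
                            conditionMessage(e)))
            NULL
          })
        if (!is.null(ft)) res$factors[[nm]] <- ft
      }
      if (length(res$factors)) {
        frows <- do.call(rbind, lapply(names(res$factors), function(nm) {
          ft <- res$factors[[nm]]
          s <- summarize_factor(ft)
          data.frame(factor = nm, category = s$category,
                     n_case = s$n_case, n_noncase = s$n_noncase,
                     pct_case = round_half_up(100 * s$prop_case, 1),
                     pct_noncase = round_half_up(100 * s$prop_noncase, 1),
                     proportion_ratio = s$proportion_ratio,
                     chi2 = ft$chi2, df = ft$df, p_value = ft$p_value,
                     posthoc = if (!is.null(ft$posthoc))
                       ifelse(ft$posthoc$significant,
                              ft$posthoc$direction, "") else "",
                     stringsAsFactors = FALSE)
        }))
        emit(frows, sprintf("factors_%s.tsv", dtag),
             sprintf("factors %s", drug))
      }
    }

    full_scr <- res$screens[["full_database"]]
    summary_out$drugs[[drug]] <- list(
      n_reports = n_drug_reports,
      n_cases = sum(is_case(
        filter_reports(db, drug, c("suspected", "interacting")), cfg$smq)),
      signals = lapply(res$screens, function(s)
        s$term[s$signal & !s$pooled]),
      signal_report_total = if (!is.null(full_scr))
        sum(full_scr$a[full_scr$signal & !full_scr$pooled]) else 0,
      factor_ratios = lapply(res$factors, function(ft) {
        s <- summarize_factor(ft)
        setNames(s$proportion_ratio, s$category)
      }))
    results[[drug]] <- res
  }

  sp <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary_out, sp, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  paths <- c(paths, sp)
  say("done", "%d files in %s", length(paths), cfg$out_dir)

  invisible(structure(list(db = db, results = results,
                           summary = summary_out, paths = paths),
                      class = "report_bundle"))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("pvsignal report bundle: %d reports, %d drugs analysed\n",
              x$db$n_total, length(x$results)))
  for (d in names(x$summary$drugs)) {
    s <- x$summary$drugs[[d]]
    cat(sprintf("  %s: %d reports, %d cases; signals (full database): %s\n",
                d, s$n_reports, s$n_cases,
                paste(s$signals$full_database, collapse = ", ")))
  }
  invisible(x)
}
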