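#' Individual case safety report databases
#'
#' An `icsr_db` object holds a spontaneous-reporting database in report
#' grain: one row per report in `$reports` (demographics, seriousness,
#' death flag), one row per drug entry in `$drugs` (name, ATC code, reported
#' role), and one row per event entry in `$events` (MedDRA preferred term).
#' All strings are stored in canonical form (trimmed, whitespace-squeezed,
#' lower case; ATC codes upper case), so matching throughout the package is
#' effectively case-insensitive.
#'
#' @param reports data.frame with columns `report_id`, `sex`, `age_group`,
#'   `region`, `reporter`, `year` (integer, `NA` = unknown), `serious`
#'   (`"true"`/`"false"`/`"unknown"`), `death` (logical).
#' @param drugs data.frame with columns `report_id`, `drug_name`,
#'   `atc_code` (may be `""`), `role` (`"suspected"`, `"interacting"` or
#'   `"concomitant"`).
#' @param events data.frame with columns `report_id`, `pt`.
#' Tables are stored in a canonical row order (reports by `report_id`,
#' drugs by id/name/role, events by id/term), so two databases with the
#' same content compare equal regardless of construction order.
#'
#' @param .fast internal: skip canonicalisation and validation for input
#'   already produced by package code.
#' @return An object of class `icsr_db` with elements `reports`, `drugs`,
#'   `events` and `n_total`.
#' @seealso [read_line_listing()], [write_line_listing()], [filter_reports()]
#' @export
icsr_db <- function(reports, drugs, events, .fast = FALSE) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs   <- as.data.frame(drugs,   stringsAsFactors = FALSE)
  events  <- as.data.frame(events,  stringsAsFactors = FALSE)
  if (.fast) return(.new_icsr_db(reports, drugs, events))

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    .assert(length(miss) == 0, "%s is missing column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  need(reports, c("report_id", "sex", "age_group", "region", "reporter",
                  "year", "serious", "death"), "reports")
  need(drugs, c("report_id", "drug_name", "atc_code", "role"), "drugs")
  need(events, c("report_id", "pt"), "events")

  reports$report_id <- as.character(reports$report_id)
  drugs$report_id   <- as.character(drugs$report_id)
  events$report_id  <- as.character(events$report_id)

  .assert(!anyDuplicated(reports$report_id),
          "duplicate report_id in reports table")

  for (fld in c("sex", "age_group", "region", "reporter", "serious")) {
    lv <- switch(fld, sex = .sex_levels, age_group = .age_levels,
                 region = .region_levels, reporter = .reporter_levels,
                 serious = .serious_levels)
    reports[[fld]] <- canon(reports[[fld]])
    bad <- setdiff(unique(reports[[fld]]), lv)
    .assert(length(bad) == 0, "invalid %s value(s): %s", fld,
            paste(bad, collapse = ", "))
  }
  reports$year  <- suppressWarnings(as.integer(reports$year))
  reports$death <- as.logical(reports$death)
  .assert(!anyNA(reports$death), "death flag must be TRUE/FALSE")
  # a fatal outcome is by definition serious
  .assert(!any(reports$death & reports$serious == "false"),
          "death = TRUE requires serious 'true' or 'unknown'")

  drugs$drug_name <- canon(drugs$drug_name)
  .assert(all(nzchar(drugs$drug_name)), "empty drug_name")
  drugs$atc_code <- toupper(trimws(as.character(drugs$atc_code)))
  drugs$atc_code[is.na(drugs$atc_code)] <- ""
  drugs$role <- canon(drugs$role)
  bad <- setdiff(unique(drugs$role), .role_levels)
  .assert(length(bad) == 0, "invalid drug role(s): %s",
          paste(bad, collapse = ", "))

  events$pt <- canon(events$pt)
  .assert(all(nzchar(events$pt)), "empty preferred term")

  if (nrow(reports)) {
    .assert(all(drugs$report_id %in% reports$report_id) &&
              all(events$report_id %in% reports$report_id),
            "drug/event rows reference unknown report_id")
    .assert(all(reports$report_id %in% drugs$report_id),
            "every report needs at least one drug entry")
    .assert(all(reports$report_id %in% events$report_id),
            "every report needs at least one event entry")
  }

  drugs  <- unique(drugs)
  events <- unique(events)
  .new_icsr_db(reports, drugs, events)
}

# canonical row order + class stamp; callers guarantee validity
.new_icsr_db <- function(reports, drugs, events) {
  reports <- reports[order(reports$report_id), , drop = FALSE]
  drugs   <- drugs[order(drugs$report_id, drugs$drug_name, drugs$role), ,
                   drop = FALSE]
  events  <- events[order(events$report_id, events$pt), , drop = FALSE]
  rownames(reports) <- rownames(drugs) <- rownames(events) <- NULL
  structure(list(reports = reports, drugs = drugs, events = events,
                 n_total = nrow(reports)),
            class = "icsr_db")
}

#' @export
print.icsr_db <- function(x, ...) {
  cat(sprintf("ICSR database: %d reports, %d drug entries, %d event entries\n",
              x$n_total, nrow(x$drugs), nrow(x$events)))
  cat(sprintf("  distinct drugs: %d, distinct preferred terms: %d\n",
              length(unique(x$drugs$drug_name)),
              length(unique(x$events$pt))))
  invisible(x)
}

#' @export
summary.icsr_db <- function(object, ...) {
  r <- object$reports
  out <- list(
    n_total = object$n_total,
    sex = table(factor(r$sex, .sex_levels)),
    age_group = table(factor(r$age_group, .age_levels)),
    region = table(factor(r$region, .region_levels)),
    serious = table(factor(r$serious, .serious_levels)),
    deaths = sum(r$death)
  )
  class(out) <- "summary.icsr_db"
  out
}

#' @export
print.summary.icsr_db <- function(x, ...) {
  cat(sprintf("ICSR database: %d reports, %d deaths\n", x$n_total, x$deaths))
  for (f in c("sex", "age_group", "region", "serious")) {
    cat(" ", f, ":", paste(names(x[[f]]), as.integer(x[[f]]),
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

.listing_columns <- c("report_id", "sex", "age_group", "region", "reporter",
                      "year", "serious", "death", "drug_name", "atc_code",
                      "role", "pt")

#' Read an ICSR line listing
#'
#' Reads a UTF-8 tab-separated line listing in report-drug-event grain (one
#' row per report/drug/event triple, the grain of typical VigiBase-style
#' extracts) and merges rows sharing a `report_id` into single reports with
#' the union of their drug and event entries.
#'
#' Demographic fields must agree across all rows of one `report_id`;
#' a conflict is a hard error naming the offending report. An unrecognised
#' enum token is a hard error naming the row.
#'
#' @param path path to a TSV file with header
#'   `report_id sex age_group region reporter year serious death drug_name
#'   atc_code role pt`; unknown year is written `NA`.
#' @return An [icsr_db] object.
#' @export
read_line_listing <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  .assert(identical(names(raw), .listing_columns),
          "unexpected header: %s", paste(names(raw), collapse = " "))
  if (nrow(raw) == 0) {
    empty <- function(cols) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                   cols))
      df
    }
    rep0 <- empty(c("report_id", "sex", "age_group", "region", "reporter"))
    rep0$year <- integer(0); rep0$serious <- character(0)
    rep0$death <- logical(0)
    return(icsr_db(rep0,
                   empty(c("report_id", "drug_name", "atc_code", "role")),
                   empty(c("report_id", "pt"))))
  }

  check_enum <- function(col, levels) {
    v <- canon(raw[[col]])
    bad <- which(!(v %in% levels))
    .assert(length(bad) == 0,
            "row %d: invalid %s token '%s'", bad[1], col, raw[[col]][bad[1]])
    v
  }
  raw$sex       <- check_enum("sex", .sex_levels)
  raw$age_group <- check_enum("age_group", .age_levels)
  raw$region    <- check_enum("region", .region_levels)
  raw$reporter  <- check_enum("reporter", .reporter_levels)
  raw$serious   <- check_enum("serious", .serious_levels)
  raw$role      <- check_enum("role", .role_levels)
  dtok <- canon(raw$death)
  bad <- which(!(dtok %in% c("true", "false")))
  .assert(length(bad) == 0, "row %d: invalid death token '%s'",
          if (length(bad)) bad[1] else 0L,
          if (length(bad)) raw$death[bad[1]] else "")
  raw$death <- dtok == "true"
  ytok <- trimws(raw$year)
  bad <- which(!(ytok == "NA" | grepl("^-?[0-9]+$", ytok)))
  .assert(length(bad) == 0, "row %d: invalid year token '%s'",
          if (length(bad)) bad[1] else 0L,
          if (length(bad)) raw$year[bad[1]] else "")
  raw$year <- suppressWarnings(as.integer(ifelse(ytok == "NA", NA, ytok)))

  demo_cols <- c("report_id", "sex", "age_group", "region", "reporter",
                 "year", "serious", "death")
  demo_key <- do.call(paste, c(raw[demo_cols], sep = "\x1f"))
  first <- match(raw$report_id, raw$report_id)
  bad <- which(demo_key != demo_key[first])
  .assert(length(bad) == 0, "conflicting demographics for report_id '%s'",
          if (length(bad)) raw$report_id[bad[1]] else "")
  demo <- raw[!duplicated(raw$report_id), demo_cols, drop = FALSE]
  .assert(!any(demo$death & demo$serious == "false"),
          "death = TRUE requires serious 'true' or 'unknown'")

  raw$drug_name <- canon(raw$drug_name)
  raw$atc_code <- toupper(trimws(raw$atc_code))
  raw$pt <- canon(raw$pt)
  .assert(all(nzchar(raw$drug_name)), "empty drug_name")
  .assert(all(nzchar(raw$pt)), "empty preferred term")

  dkey <- paste(raw$report_id, raw$drug_name, raw$atc_code, raw$role,
                sep = "\x1f")
  ekey <- paste(raw$report_id, raw$pt, sep = "\x1f")
  icsr_db(demo,
          raw[!duplicated(dkey), c("report_id", "drug_name", "atc_code",
                                   "role"), drop = FALSE],
          raw[!duplicated(ekey), c("report_id", "pt"), drop = FALSE],
          .fast = TRUE)
}

#' Write an ICSR line listing
#'
#' Expands each report to report-drug-event grain (the Cartesian product of
#' its drug and event entries) and writes a UTF-8 TSV whose rows are sorted
#' by (`report_id`, `drug_name`, `role`, `pt`) so identical databases always
#' produce byte-identical files. `read_line_listing()` of the output
#' reproduces the database field for field.
#'
#' @param db an [icsr_db].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_line_listing <- function(db, path) {
  stopifnot(inherits(db, "icsr_db"))
  if (db$n_total == 0) {
    writeLines(paste(.listing_columns, collapse = "\t"), path,
               useBytes = TRUE)
    return(invisible(path))
  }
  rows <- merge(db$drugs, db$events, by = "report_id")
  rows <- merge(db$reports, rows, by = "report_id")
  rows <- rows[order(rows$report_id, rows$drug_name, rows$role, rows$pt), ,
               drop = FALSE]
  rows <- rows[.listing_columns]
  rows$death <- ifelse(rows$death, "true", "false")
  rows$year  <- ifelse(is.na(rows$year), "NA", as.character(rows$year))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.listing_columns, collapse = "\t"), con, useBytes = TRUE)
  body <- do.call(paste, c(lapply(rows, as.character), sep = "\t"))
  writeLines(body, con, useBytes = TRUE)
  invisible(path)
}

# subset a database to a set of report ids
subset_db <- function(db, ids) {
  keep <- db$reports$report_id %in% ids
  kept <- db$reports$report_id[keep]
  icsr_db(db$reports[keep, , drop = FALSE],
          db$drugs[db$drugs$report_id %in% kept, , drop = FALSE],
          db$events[db$events$report_id %in% kept, , drop = FALSE],
          .fast = TRUE)
}

#' Filter reports by drug and reported role
#'
#' Returns the sub-database of reports that contain `drug_name` with one of
#' the given roles. The counting unit is the report: a report matches once
#' no matter how many qualifying drug entries it carries. Disproportionality
#' analyses use roles `c("suspected", "interacting")`, the conventional
#' case definition for suspect/interacting reports.
#'
#' @param db an [icsr_db].
#' @param drug_name drug to match (case-insensitive exact match).
#' @param roles character subset of
#'   `c("suspected", "interacting", "concomitant")`.
#' @return An [icsr_db] containing only the matching reports.
#' @export
filter_reports <- function(db, drug_name,
                           roles = c("suspected", "interacting")) {
  stopifnot(inherits(db, "icsr_db"))
  roles <- canon(roles)
  .assert(length(roles) > 0 && all(roles %in% .role_levels),
          "roles must be a non-empty subset of the three role tokens")
  ids <- drug_report_ids(db, drug_name, roles)
  subset_db(db, ids)
}

# report ids containing a drug under the given roles
drug_report_ids <- function(db, drug_name, roles = .role_levels) {
  d <- db$drugs
  unique(d$report_id[d$drug_name == canon(drug_name) & d$role %in% roles])
}
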