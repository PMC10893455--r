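#' SMQ definitions
#'
#' A Standardised MedDRA Query (SMQ) is a validated, predefined set of
#' preferred terms representing one clinical concept. Membership tests are
#' case-insensitive (terms are stored in canonical lower-case form).
#'
#' @param name SMQ name.
#' @param scope `"narrow"` (high specificity) or `"broad"`.
#' @param terms character vector of MedDRA preferred terms (non-empty).
#' @return An object of class `smq_definition`.
#' @export
smq_definition <- function(name, scope = c("narrow", "broad"), terms) {
  scope <- match.arg(scope)
  terms <- unique(canon(terms))
  .assert(length(terms) > 0 && all(nzchar(terms)), "terms must be non-empty")
  structure(list(name = canon(name), scope = scope, terms = terms),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("SMQ '%s' (%s scope), %d preferred terms\n",
              x$name, x$scope, length(x$terms)))
  invisible(x)
}

#' Narrow-scope acute central respiratory depression SMQ
#'
#' The 19 narrow-scope preferred terms of the "acute central respiratory
#' depression" (ACRD) SMQ used to define respiratory-depression cases.
#' The set is fixed; [read_term_file()] can supply alternatives.
#'
#' @return An [smq_definition] named `"acute central respiratory depression"`.
#' @export
builtin_acrd_smq <- function() {
  smq_definition("acute central respiratory depression", "narrow", c(
    "acute respiratory distress syndrome",
    "acute respiratory failure",
    "apnoea",
    "apnoeic attack",
    "apparent life threatening event",
    "bradypnoea",
    "breath holding",
    "breath sounds abnormal",
    "hypopnoea",
    "hypoventilation",
    "infantile apnoea",
    "neonatal respiratory arrest",
    "neonatal respiratory depression",
    "respiratory arrest",
    "respiratory depression",
    "respiratory depth decreased",
    "respiratory failure",
    "respiratory paralysis",
    "respiratory rate decreased"
  ))
}

#' Default "drug abuse and dependence" SMQ term set
#'
#' MedDRA does not permit redistribution of the full SMQ, so this default
#' covers the commonly used abuse/dependence/misuse preferred terms and is
#' intended to be replaced by a licensed term list via [read_term_file()]
#' where available.
#'
#' @return An [smq_definition] named `"drug abuse and dependence"`.
#' @export
default_abuse_smq <- function() {
  smq_definition("drug abuse and dependence", "narrow", c(
    "drug abuse",
    "drug abuser",
    "drug dependence",
    "drug withdrawal syndrome",
    "drug withdrawal convulsions",
    "intentional product misuse",
    "intentional overdose",
    "overdose",
    "substance abuse",
    "substance use disorder",
    "dependence",
    "toxicity to various agents"
  ))
}

#' Read a preferred-term list file
#'
#' One preferred term per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @param name SMQ name (default: file name without extension).
#' @param scope `"narrow"` or `"broad"`.
#' @return An [smq_definition].
#' @export
read_term_file <- function(path, name = NULL, scope = "narrow") {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  smq_definition(name %||% sub("\\.[^.]*$", "", basename(path)),
                 scope, lines)
}

#' Drug class lists
#'
#' Named sets of drug names used as risk-cofactor definitions in the factor
#' analysis (CYP2D6 inhibitors, other opioids, benzodiazepines,
#' antidepressants).
#'
#' @param class_name one of `"cyp2d6_inhibitors"`, `"opioids"`,
#'   `"benzodiazepines"`, `"antidepressants"`.
#' @param members character vector of drug names.
#' @return An object of class `drug_class`.
#' @export
drug_class <- function(class_name, members) {
  class_name <- canon(class_name)
  .assert(class_name %in% c("cyp2d6_inhibitors", "opioids",
                            "benzodiazepines", "antidepressants"),
          "unknown drug class '%s'", class_name)
  members <- unique(canon(members))
  .assert(length(members) > 0, "class members must be non-empty")
  structure(list(class_name = class_name, members = members),
            class = "drug_class")
}

#' @export
print.drug_class <- function(x, ...) {
  cat(sprintf("drug class '%s': %d members\n", x$class_name,
              length(x$members)))
  invisible(x)
}

#' Default drug-class lists
#'
#' Configurable defaults covering common class members: CYP2D6 inhibitors
#' follow the FDA's published examples of strong/moderate inhibitors; the
#' other three classes list widely co-prescribed members. Replace any of
#' them via [read_drug_class_file()] for a study-specific list.
#'
#' @return Named list of four [drug_class] objects.
#' @export
default_drug_classes <- function() {
  list(
    cyp2d6_inhibitors = drug_class("cyp2d6_inhibitors", c(
      "fluoxetine", "paroxetine", "bupropion", "quinidine", "terbinafine",
      "duloxetine", "mirabegron", "cinacalcet")),
    opioids = drug_class("opioids", c(
      "morphine", "oxycodone", "fentanyl", "hydromorphone", "codeine",
      "tapentadol", "buprenorphine", "methadone")),
    benzodiazepines = drug_class("benzodiazepines", c(
      "diazepam", "lorazepam", "alprazolam", "midazolam", "clonazepam",
      "temazepam")),
    antidepressants = drug_class("antidepressants", c(
      "sertraline", "amitriptyline", "venlafaxine", "mirtazapine",
      "citalopram", "escitalopram", "fluoxetine", "paroxetine",
      "duloxetine", "trazodone"))
  )
}

#' Read a drug-class file
#'
#' TSV with header `class_name drug_name`, one member per row.
#'
#' @param path file path.
#' @return Named list of [drug_class] objects, one per distinct class.
#' @export
read_drug_class_file <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "", fileEncoding = "UTF-8")
  .assert(all(c("class_name", "drug_name") %in% names(df)),
          "expected columns class_name and drug_name")
  by_cls <- split(df$drug_name, canon(df$class_name))
  Map(drug_class, names(by_cls), by_cls)
}

#' Back-fill missing ATC codes from a drug-name map
#'
#' @param db an [icsr_db].
#' @param path TSV with header `drug_name atc_code`.
#' @return The database with empty `atc_code` fields filled where the map
#'   has the drug.
#' @export
apply_atc_map <- function(db, path) {
  .assert(file.exists(path), "file not found: %s", path)
  m <- utils::read.delim(path, colClasses = "character", sep = "\t",
                         quote = "", fileEncoding = "UTF-8")
  .assert(all(c("drug_name", "atc_code") %in% names(m)),
          "expected columns drug_name and atc_code")
  key <- canon(m$drug_name)
  idx <- !nzchar(db$drugs$atc_code)
  hit <- match(db$drugs$drug_name[idx], key)
  db$drugs$atc_code[idx][!is.na(hit)] <-
    toupper(trimws(m$atc_code[hit[!is.na(hit)]]))
  db
}

#' Flag SMQ cases
#'
#' A report is a case when at least one of its event preferred terms belongs
#' to the SMQ; a report carrying several SMQ terms is still a single case
#' (case-level deduplication).
#'
#' @param db an [icsr_db].
#' @param smq an [smq_definition].
#' @return Named logical vector, one element per report in `db$reports`
#'   order.
#' @export
is_case <- function(db, smq) {
  stopifnot(inherits(db, "icsr_db"), inherits(smq, "smq_definition"))
  ids <- smq_case_ids(db, smq)
  setNames(db$reports$report_id %in% ids, db$reports$report_id)
}

# report ids with >= 1 event PT in the SMQ
smq_case_ids <- function(db, smq) {
  unique(db$events$report_id[db$events$pt %in% smq$terms])
}

#' Flag opioid reports by ATC code
#'
#' A report is an opioid report when it contains any drug entry whose ATC
#' code starts with `N02A` (opioid analgesics) or `N01AH` (opioid
#' anaesthetics), in any role. Entries whose drug name equals
#' `exclude_drug` are ignored, which is how the index drug is removed from
#' the opioid comparator.
#'
#' @param db an [icsr_db].
#' @param exclude_drug drug name to ignore, or `NULL`.
#' @return Named logical vector per report.
#' @export
is_opioid_report <- function(db, exclude_drug = NULL) {
  stopifnot(inherits(db, "icsr_db"))
  ids <- opioid_report_ids(db, exclude_drug)
  setNames(db$reports$report_id %in% ids, db$reports$report_id)
}

opioid_report_ids <- function(db, exclude_drug = NULL) {
  d <- db$drugs
  keep <- startsWith(d$atc_code, "N02A") | startsWith(d$atc_code, "N01AH")
  if (!is.null(exclude_drug)) keep <- keep & d$drug_name != canon(exclude_drug)
  unique(d$report_id[keep])
}

#' Flag concomitant drug-class users
#'
#' A report is a class user when it contains at least one drug belonging to
#' the class other than the index drug itself, in any reported role.
#'
#' @param db an [icsr_db].
#' @param cls a [drug_class].
#' @param index_drug the analysed drug, excluded from the class match.
#' @return Named logical vector per report.
#' @export
is_class_user <- function(db, cls, index_drug) {
  stopifnot(inherits(db, "icsr_db"), inherits(cls, "drug_class"))
  d <- db$drugs
  keep <- d$drug_name %in% setdiff(cls$members, canon(index_drug))
  ids <- unique(d$report_id[keep])
  setNames(db$reports$report_id %in% ids, db$reports$report_id)
}

#' Drugs co-reported with an index drug often enough for factor analysis
#'
#' Returns the drugs (other than the index drug) that appear together with
#' the index drug in strictly more than `min_cases` reports. Index-drug
#' reports are the suspect/interacting reports; co-medication is counted in
#' any role. Class lists are intersected with this set before a
#' concomitant-medication factor analysis, so only commonly co-reported
#' drugs enter a factor definition.
#'
#' @param db an [icsr_db].
#' @param index_drug the analysed drug.
#' @param min_cases strict lower bound on co-report count (default 20).
#' @return Character vector of drug names (possibly empty).
#' @export
eligible_concomitants <- function(db, index_drug, min_cases = 20) {
  stopifnot(inherits(db, "icsr_db"))
  .assert(min_cases >= 0, "min_cases must be >= 0")
  index_drug <- canon(index_drug)
  ids <- drug_report_ids(db, index_drug, c("suspected", "interacting"))
  d <- db$drugs[db$drugs$report_id %in% ids &
                  db$drugs$drug_name != index_drug, , drop = FALSE]
  cnt <- table(unique(d[c("report_id", "drug_name")])$drug_name)
  sort(names(cnt)[cnt > min_cases])
}
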