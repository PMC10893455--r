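# internal helpers shared across modules

.sex_levels      <- c("male", "female", "unknown")
.age_levels      <- c("le11", "a12_17", "a18_44", "a45_64", "a65_74", "ge75",
                      "unknown")
.region_levels   <- c("americas", "europe", "asia", "oceania", "africa",
                      "unknown")
.reporter_levels <- c("consumer", "physician", "other_hcp", "pharmacist",
                      "lawyer", "unknown")
.serious_levels  <- c("true", "false", "unknown")
.role_levels     <- c("suspected", "interacting", "concomitant")

# canonical string form: trimmed, internal whitespace squeezed, lower case
canon <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for display in regulatory safety tables (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
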