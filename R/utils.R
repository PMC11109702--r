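# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age in years at a reference date
#'
#' Exact day difference divided by 365.25.
#'
#' @param birth_date,at_date `Date` vectors (recycled).
#' @return Numeric vector of ages in years.
#' @export
age_years <- function(birth_date, at_date) {
  as.numeric(as.Date(at_date) - as.Date(birth_date)) / 365.25
}

#' Round half away from zero
#'
#' Printed-table percents use commercial (half-up) rounding, not the IEEE
#' round-half-even used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Normalise an external place label for matching: case-folded, trimmed,
# internal whitespace collapsed.
normalise_place <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Stop with a classed configuration error naming the offending field.
config_error <- function(field, msg) {
  stop(errorCondition(sprintf("invalid config field `%s`: %s", field, msg),
                      class = c("hdssmove_config_error", "error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("hdssmove_data_error", "error")))
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}
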