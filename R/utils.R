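#' Calendar month indexing
#'
#' The package represents calendar months internally as a single integer
#' index, `year * 12 + (month - 1)`, so that arithmetic on exposure windows
#' (e.g. "the 12 months before the interview month") is plain integer
#' arithmetic. These helpers convert between the index and (year, month).
#'
#' @param year,month Integer calendar year and month (1-12).
#' @param ym Integer month index.
#' @return `ym_index()` returns the integer index; `ym_year()` and
#'   `ym_month()` invert it.
#' @examples
#' ym_index(2010, 6)
#' ym_month(ym_index(2010, 6) - 12) # same calendar month, previous year
#' @export
ym_index <- function(year, month) {
  stopifnot(all(month >= 1L & month <= 12L))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @rdname ym_index
#' @export
ym_year <- function(ym) as.integer(ym) %/% 12L

#' @rdname ym_index
#' @export
ym_month <- function(ym) as.integer(ym) %% 12L + 1L

# Deterministic per-purpose sub-seed so that each generator draws from its
# own named stream: changing e.g. the cohort layout never perturbs the
# climate realisation for the same master seed. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 1009)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with a consistent condition class so callers can test error families
abort_hg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "heatgrowth_error"))
}
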