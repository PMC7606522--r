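#' LMS Z-score transform
#'
#' Standardizes a raw anthropometric measurement against reference LMS
#' parameters: `z = ((value/M)^L - 1) / (L * S)`, with the limiting form
#' `z = log(value/M) / S` used when `|L| < 1e-8`. The transform is strictly
#' increasing in `value` for fixed parameters. `lms_inverse()` inverts it,
#' mapping a Z-score back to the raw measurement scale; the package's
#' synthetic cohort generator uses the inverse so that generated weights and
#' heights round-trip exactly through [compute_zscores()].
#'
#' @param value Measurement (kg or cm); must be positive.
#' @param L Skewness power (unitless).
#' @param M Reference median, in measurement units; positive.
#' @param S Coefficient of variation (unitless); positive.
#' @param z Z-score (sigma units).
#' @return Z-scores (or, for `lms_inverse`, measurement values); vectorized.
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1) # exactly 1
#' lms_inverse(lms_zscore(8.2, -0.3, 9, 0.08), -0.3, 9, 0.08)
#' @export
lms_zscore <- function(value, L, M, S) {
  if (any(!is.finite(value)) || any(value <= 0) ||
      any(M <= 0) || any(S <= 0)) {
    abort_hg("lms_zscore requires value > 0, M > 0, S > 0", "lms_domain_error")
  }
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  small <- abs(L) < 1e-8
  z <- numeric(n)
  r <- value / M
  if (any(small)) z[small] <- log(r[small]) / S[small]
  if (any(!small)) {
    z[!small] <- (r[!small]^L[!small] - 1) / (L[!small] * S[!small])
  }
  z
}

#' @rdname lms_zscore
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) {
    abort_hg("lms_inverse requires M > 0 and S > 0", "lms_domain_error")
  }
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  small <- abs(L) < 1e-8
  v <- numeric(n)
  if (any(small)) v[small] <- M[small] * exp(S[small] * z[small])
  if (any(!small)) {
    base <- 1 + L[!small] * S[!small] * z[!small]
    if (any(base <= 0)) {
      abort_hg("lms_inverse: z outside the invertible range for these L, S",
               "lms_domain_error")
    }
    v[!small] <- M[!small] * base^(1 / L[!small])
  }
  v
}

#' Score a cohort against an LMS reference
#'
#' Computes the three standard indices for each child: weight-for-height
#' (`whz`, height-indexed), weight-for-age (`waz`) and height-for-age
#' (`haz`, both age-indexed), sex-specifically, with linear interpolation of
#' the L, M, S parameters between reference rows. Children whose age or
#' height falls outside the reference domain get `NA` for the affected
#' index; the number of such misses is reported via a warning and the
#' `n_out_of_domain` attribute.
#'
#' @param children A tibble with columns `child_id`, `sex` ("male"/"female"),
#'   `age_months`, `height_cm`, `weight_kg` (e.g. from [generate_cohort()]).
#' @param ref An LMS reference, default [synthetic_lms_reference()].
#' @return A tibble `child_id, whz, waz, haz` with one row per child, plus a
#'   logical `flagged` column marking any `|Z| > 6`.
#' @export
compute_zscores <- function(children, ref = synthetic_lms_reference()) {
  validate_lms_reference(ref)
  needed <- c("child_id", "sex", "age_months", "height_cm", "weight_kg")
  if (!all(needed %in% names(children))) {
    abort_hg(paste("compute_zscores needs columns:",
                   paste(needed, collapse = ", ")), "anthro_input_error")
  }
  n <- nrow(children)
  whz <- waz <- haz <- rep(NA_real_, n)
  for (sx in unique(children$sex)) {
    i <- which(children$sex == sx)
    blk <- function(m) ref[ref$sex == sx & ref$measure == m, ]
    p <- interp_lms(blk("weight_for_height"), children$height_cm[i])
    ok <- !is.na(p$M)
    whz[i[ok]] <- lms_zscore(children$weight_kg[i][ok],
                             p$L[ok], p$M[ok], p$S[ok])
    p <- interp_lms(blk("weight_for_age"), children$age_months[i])
    ok <- !is.na(p$M)
    waz[i[ok]] <- lms_zscore(children$weight_kg[i][ok],
                             p$L[ok], p$M[ok], p$S[ok])
    p <- interp_lms(blk("height_for_age"), children$age_months[i])
    ok <- !is.na(p$M)
    haz[i[ok]] <- lms_zscore(children$height_cm[i][ok],
                             p$L[ok], p$M[ok], p$S[ok])
  }
  miss <- sum(is.na(whz)) + sum(is.na(waz)) + sum(is.na(haz))
  if (miss > 0) {
    warning(sprintf("%d Z-scores outside the reference domain set to NA", miss))
  }
  out <- tibble::tibble(
    child_id = children$child_id, whz = whz, waz = waz, haz = haz,
    flagged = (abs(whz) > 6 & !is.na(whz)) |
      (abs(waz) > 6 & !is.na(waz)) | (abs(haz) > 6 & !is.na(haz))
  )
  attr(out, "n_out_of_domain") <- miss
  out
}

#' Join Z-scores onto a cohort table
#'
#' Convenience pipeline step: scores the cohort and left-joins `whz`, `waz`,
#' `haz` back onto the child records so downstream design construction can
#' pick any of them as the outcome.
#'
#' @inheritParams compute_zscores
#' @return The input tibble with `whz`, `waz`, `haz`, `flagged` appended.
#' @export
score_cohort <- function(children, ref = synthetic_lms_reference()) {
  z <- compute_zscores(children, ref)
  dplyr::left_join(children, z, by = "child_id")
}

#' Remove implausibly extreme Z-scores
#'
#' Drops records where any computed index exceeds 6 sigma in absolute value,
#' the conventional biological-plausibility screen for survey anthropometry
#' (such values are overwhelmingly measurement or data-entry error). The
#' comparison is strict (`|z| > 6`), so a record at exactly 6 sigma is kept.
#' Idempotent: filtering a filtered table removes nothing further.
#'
#' @param records A tibble containing any of `whz`, `waz`, `haz`.
#' @return The surviving rows, with attributes `n_excluded` (total rows
#'   removed) and `excluded_by` (named count of rows whose `whz`/`waz`/`haz`
#'   individually exceeded the threshold).
#' @export
apply_who_flags <- function(records) {
  cols <- intersect(c("whz", "waz", "haz"), names(records))
  if (length(cols) == 0) {
    abort_hg("apply_who_flags: no Z-score columns present", "anthro_input_error")
  }
  per <- vapply(cols, function(cl) {
    z <- records[[cl]]
    sum(abs(z) > 6, na.rm = TRUE)
  }, integer(1))
  bad <- Reduce(`|`, lapply(cols, function(cl) {
    z <- records[[cl]]
    !is.na(z) & abs(z) > 6
  }))
  out <- records[!bad, , drop = FALSE]
  attr(out, "n_excluded") <- sum(bad)
  attr(out, "excluded_by") <- per
  out
}

#' Classify malnutrition severity from a Z-score
#'
#' Standard two-threshold classification: severe below -3 sigma, moderate
#' from -3 (inclusive) to -2 (exclusive), none otherwise. The boundary value
#' -3 is assigned to the milder class (moderate) and -2 to none; i.e. the
#' comparisons are strict `z < -3` and `z < -2`.
#'
#' @param z Numeric Z-scores; must be finite.
#' @param moderate,severe Thresholds in sigma units.
#' @return A factor with levels `none`, `moderate`, `severe`.
#' @export
classify_malnutrition <- function(z, moderate = -2, severe = -3) {
  if (any(!is.finite(z))) {
    abort_hg("classify_malnutrition requires finite Z-scores", "anthro_domain_error")
  }
  out <- ifelse(z < severe, "severe", ifelse(z < moderate, "moderate", "none"))
  factor(out, levels = c("none", "moderate", "severe"))
}

#' Survey-weighted prevalence
#'
#' Weighted proportion of records satisfying a condition:
#' `sum(w * 1[condition]) / sum(w)`. Invariant to rescaling all weights by a
#' positive constant. Used both for sample wasting rates and inside the
#' projection module.
#'
#' @param z Numeric vector (typically Z-scores), or any vector the condition
#'   applies to.
#' @param condition Either a logical vector of the same length, or a
#'   function of `z` returning one. Default: wasting, `z < -2`.
#' @param weights Positive sampling weights; default equal weights.
#' @return A single proportion in `[0, 1]`.
#' @examples
#' weighted_prevalence(c(-2.5, -1, -3.5)) # 2/3 wasted
#' @export
weighted_prevalence <- function(z, condition = function(x) x < -2,
                                weights = NULL) {
  if (length(z) == 0) {
    abort_hg("weighted_prevalence is undefined for an empty table",
             "prevalence_error")
  }
  weights <- weights %||% rep(1, length(z))
  if (any(weights <= 0) || length(weights) != length(z)) {
    abort_hg("weights must be positive and match the data length",
             "prevalence_error")
  }
  ind <- if (is.function(condition)) condition(z) else condition
  stopifnot(is.logical(ind), length(ind) == length(z))
  sum(weights * ind) / sum(weights)
}
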