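#' Synthetic LMS growth reference
#'
#' Builds a smooth, sex-specific LMS reference table for the three standard
#' child growth indices: weight-for-height (indexed by height in cm),
#' weight-for-age and height-for-age (indexed by age in months). The shapes
#' are loosely calibrated to healthy-child medians (length about 50 cm at
#' birth and 109 cm at five years; weight about 3.3 kg at birth and 18 kg at
#' five years) but the table is *synthetic*: it is not a WHO product and
#' ships only so the scoring machinery can be exercised and tested without
#' bundling restricted reference data. Real LMS tables in the same column
#' layout can be dropped in via [read_lms_reference()].
#'
#' @param height_range Height domain (cm) for the weight-for-height index.
#' @param age_range Age domain (months) for the age-indexed measures.
#' @return A tibble with columns `sex` ("male"/"female"), `measure`
#'   ("weight_for_height", "weight_for_age", "height_for_age"), `axis`
#'   ("height_cm" or "age_months"), `index` (the indexing value), and the
#'   LMS parameters `L`, `M`, `S`. Index values are strictly increasing
#'   within each (sex, measure) block.
#' @seealso [lms_zscore()], [compute_zscores()]
#' @export
synthetic_lms_reference <- function(height_range = c(45, 140),
                                    age_range = c(0, 60)) {
  h <- seq(height_range[1], height_range[2], by = 1)
  a <- seq(age_range[1], age_range[2], by = 1)

  one_sex <- function(sex) {
    fem <- sex == "female"
    wfh <- tibble::tibble(
      sex = sex, measure = "weight_for_height", axis = "height_cm", index = h,
      L = -0.35,
      M = (2.4 + 0.095 * (h - 45) + 0.0020 * (h - 45)^2) * ifelse(fem, 0.97, 1),
      S = 0.082
    )
    wfa <- tibble::tibble(
      sex = sex, measure = "weight_for_age", axis = "age_months", index = a,
      L = 0.2,
      M = (3.3 + 1.8 * sqrt(a) + 0.015 * a) * ifelse(fem, 0.95, 1),
      S = 0.11 + 0.0003 * a
    )
    hfa <- tibble::tibble(
      sex = sex, measure = "height_for_age", axis = "age_months", index = a,
      L = 1,
      M = (50 + 6 * sqrt(a) + 0.2 * a) * ifelse(fem, 0.985, 1),
      S = 0.035
    )
    dplyr::bind_rows(wfh, wfa, hfa)
  }

  ref <- dplyr::bind_rows(one_sex("male"), one_sex("female"))
  class(ref) <- c("lms_reference", class(ref))
  ref
}

#' Read or write an LMS reference table as CSV
#'
#' The on-disk layout is one row per (sex, measure, index) with columns
#' `sex, measure, axis, index, L, M, S`, matching
#' [synthetic_lms_reference()]. Validation enforces `M > 0`, `S > 0` and a
#' strictly increasing index within each (sex, measure) block.
#'
#' @param path File path.
#' @param ref An LMS reference tibble.
#' @return `read_lms_reference()` returns the validated reference tibble;
#'   `write_lms_reference()` returns `path` invisibly.
#' @export
read_lms_reference <- function(path) {
  ref <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_lms_reference(ref)
  class(ref) <- c("lms_reference", class(ref))
  ref
}

#' @rdname read_lms_reference
#' @export
write_lms_reference <- function(ref, path) {
  validate_lms_reference(ref)
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

validate_lms_reference <- function(ref) {
  needed <- c("sex", "measure", "axis", "index", "L", "M", "S")
  if (!all(needed %in% names(ref))) {
    abort_hg("LMS reference must have columns sex, measure, axis, index, L, M, S",
             "lms_reference_error")
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort_hg("LMS reference requires M > 0 and S > 0", "lms_reference_error")
  }
  bad <- ref |>
    dplyr::group_by(.data$sex, .data$measure) |>
    dplyr::summarise(ok = !is.unsorted(.data$index, strictly = TRUE),
                     .groups = "drop")
  if (any(!bad$ok)) {
    abort_hg("LMS reference index must be strictly increasing within sex/measure",
             "lms_reference_error")
  }
  invisible(ref)
}

# Linear interpolation of L, M, S at arbitrary index values, for one
# (sex, measure) block. Returns a list of vectors; NA outside the domain.
interp_lms <- function(ref_block, at) {
  out <- list(
    L = stats::approx(ref_block$index, ref_block$L, xout = at, rule = 1)$y,
    M = stats::approx(ref_block$index, ref_block$M, xout = at, rule = 1)$y,
    S = stats::approx(ref_block$index, ref_block$S, xout = at, rule = 1)$y
  )
  out
}
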