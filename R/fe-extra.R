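#' Crop-area-weighted growing-season regression
#'
#' Fits the growing-season temperature regression for one crop, weighting
#' each child by sampling weight times the local area share of that crop,
#' so fully specialized locations dominate identification of the crop's
#' effect and mixed-cropping cells contribute proportionally. Children in
#' cells with zero share (empty growing-season window) drop out.
#'
#' @param children Scored cohort tibble.
#' @param grid A `climate_grid`.
#' @param cropmap A `crop_map`.
#' @param crop Crop name.
#' @param spec A [regression_spec()]; its window/crop are overridden.
#' @return An `fe_fit` (with the combined weight), plus attribute
#'   `n_zero_share` on the fit recording dropped children.
#' @export
crop_weighted_fit <- function(children, grid, cropmap, crop,
                              spec = regression_spec()) {
  spec$window <- "growing_season"
  spec$crop <- crop
  design <- build_design(children, grid, spec, cropmap)
  if (nrow(design) == 0 || all(design$share * design[[spec$weight_col]] == 0)) {
    abort_hg("no identifying weight: all crop shares are zero",
             "crop_weight_error")
  }
  fit <- fit_fe_ols(design, spec,
                    weights = design[[spec$weight_col]] * design$share)
  fit$crop <- crop
  fit
}

#' Group-wise fixed-effects fits
#'
#' Estimates the shared specification independently within each group of a
#' partition of the sample (age bands, urban/rural, ...). Groups smaller
#' than `min_n` are skipped with a warning and absent from the result.
#'
#' @param design Design tibble from [build_design()].
#' @param spec A [regression_spec()]; defaults to the design's.
#' @param group Either the name of a column of `design` or a vector of
#'   group labels of matching length.
#' @param min_n Minimum group size to attempt a fit.
#' @return A tibble with one row per fitted group: `group`, `n_obs` and a
#'   `fit` list-column of `fe_fit` objects.
#' @export
fit_by_group <- function(design, spec = attr(design, "spec"), group,
                         min_n = 50) {
  g <- if (length(group) == 1 && is.character(group) &&
           group %in% names(design)) design[[group]] else group
  if (length(g) != nrow(design)) {
    abort_hg("grouping must partition the design rows", "group_error")
  }
  meta <- attributes(design)[c("feature_cols", "control_cols", "spec")]
  res <- purrr::map(split(seq_len(nrow(design)), g), function(idx) {
    if (length(idx) < min_n) return(NULL)
    d <- design[idx, , drop = FALSE]
    attr(d, "feature_cols") <- meta$feature_cols
    attr(d, "control_cols") <- meta$control_cols
    attr(d, "spec") <- meta$spec
    fit_fe_ols(d, spec)
  })
  skipped <- names(res)[vapply(res, is.null, logical(1))]
  if (length(skipped) > 0) {
    warning(sprintf("groups below min_n skipped: %s",
                    paste(skipped, collapse = ", ")))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  tibble::tibble(group = names(res),
                 n_obs = vapply(res, function(f) f$n_obs, numeric(1)),
                 fit = unname(res))
}

#' Restrict to children resident for the exposure period
#'
#' Migration robustness subset: keeps children whose recorded residence
#' duration (months) covers the exposure window — the child's age for
#' lifetime windows, 12 months for prior-year, 1 for survey month, and age
#' plus 9 months for trimester windows. Children with missing duration are
#' excluded.
#'
#' @param children Cohort tibble with `residence_months` and `age_months`.
#' @param window Window kind.
#' @return The surviving rows.
#' @export
residence_filter <- function(children,
                             window = c("lifetime", "prior_year",
                                        "survey_month", "trimester1",
                                        "trimester2", "trimester3",
                                        "growing_season")) {
  window <- match.arg(window)
  req <- switch(window,
    lifetime = children$age_months,
    prior_year = 12, growing_season = 12, survey_month = 1,
    trimester1 = children$age_months + 9,
    trimester2 = children$age_months + 9,
    trimester3 = children$age_months + 9)
  d <- children$residence_months
  children[!is.na(d) & d >= req, , drop = FALSE]
}

#' Cross-sectional quartic fit of regional means
#'
#' The descriptive regional analysis: weighted least squares of regional
#' mean outcome on a fourth-order polynomial in regional mean temperature,
#' weighted by the number of observations per region, with the overall
#' F-statistic for the four slope terms.
#'
#' @param region_means Tibble with columns `mean_temp`, `mean_outcome`,
#'   `n_obs`; at least 6 regions.
#' @return A `cross_section_fit`: list with `coefficients` (intercept and
#'   quartic terms), `f_statistic`, `df`, `p.value` and the underlying
#'   `lm` object. Methods: `tidy`, `glance`, `autoplot`.
#' @seealso [regional_summary()] to build the input from a scored cohort.
#' @export
cross_section_fit <- function(region_means) {
  needed <- c("mean_temp", "mean_outcome", "n_obs")
  if (!all(needed %in% names(region_means))) {
    abort_hg("region_means needs columns mean_temp, mean_outcome, n_obs",
             "cross_section_error")
  }
  if (nrow(region_means) < 6) {
    abort_hg("need at least 6 regions for a quartic fit", "cross_section_error")
  }
  fit <- stats::lm(mean_outcome ~ mean_temp + I(mean_temp^2) +
                     I(mean_temp^3) + I(mean_temp^4),
                   data = region_means, weights = region_means$n_obs)
  fs <- summary(fit)$fstatistic
  structure(list(
    coefficients = stats::coef(fit),
    f_statistic = unname(fs[1]), df = unname(fs[2:3]),
    p.value = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    lm = fit, data = region_means),
    class = "cross_section_fit")
}

#' @importFrom generics tidy
#' @method tidy cross_section_fit
#' @export
tidy.cross_section_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @importFrom generics glance
#' @method glance cross_section_fit
#' @export
glance.cross_section_fit <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df = x$df[1], df.residual = x$df[2],
                 p.value = unname(x$p.value), n_regions = nrow(x$data))
}

#' @export
print.cross_section_fit <- function(x, ...) {
  cat(sprintf("<cross_section_fit> quartic over %d regions, F(%g, %g) = %.2f (p = %.3g)\n",
              nrow(x$data), x$df[1], x$df[2], x$f_statistic, x$p.value))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Regional summary for the cross-sectional analysis
#'
#' Aggregates a scored cohort to one row per subnational region: long-run
#' mean temperature over the region's children's grid cells (full grid
#' period), survey-weighted mean outcome, and the observation count.
#'
#' @param children Scored cohort tibble (with the outcome column).
#' @param grid A `climate_grid`.
#' @param outcome Outcome column name; default `"whz"`.
#' @return Tibble `region, mean_temp, mean_outcome, n_obs`.
#' @export
regional_summary <- function(children, grid, outcome = "whz") {
  cell_mean <- rowMeans(grid$temp)
  children |>
    dplyr::mutate(cell_t = cell_mean[.data$cell]) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      mean_temp = mean(.data$cell_t),
      mean_outcome = stats::weighted.mean(.data[[outcome]], .data$sweight,
                                          na.rm = TRUE),
      n_obs = dplyr::n(), .groups = "drop")
}
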