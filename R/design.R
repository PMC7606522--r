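#' Specification of a fixed-effects temperature regression
#'
#' Bundles every choice that defines one estimating equation: outcome
#' index, temperature functional form and exposure window, control set,
#' fixed-effect dimensions to absorb, clustering dimension, weights, and
#' numerical settings for the demeaning. Defaults reproduce the package's
#' main specification: survey-weighted regression of weight-for-height on
#' a prior-year temperature function, controlling for survey-month
#' temperature, precipitation and demographics, absorbing subnational
#' region, country-by-year and calendar-month fixed effects, with errors
#' clustered at the country-by-year level.
#'
#' @param outcome One of `"whz"`, `"waz"`, `"haz"` (a column of the scored
#'   cohort).
#' @param form `"degree_month"`, `"polynomial"` or `"binned"`.
#' @param window Exposure window kind (see [resolve_window()]) or
#'   `"growing_season"` (requires `crop`).
#' @param crop Crop name for growing-season designs.
#' @param controls Include the demographic/precipitation control block?
#' @param fe_dims Character vector of fixed-effect label columns to absorb.
#' @param cluster_dim Column defining the clustering of errors.
#' @param weight_col Sampling-weight column.
#' @param demean_tol Convergence tolerance for the alternating-projection
#'   demeaning, applied on unit-scaled columns.
#' @param max_iter Sweep cap for the demeaning.
#' @param edges,omitted Temperature bin scheme (binned form).
#' @param threshold Degree-month threshold, degrees C.
#' @param degree Polynomial degree.
#' @param poly_mode `"per_month_sum"` or `"window_mean"`; default per-month
#'   sums except for lifetime windows, which use the window mean.
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(outcome = c("whz", "waz", "haz"),
                            form = c("degree_month", "polynomial", "binned"),
                            window = "prior_year", crop = NULL,
                            controls = TRUE,
                            fe_dims = c("region", "country_year", "cal_month"),
                            cluster_dim = "country_year",
                            weight_col = "sweight",
                            demean_tol = 1e-10, max_iter = 10000,
                            edges = default_bin_edges(), omitted = 24,
                            threshold = 25, degree = 4, poly_mode = NULL) {
  outcome <- match.arg(outcome)
  form <- match.arg(form)
  if (length(fe_dims) == 0) abort_hg("fe_dims must be non-empty", "spec_error")
  if (window == "growing_season" && is.null(crop)) {
    abort_hg("growing_season window requires a crop", "spec_error")
  }
  structure(list(outcome = outcome, form = form, window = window, crop = crop,
                 controls = controls, fe_dims = fe_dims,
                 cluster_dim = cluster_dim, weight_col = weight_col,
                 demean_tol = demean_tol, max_iter = max_iter, edges = edges,
                 omitted = omitted, threshold = threshold, degree = degree,
                 poly_mode = poly_mode),
            class = "regression_spec")
}

# 0/1 dummy columns for a factor, dropping the reference (first) level
dummy_cols <- function(f, prefix) {
  f <- droplevels(as.factor(f))
  lv <- levels(f)
  if (length(lv) < 2) return(NULL)
  m <- sapply(lv[-1], function(l) as.numeric(f == l))
  colnames(m) <- paste0(prefix, lv[-1])
  m
}

#' Assemble a regression design table
#'
#' One row per usable child: the outcome, the temperature features implied
#' by the spec's form and window, the survey-month temperature control
#' (except when the window *is* the survey month), precipitation controls
#' (interview month and cumulative previous 12 months), the demographic
#' control block (mother's education indicators, mother's age, birth order
#' fully interacted with sex, birth-month indicators), fixed-effect group
#' labels, the cluster label and the sampling weight. Children whose
#' window or precipitation history extends beyond the grid, or whose
#' outcome is missing, are dropped; the count is recorded in the
#' `n_dropped` attribute. Bin-count columns that are zero for every child
#' (temperatures never observed there) are removed and listed in the
#' `dropped_bins` attribute. For growing-season designs the crop's area
#' `share` is attached and zero-share children are dropped.
#'
#' @param children Scored cohort tibble (see [score_cohort()]); must
#'   contain the outcome column named in `spec`.
#' @param grid A `climate_grid`.
#' @param spec A [regression_spec()].
#' @param cropmap A `crop_map`; required for growing-season windows.
#' @return A tibble with attributes `feature_cols`, `control_cols`,
#'   `spec`, `n_dropped`, `dropped_bins`.
#' @export
build_design <- function(children, grid, spec, cropmap = NULL) {
  stopifnot(inherits(spec, "regression_spec"), inherits(grid, "climate_grid"))
  if (!spec$outcome %in% names(children)) {
    abort_hg(sprintf("outcome column '%s' missing; run score_cohort() first",
                     spec$outcome), "design_error")
  }
  n <- nrow(children)
  cell <- if ("cell" %in% names(children)) children$cell else
    match_to_cell(children$lat, children$lon, grid)
  survey_ym <- ym_index(children$survey_year, children$survey_month)
  birth_ym <- survey_ym - children$age_months

  season_cal <- NULL
  share <- NULL
  if (spec$window == "growing_season") {
    if (is.null(cropmap)) abort_hg("growing_season needs a cropmap", "design_error")
    cm <- cropmap[cropmap$crop == spec$crop, ]
    if (nrow(cm) == 0) abort_hg("crop not present in map", "crop_config_error")
    idx <- match(cell, cm$cell)
    if (any(is.na(idx))) abort_hg("children in cells without crop data",
                                  "crop_config_error")
    start <- cm$season_start[idx]; len <- cm$season_len[idx]
    season_cal <- sapply(1:12, function(m) ((m - start) %% 12) < len)
    if (n == 1) season_cal <- matrix(season_cal, nrow = 1)
    share <- cm$share[idx]
  }

  ef <- exposure_features(grid, cell, birth_ym, survey_ym, spec$window,
                          spec$form, spec$edges, spec$omitted, spec$threshold,
                          spec$degree, spec$poly_mode, season_cal)

  # controls need the survey month and the 12 months before it
  m0 <- grid$months[1]; nm <- length(grid$months)
  t0_col <- survey_ym - m0 + 1L
  ok <- ef$ok & t0_col >= 13L & t0_col <= nm & !is.na(children[[spec$outcome]])
  if (!is.null(share)) ok <- ok & share > 0

  n_dropped <- sum(!ok)
  keep <- which(ok)
  F <- ef$F[keep, , drop = FALSE]
  dropped_bins <- character(0)
  if (spec$form == "binned") {
    empty <- colSums(F != 0) == 0
    dropped_bins <- colnames(F)[empty]
    F <- F[, !empty, drop = FALSE]
  }

  ch <- children[keep, , drop = FALSE]
  cellk <- cell[keep]; t0k <- t0_col[keep]
  t_survey <- grid$temp[cbind(cellk, t0k)]
  precip_survey <- grid$precip[cbind(cellk, t0k)]
  precip_12m <- rowSums(matrix(
    grid$precip[cbind(rep(cellk, 12), as.vector(outer(t0k, 1:12, `-`)))],
    length(keep), 12))

  out <- tibble::tibble(
    child_id = ch$child_id,
    y = ch[[spec$outcome]],
    region = as.character(ch$region),
    country_year = paste0("c", ch$country, "_y", ch$survey_year),
    cal_month = sprintf("m%02d", ch$survey_month),
    sweight = ch$sweight,
    urban = ch$urban,
    age_months = ch$age_months,
    residence_months = ch$residence_months %||% rep(NA_real_, nrow(ch)))
  names(out)[names(out) == "y"] <- spec$outcome
  if (!is.null(share)) out$share <- share[keep]

  out <- dplyr::bind_cols(out, tibble::as_tibble(F))

  control_cols <- character(0)
  if (isTRUE(spec$controls)) {
    ctl <- list()
    if (spec$window != "survey_month") ctl$t_survey <- t_survey
    ctl$precip_survey <- precip_survey
    ctl$precip_12m <- precip_12m
    ctl$mother_age <- as.numeric(ch$mother_age)
    ctl <- tibble::as_tibble(ctl)
    edu <- dummy_cols(factor(ch$mother_edu, levels = 0:3), "edu")
    bos <- dummy_cols(interaction(pmin(ch$birth_order, 6), ch$sex, sep = "_",
                                  drop = FALSE), "bo")
    bm <- dummy_cols(factor(ch$birth_month, levels = 1:12), "bm")
    for (m in list(edu, bos, bm)) {
      if (!is.null(m)) ctl <- dplyr::bind_cols(ctl, tibble::as_tibble(m))
    }
    control_cols <- names(ctl)
    out <- dplyr::bind_cols(out, ctl)
  }

  attr(out, "feature_cols") <- colnames(F)
  attr(out, "control_cols") <- control_cols
  attr(out, "spec") <- spec
  attr(out, "n_dropped") <- n_dropped
  attr(out, "dropped_bins") <- dropped_bins
  out
}
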