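#' Match points to climate grid cells
#'
#' Assigns each (lat, lon) point to the grid cell whose half-open square
#' `[center - res/2, center + res/2)` contains it, in both coordinates. A
#' point exactly on a shared edge therefore belongs to the higher-indexed
#' (more northern/eastern) cell. Points outside the grid's outer bounding
#' box raise a coverage error.
#'
#' @param lat,lon Numeric vectors, degrees.
#' @param grid A `climate_grid`.
#' @return Integer cell indices into `grid$cells`.
#' @export
match_to_cell <- function(lat, lon, grid) {
  stopifnot(inherits(grid, "climate_grid"))
  lats <- sort(unique(grid$cells$lat))
  lons <- sort(unique(grid$cells$lon))
  r <- grid$res
  i <- floor((lat - (lats[1] - r / 2)) / r) + 1
  j <- floor((lon - (lons[1] - r / 2)) / r) + 1
  bad <- i < 1 | i > length(lats) | j < 1 | j > length(lons)
  if (any(bad)) {
    abort_hg(sprintf("%d point(s) fall outside the climate grid", sum(bad)),
             "coverage_error")
  }
  # cells are laid out lat-major (see generate_climate_grid)
  as.integer((i - 1) * length(lons) + j)
}

#' Resolve an exposure window to calendar months
#'
#' Window conventions (month indices, see [ym_index()]):
#' * `survey_month`: the interview month itself (1 month).
#' * `prior_year`: the 12 months strictly before the interview month.
#' * `lifetime`: birth month through interview month, inclusive
#'   (`age_months + 1` months).
#' * `trimester1/2/3`: counting back from the birth month, months -9..-7,
#'   -6..-4 and -3..-1 respectively; together they partition the 9 months
#'   before birth.
#'
#' @param kind One of `"survey_month"`, `"prior_year"`, `"lifetime"`,
#'   `"trimester1"`, `"trimester2"`, `"trimester3"`.
#' @param birth_ym,survey_ym Integer month indices.
#' @return Integer vector of month indices.
#' @export
resolve_window <- function(kind, birth_ym, survey_ym) {
  kind <- match.arg(kind, c("survey_month", "prior_year", "lifetime",
                            "trimester1", "trimester2", "trimester3"))
  switch(kind,
    survey_month = survey_ym,
    prior_year   = seq(survey_ym - 12L, survey_ym - 1L),
    lifetime     = seq(birth_ym, survey_ym),
    trimester1   = seq(birth_ym - 9L, birth_ym - 7L),
    trimester2   = seq(birth_ym - 6L, birth_ym - 4L),
    trimester3   = seq(birth_ym - 3L, birth_ym - 1L)
  )
}

#' Default temperature bin scheme
#'
#' 2 degree C bins with open-ended extremes: `(-Inf, 14), [14, 16), ...,
#' [32, 34), [34, Inf)`. The `[24, 26)` bin is the conventional omitted
#' (reference) category.
#'
#' @return Numeric vector of interior bin edges.
#' @export
default_bin_edges <- function() seq(14, 34, by = 2)

bin_labels <- function(edges) {
  k <- length(edges)
  c(sprintf("bin_lt%g", edges[1]),
    sprintf("bin_%g_%g", edges[-k], edges[-1]),
    sprintf("bin_ge%g", edges[k]))
}

#' Binned monthly temperature counts
#'
#' Counts the months of a series falling in each temperature bin, with
#' half-open `[lo, hi)` intervals and open-ended extreme bins, then drops
#' the omitted (reference) bin from the returned vector. Including the
#' omitted bin, the counts always sum to the series length.
#'
#' @param series Numeric monthly temperatures, degrees C.
#' @param edges Strictly increasing interior bin edges;
#'   default [default_bin_edges()].
#' @param omitted Lower edge of the omitted bin (the bin `[omitted,
#'   next edge)`); default 24.
#' @return Named integer vector of counts for the non-omitted bins.
#' @export
binned_month_counts <- function(series, edges = default_bin_edges(),
                                omitted = 24) {
  if (is.unsorted(edges, strictly = TRUE)) {
    abort_hg("bin edges must be strictly increasing", "exposure_input_error")
  }
  labs <- bin_labels(edges)
  om_lab <- labs[match(omitted, c(-Inf, edges))]
  if (is.na(om_lab)) abort_hg("omitted bin not found", "exposure_input_error")
  idx <- findInterval(series, edges) + 1L  # 1..k+1
  counts <- tabulate(idx, nbins = length(labs))
  names(counts) <- labs
  counts[names(counts) != om_lab]
}

#' Degree-months above a threshold
#'
#' Cumulative heat exposure: `sum(pmax(0, T - threshold))` over the monthly
#' series, in degree C months. Zero exactly when no month exceeds the
#' threshold.
#'
#' @param series Numeric monthly temperatures, degrees C.
#' @param threshold Degrees C; default 25.
#' @return A nonnegative scalar.
#' @export
degree_months <- function(series, threshold = 25) {
  if (any(!is.finite(series))) {
    abort_hg("degree_months requires finite temperatures", "exposure_input_error")
  }
  sum(pmax(0, series - threshold))
}

#' Polynomial temperature exposure
#'
#' Power sums of a monthly temperature series for a degree-4 polynomial
#' response. `per_month_sum` returns `(sum T, sum T^2, sum T^3, sum T^4)` —
#' the regressors for a per-month polynomial summed over the window, as
#' used for prior-year models. `window_mean` returns the powers of the
#' window-mean temperature, as used for lifetime-average models.
#'
#' @param series Numeric monthly temperatures; must be non-empty.
#' @param degree Polynomial degree; default 4.
#' @param mode `"per_month_sum"` or `"window_mean"`.
#' @return Named numeric vector `temp_p1 ... temp_p<degree>`.
#' @export
polynomial_exposure <- function(series, degree = 4,
                                mode = c("per_month_sum", "window_mean")) {
  mode <- match.arg(mode)
  if (length(series) == 0) {
    abort_hg("polynomial_exposure requires a non-empty series",
             "exposure_input_error")
  }
  x <- if (mode == "window_mean") mean(series) else series
  out <- vapply(seq_len(degree), function(p) sum(x^p), numeric(1))
  names(out) <- paste0("temp_p", seq_len(degree))
  out
}

#' Growing-season exposure window
#'
#' The growing-season window for a child is the prior-year window (the 12
#' months strictly before the interview month) restricted to the crop's
#' growing-season calendar months in the child's cell — i.e. the previous
#' year's growing season. Always a subset of the 12 months preceding the
#' interview; equals the full prior-year window when the season covers all
#' 12 calendar months. If the crop has zero area share in the cell the
#' window is empty, signalling that the child drops out of that crop's
#' regression.
#'
#' @param cell Grid cell index.
#' @param crop Crop name.
#' @param cropmap A `crop_map` from [generate_crop_map()].
#' @param survey_ym Interview month index.
#' @return Integer vector of month indices (possibly empty).
#' @export
growing_season_window <- function(cell, crop, cropmap, survey_ym) {
  row <- cropmap[cropmap$cell == cell & cropmap$crop == crop, ]
  if (nrow(row) != 1) {
    abort_hg("crop not present in map for this cell", "crop_config_error")
  }
  if (row$share == 0) return(integer(0))
  months <- resolve_window("prior_year", NA_integer_, survey_ym)
  sm <- season_months(cropmap, cell, crop)
  months[ym_month(months) %in% sm]
}
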