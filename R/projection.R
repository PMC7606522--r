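#' Temperature response curve with delta-method intervals
#'
#' Evaluates the fitted temperature response of a single month at average
#' temperature `T`, relative to the reference temperature (default 25
#' degrees C, the omitted category), using the temperature coefficients
#' only: `effect(T) = f_hat(T) - f_hat(reference)`. The pointwise standard
#' error is the delta method `sqrt(c(T)' V c(T))` with `c(T)` the feature
#' contrast vector, so both effect and SE are exactly zero at the
#' reference. For binned fits the effect is the bin coefficient (NA with a
#' warning for bins dropped as empty at fit time).
#'
#' @param fit An `fe_fit`.
#' @param temps Temperature grid, degrees C. Values outside a plausible
#'   physical range (-20..50) trigger a warning.
#' @param reference Reference temperature, degrees C.
#' @return A `response_curve` tibble: `temp`, `effect` (sigma), `se`.
#' @export
response_curve <- function(fit, temps = seq(10, 40, by = 0.5),
                           reference = 25) {
  stopifnot(inherits(fit, "fe_fit"))
  if (any(temps < -20 | temps > 50)) {
    warning("temperature grid extends outside a plausible physical range")
  }
  C <- response_contrast(fit, temps, reference)
  b <- fit$beta[fit$feature_names]
  V <- fit$vcov[fit$feature_names, fit$feature_names, drop = FALSE]
  effect <- as.numeric(C %*% b)
  se <- sqrt(pmax(0, rowSums((C %*% V) * C)))
  out <- tibble::tibble(temp = temps, effect = effect, se = se)
  attr(out, "reference") <- reference
  attr(out, "form") <- fit$spec$form
  class(out) <- c("response_curve", class(out))
  out
}

# contrast matrix mapping temperature coefficients to a single-month
# response relative to the reference temperature
response_contrast <- function(fit, temps, reference) {
  spec <- fit$spec
  feat <- fit$feature_names
  k <- length(temps)
  if (spec$form == "degree_month") {
    C <- matrix(pmax(0, temps - spec$threshold) -
                  pmax(0, reference - spec$threshold), ncol = 1)
    colnames(C) <- "degree_months"
  } else if (spec$form == "polynomial") {
    deg <- spec$degree
    C <- sapply(seq_len(deg), function(p) temps^p - reference^p)
    if (k == 1) C <- matrix(C, nrow = 1)
    colnames(C) <- paste0("temp_p", seq_len(deg))
  } else {
    labs <- bin_labels(spec$edges)
    lo <- c(-Inf, spec$edges); hi <- c(spec$edges, Inf)
    bin_of <- function(t) labs[findInterval(t, spec$edges) + 1L]
    C <- matrix(0, k, length(feat), dimnames = list(NULL, feat))
    tb <- bin_of(temps)
    rb <- bin_of(reference)
    missing_bins <- setdiff(unique(tb), c(feat, setdiff(labs, feat)))
    for (i in seq_len(k)) {
      if (tb[i] %in% feat) C[i, tb[i]] <- 1
      else if (!identical(tb[i], labs[match(spec$omitted, c(-Inf, spec$edges))])) {
        C[i, ] <- NA  # bin dropped at fit time: effect unidentified
      }
      if (rb %in% feat) C[i, rb] <- C[i, rb] - 1
    }
    if (any(is.na(C))) {
      warning("some temperatures fall in bins dropped at fit time; effect NA")
    }
  }
  C[, feat, drop = FALSE]
}

#' Annual weight-for-height shift from projected warming
#'
#' For the per-month polynomial response `p(T) = sum_k b_k T^k`, the shift
#' in the annual outcome between a projected year and the 2015 baseline is
#' `delta = sum_m [ p(T_m^year) - p(T_m^2015) ]` over the 12 calendar
#' months, in sigma units.
#'
#' @param coefs Polynomial coefficients `b_1 ... b_k` (no intercept).
#' @param year_series,baseline_series Monthly temperature series, exactly
#'   12 values each, degrees C.
#' @return The shift in sigma.
#' @export
delta_whz <- function(coefs, year_series, baseline_series) {
  if (length(year_series) != 12 || length(baseline_series) != 12) {
    abort_hg("delta_whz requires two 12-month series", "projection_input_error")
  }
  p <- function(t) {
    acc <- 0
    for (kk in seq_along(coefs)) acc <- acc + coefs[kk] * t^kk
    acc
  }
  sum(p(year_series) - p(baseline_series))
}

#' Shift a Z-score distribution uniformly
#'
#' Applies the same shift to every child — the projection's assumption
#' that temperature-driven weight loss is homogeneous across the outcome
#' distribution. Weights are untouched.
#'
#' @param z Z-scores.
#' @param delta Shift, sigma units; must be finite.
#' @return Shifted values.
#' @export
shift_distribution <- function(z, delta) {
  if (!is.finite(delta)) abort_hg("delta must be finite", "projection_input_error")
  z + delta
}

# power-sum contrast S[region-year, k] = sum_m (T_m^k - Tbase_m^k), so the
# annual shift for coefficient draw b is S %*% b
projection_power_sums <- function(projections, degree, baseline_year = 2015) {
  proj <- dplyr::arrange(projections, .data$region, .data$year, .data$month)
  base <- proj[proj$year == baseline_year, ]
  if (nrow(base) == 0) abort_hg("projections lack the baseline year",
                                "projection_input_error")
  key <- paste(proj$region, proj$month)
  bt <- stats::setNames(base$temp, paste(base$region, base$month))[key]
  S <- sapply(seq_len(degree), function(k) proj$temp^k - bt^k)
  agg <- rowsum(S, paste(proj$region, proj$year, sep = "\r"))
  ids <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  list(region = ids[, 1], year = as.integer(ids[, 2]), S = unname(agg))
}

#' Projected wasting trajectory
#'
#' Applies a fitted per-month polynomial temperature response to regional
#' monthly projections: for each region and year, computes the annual
#' shift relative to the 2015 series ([delta_whz()]), translates the
#' region's baseline (survey-weighted) weight-for-height distribution by
#' it, and evaluates wasting prevalence below the threshold. Percent
#' change is relative to the 2015 prevalence, which is therefore exactly
#' zero in 2015.
#'
#' @param fit An `fe_fit` with `form = "polynomial"` and per-month-sum
#'   exposure.
#' @param projections Tibble `region, year, month, temp` (see
#'   [generate_projection_series()]); must include year 2015.
#' @param baseline Tibble with the baseline children: columns `region`,
#'   the outcome `whz`, and `sweight`.
#' @param threshold Wasting threshold, sigma; default -2.
#' @param baseline_year Baseline year; default 2015.
#' @return A `wasting_projection` tibble: `region, year, delta_whz,
#'   prevalence, pct_change`.
#' @export
wasting_trajectory <- function(fit, projections, baseline, threshold = -2,
                               baseline_year = 2015) {
  stopifnot(inherits(fit, "fe_fit"))
  if (fit$spec$form != "polynomial") {
    abort_hg("wasting_trajectory requires a polynomial fit", "projection_input_error")
  }
  if (!all(unique(projections$region) %in% unique(baseline$region))) {
    abort_hg("projection regions missing from the baseline cohort",
             "projection_input_error")
  }
  b <- unname(fit$beta[fit$feature_names])
  ps <- projection_power_sums(projections, length(b), baseline_year)
  delta <- as.numeric(ps$S %*% b)
  out <- trajectory_from_delta(ps$region, ps$year, delta, baseline, threshold,
                               baseline_year)
  class(out) <- c("wasting_projection", class(out))
  out
}

trajectory_from_delta <- function(region, year, delta, baseline, threshold,
                                  baseline_year) {
  prev <- numeric(length(region))
  for (r in unique(region)) {
    i <- region == r
    bl <- baseline[baseline$region == r, ]
    o <- order(bl$whz)
    zs <- bl$whz[o]; cw <- cumsum(bl$sweight[o]) / sum(bl$sweight)
    # prevalence of z + delta < threshold  <=>  z < threshold - delta
    idx <- findInterval(threshold - delta[i], zs, left.open = TRUE)
    prev[i] <- ifelse(idx == 0, 0, cw[pmax(idx, 1)])
  }
  out <- tibble::tibble(region = region, year = year, delta_whz = delta,
                        prevalence = prev)
  base <- out[out$year == baseline_year, c("region", "prevalence")]
  names(base)[2] <- "prev0"
  out <- dplyr::left_join(out, base, by = "region")
  if (any(out$prev0 < 1e-6)) {
    abort_hg("baseline prevalence is (near) zero; percent change undefined",
             "projection_baseline_error")
  }
  out$pct_change <- 100 * (out$prevalence - out$prev0) / out$prev0
  out$prev0 <- NULL
  dplyr::arrange(out, .data$region, .data$year)
}

#' Parameter-uncertainty confidence bands for the wasting trajectory
#'
#' Draws coefficient vectors from a multivariate normal centered at the
#' fitted temperature coefficients with their cluster-robust covariance
#' block, recomputes the full trajectory for each draw, and reports
#' equal-tailed 2.5/97.5 percentile bands of the percent change per
#' region-year. Deterministic for a given seed. A covariance block that is
#' not positive semidefinite beyond a symmetric repair at tolerance 1e-10
#' is an error.
#'
#' @inheritParams wasting_trajectory
#' @param n_draws Number of coefficient draws (>= 200).
#' @param seed Integer seed.
#' @return Tibble `region, year, lo, hi` (percent-change percentiles).
#' @export
parameter_uncertainty_ci <- function(fit, projections, baseline,
                                     threshold = -2, n_draws = 1000,
                                     seed = 1, baseline_year = 2015) {
  if (n_draws < 200) abort_hg("n_draws must be >= 200", "projection_input_error")
  b <- unname(fit$beta[fit$feature_names])
  V <- fit$vcov[fit$feature_names, fit$feature_names, drop = FALSE]
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values))) {
    abort_hg("covariance block is not positive semidefinite", "projection_vcov_error")
  }
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(b))
  ps <- projection_power_sums(projections, length(b), baseline_year)

  draws <- withr::with_seed(substream_seed(seed, "projection-ci"), {
    matrix(stats::rnorm(n_draws * length(b)), length(b), n_draws)
  })
  B <- b + A %*% draws                       # p x n_draws
  D <- ps$S %*% B                            # region-year x n_draws deltas

  pct <- matrix(NA_real_, nrow(D), n_draws)
  for (d in seq_len(n_draws)) {
    tr <- trajectory_from_delta(ps$region, ps$year, D[, d], baseline,
                                threshold, baseline_year)
    key <- paste(ps$region, ps$year)
    pct[, d] <- tr$pct_change[match(key, paste(tr$region, tr$year))]
  }
  qs <- t(apply(pct, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  tibble::tibble(region = ps$region, year = ps$year,
                 lo = qs[, 1], hi = qs[, 2]) |>
    dplyr::arrange(.data$region, .data$year)
}

#' Full wasting projection: point estimates plus uncertainty bands
#'
#' Convenience wrapper combining [wasting_trajectory()] and
#' [parameter_uncertainty_ci()].
#'
#' @inheritParams parameter_uncertainty_ci
#' @param ci Compute the parameter-uncertainty bands?
#' @return A `wasting_projection` tibble with `lo`/`hi` columns appended
#'   (when `ci = TRUE`), plus attributes `n_draws` and `seed`.
#' @export
project_wasting <- function(fit, projections, baseline, threshold = -2,
                            n_draws = 1000, seed = 1, ci = TRUE,
                            baseline_year = 2015) {
  out <- wasting_trajectory(fit, projections, baseline, threshold,
                            baseline_year)
  if (ci) {
    bands <- parameter_uncertainty_ci(fit, projections, baseline, threshold,
                                      n_draws, seed, baseline_year)
    out <- dplyr::left_join(out, bands, by = c("region", "year"))
    class(out) <- c("wasting_projection", class(tibble::tibble()))
    attr(out, "n_draws") <- n_draws
    attr(out, "seed") <- seed
  }
  out
}
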