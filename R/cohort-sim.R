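#' Injected temperature response (ground truth)
#'
#' Defines the true temperature response used by the cohort generator, in
#' one of the three functional forms the estimator supports. Parameters are
#' in Z-score units per feature unit (per degree-month, per month-in-bin,
#' or per power of degrees C). When `parameters` is omitted, defaults
#' emulate an empirically plausible response: a hinge of -0.08/12 sigma per
#' degree C month above 25 degrees C (so one full year 1 degree hotter
#' costs about 0.08 sigma), expressed exactly for the degree-month form and
#' translated into bin midpoints / a least-squares quartic for the others.
#'
#' @param form `"degree_month"`, `"polynomial"` or `"binned"`.
#' @param parameters Named coefficient vector matching the form's feature
#'   names; default as described above.
#' @param window Exposure window the response acts over (see
#'   [resolve_window()]); default `"prior_year"`.
#' @param reference_temp Reference temperature, degrees C (default 25).
#' @param edges,omitted Bin scheme for the binned form.
#' @param crop Optional crop name for growing-season responses.
#' @param threshold Degree-month threshold, degrees C.
#' @param degree Polynomial degree.
#' @return A `true_response` object.
#' @export
true_response <- function(form = c("degree_month", "polynomial", "binned"),
                          parameters = NULL, window = "prior_year",
                          reference_temp = 25, edges = default_bin_edges(),
                          omitted = 24, threshold = 25, degree = 4,
                          crop = NULL) {
  form <- match.arg(form)
  slope <- -0.08 / 12  # sigma per degree C month above threshold
  if (is.null(parameters)) {
    parameters <- switch(form,
      degree_month = c(degree_months = slope),
      polynomial = {
        tg <- seq(5, 40, by = 0.1)
        y <- slope * pmax(0, tg - threshold)
        X <- cbind(tg, tg^2, tg^3, tg^4)
        b <- stats::coef(stats::lm.fit(X, y))
        stats::setNames(as.numeric(b), paste0("temp_p", 1:4))
      },
      binned = {
        labs <- bin_labels(edges)
        mids <- c(edges[1] - 1, (edges[-length(edges)] + edges[-1]) / 2,
                  edges[length(edges)] + 1)
        names(mids) <- labs
        om_lab <- labs[match(omitted, c(-Inf, edges))]
        eff <- slope * pmax(mids - threshold, 0)
        eff[setdiff(labs, om_lab)]
      })
  }
  p_expected <- switch(form, degree_month = 1L,
                       polynomial = as.integer(degree),
                       binned = length(bin_labels(edges)) - 1L)
  if (length(parameters) != p_expected) {
    abort_hg("parameter vector length does not match the form's dimension",
             "truth_config_error")
  }
  structure(list(form = form, parameters = parameters, window = window,
                 reference_temp = reference_temp, edges = edges,
                 omitted = omitted, threshold = threshold, degree = degree,
                 crop = crop),
            class = "true_response")
}

# Vectorized exposure-feature construction shared by the cohort generator
# and build_design(). Returns list(F = n x p feature matrix, ok = logical
# coverage indicator per child, mask_len = window length used).
exposure_features <- function(grid, cell, birth_ym, survey_ym, window, form,
                              edges = default_bin_edges(), omitted = 24,
                              threshold = 25, degree = 4, poly_mode = NULL,
                              season_cal = NULL) {
  n <- length(cell)
  birth_ym <- rep_len(as.integer(birth_ym), n)
  survey_ym <- rep_len(as.integer(survey_ym), n)
  m0 <- grid$months[1]
  nm <- length(grid$months)

  if (window == "lifetime") {
    age <- survey_ym - birth_ym
    L <- max(age) + 1L
    offs <- 0:(L - 1L)
    ym <- outer(survey_ym, offs, `-`)
    mask <- outer(age, offs, `>=`)
  } else if (window == "survey_month") {
    ym <- matrix(survey_ym, ncol = 1)
    mask <- matrix(TRUE, n, 1)
  } else if (window == "prior_year") {
    ym <- outer(survey_ym, 1:12, `-`)
    mask <- matrix(TRUE, n, 12)
  } else if (window %in% c("trimester1", "trimester2", "trimester3")) {
    offs <- switch(window, trimester1 = 9:7, trimester2 = 6:4, trimester3 = 3:1)
    ym <- outer(birth_ym, offs, `-`)
    mask <- matrix(TRUE, n, 3)
  } else if (window == "growing_season") {
    if (is.null(season_cal)) {
      abort_hg("growing_season window needs per-child season months",
               "exposure_input_error")
    }
    ym <- outer(survey_ym, 1:12, `-`)
    cal <- ym_month(ym); dim(cal) <- dim(ym)
    mask <- season_cal[cbind(rep(seq_len(n), ncol(ym)), as.vector(cal))]
    dim(mask) <- dim(ym)
  } else {
    abort_hg(paste("unknown window:", window), "exposure_input_error")
  }

  col <- ym - m0 + 1L
  covered <- !mask | (col >= 1L & col <= nm)
  ok <- rowSums(!covered) == 0
  col[col < 1L | col > nm] <- 1L  # placeholder; masked out below
  Tm <- grid$temp[cbind(rep(cell, ncol(col)), as.vector(col))]
  dim(Tm) <- dim(col)
  mask <- mask & matrix(ok, n, ncol(col))

  if (form == "degree_month") {
    F <- cbind(degree_months = rowSums(pmax(0, Tm - threshold) * mask))
  } else if (form == "polynomial") {
    poly_mode <- poly_mode %||%
      (if (window == "lifetime") "window_mean" else "per_month_sum")
    if (poly_mode == "window_mean") {
      xbar <- rowSums(Tm * mask) / pmax(1, rowSums(mask))
      F <- sapply(seq_len(degree), function(p) xbar^p)
    } else {
      F <- sapply(seq_len(degree), function(p) rowSums((Tm^p) * mask))
    }
    colnames(F) <- paste0("temp_p", seq_len(degree))
  } else if (form == "binned") {
    labs <- bin_labels(edges)
    om_lab <- labs[match(omitted, c(-Inf, edges))]
    lo <- c(-Inf, edges); hi <- c(edges, Inf)
    F <- sapply(seq_along(labs), function(b) {
      rowSums((Tm >= lo[b] & Tm < hi[b]) * mask)
    })
    colnames(F) <- labs
    F <- F[, setdiff(labs, om_lab), drop = FALSE]
  } else {
    abort_hg(paste("unknown form:", form), "exposure_input_error")
  }
  if (n == 1) F <- matrix(F, nrow = 1, dimnames = list(NULL, colnames(F)))
  list(F = F, ok = ok)
}

#' Configuration for the synthetic DHS-like cohort
#'
#' Layout is hierarchical: countries contain subnational regions, regions
#' contain survey clusters (villages), clusters contain children. Each
#' cluster is placed uniformly inside a randomly chosen cell of its
#' region's cell block and all its children share those coordinates,
#' mirroring the granularity of cluster GPS matching in georeferenced
#' surveys. The latent weight-for-height Z-score of each child is
#'
#' `z = baseline_z + f(T; truth) + nu * T_survey + controls + region FE +
#'  country-year FE + calendar-month FE + cluster RE + noise`
#'
#' with all fixed-effect draws Gaussian with the configured SDs, and the
#' control effects linear with fixed coefficients (see
#' [default_control_coefs()]). Raw weight and height are then back-computed
#' from the latent Z-scores through the inverse LMS reference so the
#' scoring module recovers them exactly.
#'
#' @param n_countries,regions_per_country,clusters_per_region,children_per_cluster
#'   Cohort layout counts.
#' @param survey_years Calendar years surveys take place in.
#' @param age_range_months Inclusive age range; default `c(12, 59)`
#'   (children over age 1).
#' @param urban_fraction Probability a cluster is urban.
#' @param weight_dispersion Log-SD of the lognormal sampling weights
#'   (normalized to mean 1).
#' @param noise_sd Child-level residual SD, Z-score units.
#' @param cluster_re_sd,region_fe_sd,country_year_fe_sd,month_fe_sd SDs of
#'   the variance components, Z-score units.
#' @param baseline_z Population baseline weight-for-height, sigma.
#' @param nu True effect of survey-month temperature (sigma per degree C);
#'   ignored (forced 0) when the injected response acts on the survey
#'   month itself.
#' @param control_coefs Named list of control coefficients; see
#'   [default_control_coefs()].
#' @param age_effect_slope Age interaction of the injected response: the
#'   temperature effect is multiplied by
#'   `1 + age_effect_slope * (age_months - 36) / 24`, so a positive slope
#'   makes effects intensify with age (default 0, no interaction).
#' @param haz_mean,haz_sd Latent height-for-age distribution.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_countries = 2, regions_per_country = 3,
                          clusters_per_region = 8, children_per_cluster = 25,
                          survey_years = 2008:2012,
                          age_range_months = c(12, 59),
                          urban_fraction = 0.3, weight_dispersion = 0.3,
                          noise_sd = 0.9, cluster_re_sd = 0.3,
                          region_fe_sd = 0.3, country_year_fe_sd = 0.2,
                          month_fe_sd = 0.1, baseline_z = -1, nu = -0.005,
                          control_coefs = default_control_coefs(),
                          age_effect_slope = 0,
                          haz_mean = -1.4, haz_sd = 1.1) {
  sds <- c(noise_sd, cluster_re_sd, region_fe_sd, country_year_fe_sd,
           month_fe_sd, weight_dispersion)
  if (any(sds < 0)) abort_hg("all SDs must be >= 0", "cohort_config_error")
  if (age_range_months[1] < 0 || age_range_months[2] > 59 ||
      age_range_months[1] > age_range_months[2]) {
    abort_hg("age range must lie within [0, 59] months", "cohort_config_error")
  }
  if (urban_fraction < 0 || urban_fraction > 1) {
    abort_hg("urban_fraction must be in [0, 1]", "cohort_config_error")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Default control-effect coefficients for the cohort generator
#'
#' Fixed linear effects of the demographic controls on the latent Z-score,
#' all expressible in the span of the regression's control dummies so that
#' control adjustment is exactly testable: mother's education (levels
#' 0-3), mother's age (linear, centered at 28), birth order (linear in
#' order) plus a birth-order-by-sex interaction, a seasonal birth-month
#' effect, and linear precipitation terms.
#'
#' @return Named list of coefficients.
#' @export
default_control_coefs <- function() {
  list(edu = c(0, 0.08, 0.16, 0.28),
       mother_age = 0.004,
       birth_order = -0.03,
       birth_order_male = -0.012,
       birth_month_amp = 0.05,
       precip_month = -2e-4,
       precip_12m = -5e-5)
}

control_effect <- function(children, coefs, precip_month, precip_12m) {
  coefs$edu[children$mother_edu + 1] +
    coefs$mother_age * (children$mother_age - 28) +
    coefs$birth_order * (children$birth_order - 1) +
    coefs$birth_order_male * (children$birth_order - 1) *
      (children$sex == "male") +
    coefs$birth_month_amp * cos(2 * pi * (children$birth_month - 1) / 12) +
    coefs$precip_month * precip_month +
    coefs$precip_12m * precip_12m
}

#' Generate a synthetic DHS-like child cohort
#'
#' Draws the hierarchical cohort described in [cohort_config()], computes
#' each child's true temperature exposure from the climate grid, injects
#' the configured response into a latent weight-for-height Z-score, and
#' back-computes raw weight (kg) and height (cm) through the inverse LMS
#' reference so that [compute_zscores()] reproduces the latent scores to
#' machine precision. Residence duration follows the common survey
#' pattern: 85% of children have been resident their whole life, the rest
#' a uniform fraction of it.
#'
#' @param config A [cohort_config()].
#' @param grid A `climate_grid` covering all exposure windows (at least 60
#'   months of history before the earliest birth).
#' @param truth A [true_response()], or a list of them for a multi-channel
#'   world (e.g. one response per crop). A response whose `window` is
#'   `"growing_season"` must carry a `crop` element and is weighted by the
#'   child's cell's area share of that crop, so mixed-cropping cells
#'   experience a share-weighted blend of crop effects.
#' @param seed Integer master seed.
#' @param ref LMS reference used for the inverse step.
#' @param cropmap A `crop_map`; required when any response is
#'   growing-season based.
#' @return A tibble of child records (one row per child) with location,
#'   dates, demographics, sampling weight, residence duration, raw
#'   `weight_kg`/`height_cm` and the latent ground-truth scores
#'   `latent_whz`, `latent_haz`. The injected `truth` and `config` are
#'   attached as attributes.
#' @export
generate_cohort <- function(config, grid, truth = true_response(), seed = 1,
                            ref = synthetic_lms_reference(), cropmap = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(grid, "climate_grid"))
  truths <- if (inherits(truth, "true_response")) list(truth) else truth
  stopifnot(all(vapply(truths, inherits, logical(1), "true_response")))
  n_regions <- config$n_countries * config$regions_per_country
  n_clusters <- n_regions * config$clusters_per_region
  n <- n_clusters * config$children_per_cluster
  # regions are north-south strips (contiguous blocks in lon-major order)
  # so each region spans a range of latitudes and hence of base temperatures
  ord <- order(grid$cells$lon, grid$cells$lat)
  blocks <- split(grid$cells$cell[ord],
                  cut(seq_len(nrow(grid$cells)), n_regions, labels = FALSE))

  withr::with_seed(substream_seed(seed, "cohort"), {
    # clusters
    cl <- tibble::tibble(
      cluster = seq_len(n_clusters),
      region_id = rep(seq_len(n_regions), each = config$clusters_per_region))
    cl$country <- (cl$region_id - 1) %/% config$regions_per_country + 1
    cl$cell <- vapply(cl$region_id, function(r) {
      b <- blocks[[r]]
      b[sample.int(length(b), 1)]
    }, numeric(1))
    cl$lat <- grid$cells$lat[cl$cell] + stats::runif(n_clusters, -0.5, 0.5) * grid$res
    cl$lon <- grid$cells$lon[cl$cell] + stats::runif(n_clusters, -0.5, 0.5) * grid$res
    # keep strictly inside the half-open cell square
    cl$lat <- pmin(cl$lat, grid$cells$lat[cl$cell] + grid$res / 2 - 1e-9)
    cl$lon <- pmin(cl$lon, grid$cells$lon[cl$cell] + grid$res / 2 - 1e-9)
    cl$urban <- stats::runif(n_clusters) < config$urban_fraction
    cl$survey_year <- sample(config$survey_years, n_clusters, replace = TRUE)
    cl$survey_month <- sample.int(12, n_clusters, replace = TRUE)
    cl$cluster_re <- stats::rnorm(n_clusters, 0, config$cluster_re_sd)

    # children
    ch <- cl[rep(seq_len(n_clusters), each = config$children_per_cluster), ]
    ch$child_id <- seq_len(n)
    ch$age_months <- sample(seq(config$age_range_months[1],
                                config$age_range_months[2]), n, replace = TRUE)
    ch$survey_ym <- ym_index(ch$survey_year, ch$survey_month)
    ch$birth_ym <- ch$survey_ym - ch$age_months
    ch$birth_year <- ym_year(ch$birth_ym)
    ch$birth_month <- ym_month(ch$birth_ym)
    ch$sex <- sample(c("male", "female"), n, replace = TRUE)
    ch$mother_edu <- sample(0:3, n, replace = TRUE, prob = c(.4, .3, .2, .1))
    ch$mother_age <- pmin(pmax(round(stats::rnorm(n, 28, 6.5)), 15), 49)
    ch$birth_order <- sample(1:6, n, replace = TRUE,
                             prob = c(.28, .24, .18, .13, .1, .07))
    w <- stats::rlnorm(n, 0, config$weight_dispersion)
    ch$sweight <- w / mean(w)
    full <- stats::runif(n) < 0.85
    ch$residence_months <- ifelse(
      full, ch$age_months + sample(0:24, n, replace = TRUE),
      floor(stats::runif(n) * ch$age_months))

    # coverage: 60 months of history before earliest birth
    if (min(ch$birth_ym) - 60L < grid$months[1] ||
        max(ch$survey_ym) > grid$months[length(grid$months)]) {
      abort_hg("insufficient climate history for this cohort", "coverage_error")
    }

    # injected temperature response(s). A growing-season channel applies
    # at full strength wherever its crop is grown (share > 0): the local
    # food system is exposed to the season's weather whenever the crop is
    # part of it, and the area share governs the regression *weights*, not
    # the physical exposure — this keeps the share-weighted estimator's
    # estimand equal to the injected coefficient.
    f_true <- 0
    for (tr in truths) {
      season_cal <- NULL
      grown <- 1
      if (tr$window == "growing_season") {
        if (is.null(cropmap) || is.null(tr$crop)) {
          abort_hg("growing-season truth needs a cropmap and a crop",
                   "truth_config_error")
        }
        cm <- cropmap[cropmap$crop == tr$crop, ]
        idx <- match(ch$cell, cm$cell)
        start <- cm$season_start[idx]; len <- cm$season_len[idx]
        season_cal <- sapply(1:12, function(m) ((m - start) %% 12) < len)
        grown <- as.numeric(cm$share[idx] > 0)
      }
      ef <- exposure_features(grid, ch$cell, ch$birth_ym, ch$survey_ym,
                              tr$window, tr$form, tr$edges, tr$omitted,
                              tr$threshold, tr$degree, NULL, season_cal)
      f_true <- f_true + grown * as.numeric(ef$F %*% tr$parameters)
    }
    if (config$age_effect_slope != 0) {
      f_true <- f_true *
        (1 + config$age_effect_slope * (ch$age_months - 36) / 24)
    }
    t0_col <- ch$survey_ym - grid$months[1] + 1L
    t_survey <- grid$temp[cbind(ch$cell, t0_col)]
    p_survey <- grid$precip[cbind(ch$cell, t0_col)]
    p12 <- rowSums(matrix(
      grid$precip[cbind(rep(ch$cell, 12),
                        as.vector(outer(t0_col, 1:12, `-`)))], n, 12))

    nu <- if (any(vapply(truths, function(t) t$window == "survey_month",
                         logical(1)))) 0 else config$nu
    region_fe <- stats::rnorm(n_regions, 0, config$region_fe_sd)
    cy <- interaction(ch$country, ch$survey_year, drop = TRUE)
    cy_fe <- stats::rnorm(nlevels(cy), 0, config$country_year_fe_sd)
    month_fe <- stats::rnorm(12, 0, config$month_fe_sd)

    ch$latent_whz <- config$baseline_z + f_true + nu * t_survey +
      control_effect(ch, config$control_coefs, p_survey, p12) +
      region_fe[ch$region_id] + cy_fe[as.integer(cy)] +
      month_fe[ch$survey_month] + ch$cluster_re +
      stats::rnorm(n, 0, config$noise_sd)
    ch$latent_haz <- stats::rnorm(n, config$haz_mean, config$haz_sd)
  })

  # back-compute raw measurements through the inverse LMS reference
  out <- tibble::tibble(
    child_id = ch$child_id, country = ch$country,
    region = sprintf("C%02d_R%02d", ch$country, ch$region_id),
    cluster = ch$cluster, cell = as.integer(ch$cell),
    lat = ch$lat, lon = ch$lon, urban = ch$urban, sex = ch$sex,
    birth_year = ch$birth_year, birth_month = ch$birth_month,
    survey_year = ch$survey_year, survey_month = ch$survey_month,
    age_months = ch$age_months, mother_edu = ch$mother_edu,
    mother_age = ch$mother_age, birth_order = ch$birth_order,
    sweight = ch$sweight, residence_months = ch$residence_months,
    latent_whz = ch$latent_whz, latent_haz = ch$latent_haz)
  out$height_cm <- NA_real_
  out$weight_kg <- NA_real_
  for (sx in c("male", "female")) {
    i <- which(out$sex == sx)
    hfa <- ref[ref$sex == sx & ref$measure == "height_for_age", ]
    p <- interp_lms(hfa, out$age_months[i])
    out$height_cm[i] <- lms_inverse(out$latent_haz[i], p$L, p$M, p$S)
    wfh <- ref[ref$sex == sx & ref$measure == "weight_for_height", ]
    p <- interp_lms(wfh, out$height_cm[i])
    out$weight_kg[i] <- lms_inverse(out$latent_whz[i], p$L, p$M, p$S)
  }
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}
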