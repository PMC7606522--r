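test_that("crop weights of one reproduce the plain fit; rescaling leaves beta unchanged", {
  g <- small_grid()
  ch <- small_scored()
  cm <- generate_crop_map(crop_map_config(), g, seed = 6)
  cm_one <- cm
  cm_one$share <- 1
  spec <- regression_spec("whz", "degree_month")
  fit_crop <- crop_weighted_fit(ch, g, cm_one, "maize", spec)

  spec_gs <- regression_spec("whz", "degree_month", "growing_season",
                             crop = "maize")
  d <- build_design(ch, g, spec_gs, cm_one)
  fit_plain <- fit_fe_ols(d, spec_gs)
  expect_equal(fit_crop$beta, fit_plain$beta, tolerance = 1e-12)

  cm_half <- cm
  cm_half$share <- cm$share / 2
  f1 <- crop_weighted_fit(ch, g, cm, "maize", spec)
  f2 <- crop_weighted_fit(ch, g, cm_half, "maize", spec)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)

  cm0 <- cm
  cm0$share <- 0
  expect_error(crop_weighted_fit(ch, g, cm0, "maize", spec),
               class = "crop_weight_error")
})

test_that("a single all-inclusive group reproduces the pooled fit; small groups are skipped", {
  d <- small_design("degree_month")
  pooled <- fit_fe_ols(d)
  one <- fit_by_group(d, group = rep("all", nrow(d)))
  expect_equal(one$fit[[1]]$beta, pooled$beta, tolerance = 1e-12)

  g2 <- rep("big", nrow(d))
  g2[1:10] <- "tiny"
  expect_warning(res <- fit_by_group(d, group = g2, min_n = 50), "tiny")
  expect_equal(res$group, "big")
})

test_that("the residence filter keeps exactly the covered children", {
  ch <- small_cohort()
  full <- ch
  full$residence_months <- full$age_months + 1
  expect_equal(nrow(residence_filter(full, "lifetime")), nrow(ch))

  ch2 <- tibble::tibble(age_months = c(24, 30), residence_months = c(6, NA))
  expect_equal(nrow(residence_filter(ch2, "prior_year")), 0)

  got <- residence_filter(ch, "prior_year")
  brute <- sum(!is.na(ch$residence_months) & ch$residence_months >= 12)
  expect_equal(nrow(got), brute)
  got_l <- residence_filter(ch, "lifetime")
  brute_l <- sum(!is.na(ch$residence_months) &
                   ch$residence_months >= ch$age_months)
  expect_equal(nrow(got_l), brute_l)
})

test_that("the cross-sectional quartic fit recovers exact data and matches the F oracle", {
  set.seed(31)
  t <- seq(18, 32, length.out = 15)
  b <- c(1, -0.05, 0.002, -0.0001, 0.000002)
  exact <- tibble::tibble(mean_temp = t,
                          mean_outcome = b[1] + b[2] * t + b[3] * t^2 +
                            b[4] * t^3 + b[5] * t^4,
                          n_obs = sample(50:500, 15))
  fit <- cross_section_fit(exact)
  expect_lt(max(abs(fit$coefficients - b)), 1e-8)

  flat <- exact
  flat$mean_outcome <- 2
  fit0 <- cross_section_fit(flat)
  expect_lt(max(abs(fit0$coefficients[-1])), 1e-10)

  noisy <- exact
  noisy$mean_outcome <- exact$mean_outcome + rnorm(15, 0, 0.3)
  fitn <- cross_section_fit(noisy)
  # weighted ANOVA decomposition oracle
  w <- noisy$n_obs
  m0 <- lm(mean_outcome ~ 1, data = noisy, weights = w)
  rss0 <- sum(w * resid(m0)^2)
  rss1 <- sum(w * resid(fitn$lm)^2)
  f_oracle <- ((rss0 - rss1) / 4) / (rss1 / (15 - 5))
  expect_equal(fitn$f_statistic, f_oracle, tolerance = 1e-10)

  expect_error(cross_section_fit(exact[1:5, ]), class = "cross_section_error")
})

test_that("regional summaries feed the cross-section pipeline", {
  rs <- regional_summary(small_scored(), small_grid())
  expect_equal(nrow(rs), length(unique(small_scored()$region)))
  expect_true(all(c("mean_temp", "mean_outcome", "n_obs") %in% names(rs)))
  fit <- cross_section_fit(rs)
  expect_s3_class(fit, "cross_section_fit")
  expect_true(is.finite(fit$f_statistic))
})

test_that("an age-intensifying injected effect yields ordered age-band estimates", {
  g <- small_grid()
  cfg <- cohort_config(n_countries = 5, regions_per_country = 4,
                       clusters_per_region = 25, children_per_cluster = 40,
                       survey_years = 2008:2012, age_effect_slope = 0.8)
  tr <- true_response("degree_month", c(degree_months = -0.03))
  bands <- function(a) cut(a, c(11, 24, 42, 59), labels = c("b1", "b2", "b3"))
  ordered <- vapply(1:20, function(r) {
    ch <- score_cohort(generate_cohort(cfg, g, tr, seed = 900 + r))
    d <- build_design(ch, g, regression_spec("whz", "degree_month",
                                             "prior_year"))
    gb <- suppressWarnings(fit_by_group(
      d, group = as.character(bands(d$age_months))))
    est <- vapply(gb$fit, function(f) f$beta[["degree_months"]],
                  numeric(1))[order(gb$group)]
    all(diff(est) < 0)  # damage intensifies with age band
  }, logical(1))
  expect_gte(mean(ordered), 0.9)
})
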