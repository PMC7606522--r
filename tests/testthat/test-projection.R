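proj_fixture <- function() {
  memo("proj_fixture", function() {
    g <- small_grid()
    ch <- small_scored()
    fit <- fit_fe_ols(small_design("polynomial"))
    regions <- tibble::tibble(
      cell = g$cells$cell,
      region = rep(c("west", "central", "east", "south"),
                   length.out = nrow(g$cells)))
    baseline <- tibble::tibble(
      region = rep(c("west", "central", "east", "south"),
                   length.out = nrow(ch)),
      whz = ch$whz, sweight = ch$sweight)
    list(g = g, fit = fit, regions = regions, baseline = baseline)
  })
}

test_that("response curves vanish at the reference and with zero coefficients", {
  fx <- proj_fixture()
  rc <- response_curve(fx$fit, temps = c(20, 25, 30))
  expect_equal(rc$effect[rc$temp == 25], 0)
  expect_equal(rc$se[rc$temp == 25], 0)

  flat <- response_curve(fake_poly_fit(c(0, 0, 0, 0)), temps = seq(15, 35))
  expect_true(all(flat$effect == 0))
  expect_true(all(flat$se == 0))
  expect_warning(response_curve(fx$fit, temps = c(25, 60)), "physical")
})

test_that("degree-month and binned response curves use the right contrasts", {
  d <- small_design("degree_month")
  fit <- fit_fe_ols(d)
  rc <- response_curve(fit, temps = c(20, 25, 28))
  b <- fit$beta[["degree_months"]]
  expect_equal(rc$effect, c(0, 0, 3 * b), tolerance = 1e-12)

  db <- small_design("binned")
  fb <- fit_fe_ols(db)
  rcb <- response_curve(fb, temps = c(25, 27))
  expect_equal(rcb$effect, c(0, unname(fb$beta["bin_26_28"])),
               tolerance = 1e-12)
})

test_that("annual shifts follow the per-month polynomial difference", {
  base <- rep(25, 12)
  expect_equal(delta_whz(c(1, 0, 0, 0), base, base), 0)
  expect_equal(delta_whz(c(-0.01, 0, 0, 0), base + 1, base), 12 * -0.01,
               tolerance = 1e-12)
  set.seed(7)
  b <- rnorm(4, 0, 0.01)
  y1 <- runif(12, 20, 32); y0 <- runif(12, 20, 32)
  brute <- sum(sapply(1:12, function(m) {
    sum(b * y1[m]^(1:4)) - sum(b * y0[m]^(1:4))
  }))
  expect_equal(delta_whz(b, y1, y0), brute, tolerance = 1e-12)
  expect_error(delta_whz(b, y1[1:10], y0), class = "projection_input_error")
})

test_that("distribution shifts are uniform translations", {
  set.seed(8)
  z <- rnorm(500, -1, 1)
  expect_identical(shift_distribution(z, 0), z)
  w <- runif(500, 0.5, 2)
  m0 <- weighted.mean(z, w)
  expect_equal(weighted.mean(shift_distribution(z, -1), w), m0 - 1,
               tolerance = 1e-12)
  # prevalence after a shift equals the per-child recount
  for (delta in c(-0.4, 0.25)) {
    shifted <- shift_distribution(z, delta)
    expect_equal(weighted_prevalence(shifted, weights = w),
                 sum(w * (z + delta < -2)) / sum(w), tolerance = 1e-12)
  }
})

test_that("zero warming and zero response conserve the baseline trajectory", {
  fx <- proj_fixture()
  flat <- generate_projection_series(fx$regions, fx$g, warming_per_decade = 0,
                                     years = 2015:2030)
  tr <- wasting_trajectory(fx$fit, flat, fx$baseline)
  expect_equal(max(abs(tr$pct_change)), 0)
  expect_true(all(tr$prevalence >= 0 & tr$prevalence <= 1))

  warm <- generate_projection_series(fx$regions, fx$g, 0.5, years = 2015:2030)
  tr0 <- wasting_trajectory(fake_poly_fit(c(0, 0, 0, 0)), warm, fx$baseline)
  expect_equal(max(abs(tr0$pct_change)), 0)
  # the baseline year is anchored at exactly zero percent change
  tr1 <- wasting_trajectory(fx$fit, warm, fx$baseline)
  expect_equal(tr1$pct_change[tr1$year == 2015], rep(0, 4))
})

test_that("monotone harm plus monotone warming gives non-decreasing prevalence", {
  fx <- proj_fixture()
  warm <- generate_projection_series(fx$regions, fx$g, 0.4, years = 2015:2060)
  harm <- fake_poly_fit(c(-0.01, 0, 0, 0))
  tr <- wasting_trajectory(harm, warm, fx$baseline)
  for (r in unique(tr$region)) {
    expect_true(all(diff(tr$prevalence[tr$region == r]) >= 0))
  }
})

test_that("vectorized trajectories equal a per-child brute force", {
  fx <- proj_fixture()
  small <- fx$baseline[sample(nrow(fx$baseline), 800), ]
  warm <- generate_projection_series(fx$regions, fx$g, 0.5,
                                     years = c(2015, 2040, 2080))
  b <- unname(fx$fit$beta[fx$fit$feature_names])
  tr <- wasting_trajectory(fx$fit, warm, small)
  for (r in unique(small$region)) {
    bl <- small[small$region == r, ]
    base_series <- warm$temp[warm$region == r & warm$year == 2015]
    for (yy in c(2040, 2080)) {
      ys <- warm$temp[warm$region == r & warm$year == yy]
      delta <- delta_whz(b, ys, base_series)
      prev <- sum(bl$sweight * (bl$whz + delta < -2)) / sum(bl$sweight)
      got <- tr$prevalence[tr$region == r & tr$year == yy]
      expect_equal(got, prev, tolerance = 1e-12)
    }
  }
})

test_that("parameter-uncertainty bands are seeded, contain the point estimate, and collapse at zero vcov", {
  fx <- proj_fixture()
  warm <- generate_projection_series(fx$regions, fx$g, 0.5,
                                     years = seq(2015, 2055, by = 10))
  pw1 <- project_wasting(fx$fit, warm, fx$baseline, n_draws = 400, seed = 9)
  pw2 <- project_wasting(fx$fit, warm, fx$baseline, n_draws = 400, seed = 9)
  expect_identical(pw1$lo, pw2$lo)
  expect_identical(pw1$hi, pw2$hi)
  expect_true(all(pw1$lo <= pw1$pct_change + 1e-9 &
                    pw1$pct_change - 1e-9 <= pw1$hi))

  degen <- fake_poly_fit(unname(fx$fit$beta[fx$fit$feature_names]))
  ci0 <- parameter_uncertainty_ci(degen, warm, fx$baseline, n_draws = 200,
                                  seed = 2)
  tr <- wasting_trajectory(degen, warm, fx$baseline)
  expect_equal(ci0$lo, tr$pct_change, tolerance = 1e-10)
  expect_equal(ci0$hi, tr$pct_change, tolerance = 1e-10)
  expect_error(parameter_uncertainty_ci(fx$fit, warm, fx$baseline,
                                        n_draws = 10),
               class = "projection_input_error")
})

test_that("autoplot methods return ggplot objects", {
  fx <- proj_fixture()
  rc <- response_curve(fx$fit)
  expect_s3_class(ggplot2::autoplot(rc), "ggplot")
  warm <- generate_projection_series(fx$regions, fx$g, 0.5,
                                     years = c(2015, 2050))
  pw <- project_wasting(fx$fit, warm, fx$baseline, n_draws = 200, seed = 1)
  expect_s3_class(ggplot2::autoplot(pw), "ggplot")
  cs <- cross_section_fit(regional_summary(small_scored(), small_grid()))
  expect_s3_class(ggplot2::autoplot(cs), "ggplot")
})
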