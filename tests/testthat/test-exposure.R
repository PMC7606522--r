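test_that("points map to cells by the half-open convention", {
  g <- small_grid()
  # exact cell centers map to their own cell
  i <- c(1L, 17L, 100L)
  expect_equal(match_to_cell(g$cells$lat[i], g$cells$lon[i], g), i)
  # a point exactly on a shared edge belongs to the higher-indexed cell
  lat_edge <- g$cells$lat[1] + g$res / 2
  hit <- match_to_cell(lat_edge, g$cells$lon[1], g)
  expect_equal(g$cells$lat[hit], g$cells$lat[1] + g$res)
  expect_error(match_to_cell(89, 0, g), class = "coverage_error")

  # random interior points agree with brute-force nearest-center search
  set.seed(21)
  lat <- runif(1000, min(g$cells$lat) - 0.249, max(g$cells$lat) + 0.249)
  lon <- runif(1000, min(g$cells$lon) - 0.249, max(g$cells$lon) + 0.249)
  got <- match_to_cell(lat, lon, g)
  brute <- vapply(seq_along(lat), function(k) {
    which.min((g$cells$lat - lat[k])^2 + (g$cells$lon - lon[k])^2)
  }, integer(1))
  expect_equal(got, brute)
})

test_that("exposure windows follow the stated calendar conventions", {
  s <- ym_index(2010, 6)
  pw <- resolve_window("prior_year", NA, s)
  expect_equal(length(pw), 12)
  expect_equal(range(pw), c(ym_index(2009, 6), ym_index(2010, 5)))
  expect_equal(resolve_window("survey_month", NA, s), s)

  b <- ym_index(2008, 3)
  lt <- resolve_window("lifetime", b, ym_index(2010, 3))
  expect_equal(length(lt), 25)  # inclusive of birth and interview months

  t1 <- resolve_window("trimester1", b, s)
  t2 <- resolve_window("trimester2", b, s)
  t3 <- resolve_window("trimester3", b, s)
  expect_equal(length(c(t1, t2, t3)), 9)
  expect_equal(sort(c(t1, t2, t3)), seq(b - 9, b - 1))  # partition, disjoint
})

test_that("binned counts conserve the window length and match a histogram loop", {
  expect_true(all(binned_month_counts(rep(25, 12)) == 0))
  expect_true(all(binned_month_counts(numeric(0)) == 0))
  set.seed(3)
  for (i in 1:10) {
    x <- runif(24, 8, 40)
    counts <- binned_month_counts(x)
    edges <- default_bin_edges()
    brute <- integer(length(edges) + 1)
    for (t in x) {
      b <- sum(t >= edges) + 1
      brute[b] <- brute[b] + 1
    }
    names(brute) <- c("bin_lt14", paste0("bin_", edges[-length(edges)], "_",
                                         edges[-1]), "bin_ge34")
    expect_equal(counts, brute[names(counts)])
    expect_equal(sum(counts) + brute[["bin_24_26"]], length(x))
  }
})

test_that("degree-months follow the hinge sum and its translation property", {
  expect_equal(degree_months(c(24, 25, 20)), 0)
  expect_equal(degree_months(c(26, 24, 30)), 6)
  set.seed(4)
  for (i in 1:20) {
    x <- runif(12, 15, 35)
    expect_equal(degree_months(x), sum(pmax(0, x - 25)), tolerance = 1e-12)
  }
  # adding a constant when all months already exceed the threshold
  hot <- runif(12, 26, 35)
  expect_equal(degree_months(hot + 0.7), degree_months(hot) + 12 * 0.7,
               tolerance = 1e-12)
  expect_identical(degree_months(c(20, 24.9, 25)), 0)
})

test_that("polynomial exposures are power sums or powers of the window mean", {
  expect_equal(unname(polynomial_exposure(10)), c(10, 100, 1000, 10000))
  x <- rep(3, 5)
  expect_equal(unname(polynomial_exposure(x)), 5 * c(3, 9, 27, 81))
  expect_equal(unname(polynomial_exposure(x, mode = "window_mean")),
               c(3, 9, 27, 81))
  set.seed(5)
  y <- runif(12, 15, 35)
  expect_equal(unname(polynomial_exposure(y)),
               c(sum(y), sum(y^2), sum(y^3), sum(y^4)), tolerance = 1e-12)
  expect_error(polynomial_exposure(numeric(0)), class = "exposure_input_error")
})

test_that("growing-season windows are the season months of the prior year", {
  g <- small_grid()
  cm <- tibble::tibble(cell = 1L, crop = "maize", share = 0.4,
                       season_start = 6L, season_len = 3L)
  # survey Mar 2010, season Jun-Aug -> Jun-Aug 2009
  w <- growing_season_window(1, "maize", cm, ym_index(2010, 3))
  expect_equal(sort(w), ym_index(2009, 6:8))
  # full-year season equals the prior-year window
  cm12 <- tibble::tibble(cell = 1L, crop = "maize", share = 0.4,
                         season_start = 1L, season_len = 12L)
  expect_equal(sort(growing_season_window(1, "maize", cm12, ym_index(2010, 3))),
               resolve_window("prior_year", NA, ym_index(2010, 3)))
  # zero share signals exclusion
  cm0 <- tibble::tibble(cell = 1L, crop = "maize", share = 0,
                        season_start = 6L, season_len = 3L)
  expect_length(growing_season_window(1, "maize", cm0, ym_index(2010, 3)), 0)

  # containment: windows always sit inside the 12 pre-interview months
  cmap <- generate_crop_map(crop_map_config(), g, seed = 6)
  ch <- small_cohort()
  for (i in sample(nrow(ch), 50)) {
    s <- ym_index(ch$survey_year[i], ch$survey_month[i])
    w <- growing_season_window(ch$cell[i], "maize", cmap, s)
    if (length(w) > 0) {
      expect_true(all(w >= s - 12 & w <= s - 1))
    }
  }
})
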