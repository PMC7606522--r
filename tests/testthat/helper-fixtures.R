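# Shared small fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_grid <- function() {
  memo("small_grid", function() {
    generate_climate_grid(
      climate_config(lat_range = c(-12, -6.5), lon_range = c(20, 25.5),
                     start = c(1998, 1), end = c(2012, 12)),
      seed = 7)
  })
}

small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- cohort_config(n_countries = 4, regions_per_country = 3,
                         clusters_per_region = 8, children_per_cluster = 25,
                         survey_years = 2008:2012)
    generate_cohort(cfg, small_grid(), true_response("degree_month"),
                    seed = 3)
  })
}

small_scored <- function() {
  memo("small_scored", function() score_cohort(small_cohort()))
}

small_design <- function(form = "degree_month", window = "prior_year") {
  key <- paste0("design_", form, "_", window)
  memo(key, function() {
    build_design(small_scored(), small_grid(),
                 regression_spec("whz", form, window))
  })
}

# a minimal hand-made fe_fit for projection unit tests
fake_poly_fit <- function(beta, V = diag(length(beta)) * 0) {
  nm <- paste0("temp_p", seq_along(beta))
  names(beta) <- nm
  dimnames(V) <- list(nm, nm)
  structure(list(beta = beta, vcov = V, se = sqrt(diag(V)),
                 n_obs = NA_integer_, n_clusters = 10L,
                 feature_names = nm,
                 spec = regression_spec("whz", "polynomial", "prior_year",
                                        degree = length(beta))),
            class = "fe_fit")
}

# independent per-cluster sandwich oracle (explicit loop, CR1 optional)
brute_cluster_vcov <- function(X, e, cl, w, cr1 = TRUE, K = ncol(X)) {
  X <- as.matrix(X)
  XtWX <- t(X) %*% diag(w) %*% X
  bread <- solve(XtWX)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    i <- which(cl == g)
    sg <- t(X[i, , drop = FALSE]) %*% (w[i] * e[i])
    meat <- meat + sg %*% t(sg)
  }
  V <- bread %*% meat %*% bread
  if (cr1) {
    G <- length(unique(cl)); N <- nrow(X)
    V <- V * (G / (G - 1)) * ((N - 1) / (N - K))
  }
  (V + t(V)) / 2
}
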