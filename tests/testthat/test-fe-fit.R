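rand_design <- function(n = 200, seed = 1, p = 3) {
  set.seed(seed)
  list(
    X = matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))),
    y = rnorm(n),
    w = runif(n, 0.5, 2),
    fe = data.frame(f1 = sample(letters[1:6], n, TRUE),
                    f2 = sample(LETTERS[1:5], n, TRUE),
                    f3 = sample(1:4, n, TRUE)),
    cl = sample(paste0("g", 1:8), n, TRUE)
  )
}

test_that("single-dimension demeaning zeroes weighted group means in one pass", {
  d <- rand_design(150, 2)
  out <- within_transform(d$X, d$fe["f1"], d$w)
  expect_equal(attr(out, "iter"), 1L)
  for (lev in unique(d$fe$f1)) {
    i <- d$fe$f1 == lev
    expect_lt(max(abs(colSums(out[i, ] * d$w[i]) / sum(d$w[i]))), 1e-12)
  }
  # idempotent at convergence
  out2 <- within_transform(out, d$fe["f1"], d$w)
  expect_equal(unclass(out2), unclass(out), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a column constant within every group is annihilated", {
  d <- rand_design(120, 3)
  X <- cbind(d$X, absorbed = as.numeric(factor(d$fe$f1)))
  out <- within_transform(X, d$fe["f1"], d$w)
  expect_lt(max(abs(out[, "absorbed"])), 1e-12)
})

test_that("absorbed-FE regression equals explicit dummy-variable OLS (FWL)", {
  for (seed in 1:5) {
    d <- rand_design(200, seed)
    Xd <- within_transform(cbind(y = d$y, d$X), d$fe, d$w, tol = 1e-12)
    beta <- wls_solve(Xd[, 1], Xd[, -1], d$w)
    oracle <- lm(d$y ~ d$X + factor(d$fe$f1) + factor(d$fe$f2) +
                   factor(d$fe$f3), weights = d$w)
    expect_lt(max(abs(beta - coef(oracle)[paste0("d$Xx", 1:3)])), 1e-8)
  }
})

test_that("non-convergence is an error carrying the residual mean", {
  d <- rand_design(200, 4)
  expect_error(within_transform(d$X, d$fe, d$w, tol = 1e-12, max_iter = 1),
               class = "fe_convergence_error")
})

test_that("weighted least squares is exact, weight-scale invariant, and rank-checked", {
  set.seed(10)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  beta_true <- c(2, -3)
  y <- as.vector(X %*% beta_true)
  w <- runif(50, 0.1, 4)
  expect_equal(unname(wls_solve(y, X, w)), beta_true, tolerance = 1e-10)
  y2 <- y + rnorm(50)
  expect_equal(wls_solve(y2, X, w), wls_solve(y2, X, 7 * w), tolerance = 1e-12)
  oracle <- solve(t(X) %*% diag(w) %*% X, t(X) %*% (w * y2))
  expect_lt(max(abs(wls_solve(y2, X, w) - oracle)), 1e-10)
  X3 <- cbind(X, dup = X[, 1] * 2)
  expect_error(wls_solve(y2, X3, w), "dup", class = "fe_rank_error")
})

test_that("cluster-robust covariance matches the explicit sandwich oracle", {
  set.seed(12)
  n <- 50
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  e <- rnorm(n)
  w <- runif(n, 0.5, 2)
  cl <- sample(paste0("c", 1:5), n, TRUE)
  V <- cluster_robust_vcov(X, e, cl, w)
  expect_lt(max(abs(V - brute_cluster_vcov(X, e, cl, w))), 1e-12)
  # zero residuals give a zero matrix
  expect_equal(max(abs(cluster_robust_vcov(X, rep(0, n), cl, w))), 0)
  # one observation per cluster without the correction is HC0
  own <- as.character(1:n)
  V0 <- cluster_robust_vcov(X, e, own, w, cr1 = FALSE)
  bread <- solve(t(X) %*% diag(w) %*% X)
  hc0 <- bread %*% (t(X) %*% diag((w * e)^2) %*% X) %*% bread
  expect_lt(max(abs(V0 - hc0)), 1e-12)
  expect_error(cluster_robust_vcov(X, e, rep("a", n), w),
               class = "fe_cluster_error")
})

test_that("a constant outcome produces zero slopes", {
  d <- small_design("degree_month")
  d2 <- d
  d2$whz <- 1.7
  for (a in c("feature_cols", "control_cols", "spec")) {
    attr(d2, a) <- attr(d, a)
  }
  fit <- suppressWarnings(fit_fe_ols(d2))
  expect_lt(max(abs(fit$beta)), 1e-8)
})

test_that("the fitted degree-month effect recovers the injected response", {
  fit <- fit_fe_ols(small_design("degree_month"))
  truth <- attr(small_cohort(), "truth")$parameters[["degree_months"]]
  est <- fit$beta[["degree_months"]]
  se <- fit$se[["degree_months"]]
  expect_lt(abs(est - truth), 4 * se)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, nrow(small_design("degree_month")))
  td <- tidy(fit, conf.int = TRUE)
  expect_true(all(c("estimate", "std.error", "conf.low") %in% names(td)))
  expect_equal(glance(fit)$n_clusters, fit$n_clusters)
})

test_that("the joint Wald test has its closed-form special cases", {
  f0 <- fake_poly_fit(c(0, 0, 0, 0), diag(4))
  wt <- wald_joint_test(f0)
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p.value, 1)
  # scalar subset equals the squared z statistic
  fit <- fit_fe_ols(small_design("degree_month"))
  w1 <- wald_joint_test(fit, "degree_months")
  z <- fit$beta[["degree_months"]] / fit$se[["degree_months"]]
  expect_equal(w1$statistic, z^2, tolerance = 1e-10)
  expect_equal(w1$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_error(wald_joint_test(fit, character(0)), class = "wald_error")
})
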