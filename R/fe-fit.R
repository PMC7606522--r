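#' Weighted within-group demeaning (alternating projections)
#'
#' Removes high-dimensional fixed effects from a set of columns by
#' iterated weighted group demeaning: each sweep subtracts, for every
#' fixed-effect dimension in turn, the weighted group mean of every
#' column. Sweeps repeat until the maximum absolute weighted group mean
#' across all dimensions and columns falls below `tol` (with a single
#' dimension one pass suffices and the transform is idempotent).
#' Exceeding `max_iter` is an error — never a silent return — carrying the
#' residual mean reached.
#'
#' @param x Numeric matrix (rows = observations) to demean.
#' @param fe Data frame of fixed-effect labels, one column per dimension.
#' @param w Positive weights.
#' @param tol Convergence tolerance on weighted group means (same scale as
#'   `x`; callers wanting scale-free behaviour should pass unit-scaled
#'   columns, as [fit_fe_ols()] does).
#' @param max_iter Sweep cap.
#' @return The demeaned matrix with attributes `iter` (sweeps used) and
#'   `max_dev` (final maximum absolute group mean).
#' @export
within_transform <- function(x, fe, w = rep(1, nrow(x)), tol = 1e-10,
                             max_iter = 10000) {
  x <- as.matrix(x)
  fe <- as.data.frame(fe)
  if (any(w <= 0)) abort_hg("weights must be positive", "fe_input_error")
  if (any(vapply(fe, function(f) any(is.na(f)), logical(1)))) {
    abort_hg("every row must carry all FE labels", "fe_input_error")
  }
  groups <- lapply(fe, function(f) as.integer(factor(f)))
  wsums <- lapply(groups, function(g) rowsum(w, g))

  max_dev <- Inf
  iter <- 0L
  while (max_dev >= tol && iter < max_iter) {
    iter <- iter + 1L
    for (d in seq_along(groups)) {
      g <- groups[[d]]
      gm <- rowsum(x * w, g) / as.vector(wsums[[d]])
      x <- x - gm[g, , drop = FALSE]
    }
    max_dev <- 0
    for (d in seq_along(groups)) {
      g <- groups[[d]]
      gm <- rowsum(x * w, g) / as.vector(wsums[[d]])
      dev <- max(abs(gm))
      if (dev > max_dev) max_dev <- dev
    }
  }
  if (max_dev >= tol) {
    abort_hg(sprintf(
      "within_transform did not converge in %d sweeps (residual mean %.3e)",
      max_iter, max_dev), "fe_convergence_error")
  }
  attr(x, "iter") <- iter
  attr(x, "max_dev") <- max_dev
  x
}

#' Weighted least squares via QR
#'
#' Minimizes `sum(w * (y - X b)^2)` through a QR decomposition of the
#' weight-scaled, column-equilibrated design (numerically stable even for
#' raw quartic temperature columns). Invariant to rescaling all weights by
#' a positive constant. Rank deficiency is an error naming the collinear
#' columns.
#'
#' @param y Response vector.
#' @param X Numeric matrix with column names.
#' @param w Positive weights.
#' @return Named coefficient vector.
#' @export
wls_solve <- function(y, X, w = rep(1, length(y))) {
  X <- as.matrix(X)
  if (any(w <= 0)) abort_hg("weights must be positive", "fe_input_error")
  sw <- sqrt(w)
  s <- apply(X, 2, function(col) max(abs(col)))
  s[s == 0] <- 1
  Xs <- sweep(X, 2, s, "/")
  qrx <- qr(Xs * sw)
  p <- ncol(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    abort_hg(paste("design is rank deficient; collinear columns:",
                   paste(bad, collapse = ", ")), "fe_rank_error")
  }
  b <- qr.coef(qrx, y * sw) / s
  stats::setNames(as.numeric(b), colnames(X))
}

#' Cluster-robust sandwich covariance
#'
#' The CR sandwich `(X'WX)^{-1} [ sum_g s_g s_g' ] (X'WX)^{-1}` with
#' cluster score `s_g = X_g' W_g e_g`, optionally scaled by the CR1
#' small-sample factor `G/(G-1) * (N-1)/(N-K)`. With every observation its
#' own cluster and the correction off this reduces to the HC0
#' heteroskedasticity-robust form.
#'
#' @param X Demeaned regressor matrix.
#' @param residuals Residual vector.
#' @param clusters Cluster labels (>= 2 distinct values).
#' @param w Positive weights.
#' @param cr1 Apply the CR1 small-sample factor?
#' @param K Parameters estimated, for the degrees-of-freedom factor;
#'   defaults to `ncol(X)`. [fit_fe_ols()] passes slopes + absorbed fixed
#'   effects.
#' @return Symmetric covariance matrix for the coefficient vector.
#' @export
cluster_robust_vcov <- function(X, residuals, clusters, w = rep(1, nrow(X)),
                                cr1 = TRUE, K = ncol(X)) {
  X <- as.matrix(X)
  g <- factor(clusters)
  G <- nlevels(g)
  if (G < 2) abort_hg("cluster-robust inference needs >= 2 clusters",
                      "fe_cluster_error")
  N <- nrow(X)
  # column equilibration for numerical stability; undone at the end
  s <- apply(X, 2, function(col) max(abs(col)))
  s[s == 0] <- 1
  Xs <- sweep(X, 2, s, "/")
  bread <- solve(crossprod(Xs, Xs * w))
  S <- rowsum(Xs * (w * residuals), g)         # G x p cluster score sums
  meat <- crossprod(S)
  V <- bread %*% meat %*% bread
  V <- V / tcrossprod(s)
  if (cr1) V <- V * (G / (G - 1)) * ((N - 1) / (N - K))
  (V + t(V)) / 2
}

#' Fit the fixed-effects temperature regression
#'
#' End-to-end weighted estimation of one [regression_spec()]: unit-scales
#' the regressors, absorbs the fixed-effect dimensions by
#' [within_transform()] (outcome and regressors jointly), solves the
#' weighted least-squares problem, recomputes residuals on the demeaned
#' data, and forms the cluster-robust covariance with the CR1 correction
#' (degrees of freedom count slopes plus absorbed fixed effects).
#' By the Frisch-Waugh-Lovell theorem the slope estimates equal those of
#' the explicit dummy-variable regression.
#'
#' @param design Design tibble from [build_design()].
#' @param spec A [regression_spec()]; defaults to the one attached to the
#'   design.
#' @param weights Optional replacement weights (e.g. sampling weight times
#'   crop share); default the spec's weight column.
#' @param cr1 Apply the CR1 small-sample factor (default yes).
#' @return An object of class `fe_fit`: list with `beta`, `vcov`, `se`,
#'   `n_obs`, `n_clusters`, `n_fe_absorbed`, `df_K`, `converged`, `iter`,
#'   `feature_names`, and the `spec`. Methods: `print`, `tidy`, `glance`,
#'   `confint`, [wald_joint_test()], [response_curve()].
#' @export
fit_fe_ols <- function(design, spec = attr(design, "spec"), weights = NULL,
                       cr1 = TRUE) {
  stopifnot(inherits(spec, "regression_spec"))
  feat <- attr(design, "feature_cols")
  ctl <- attr(design, "control_cols")
  xcols <- c(feat, ctl)
  if (is.null(feat) || !all(xcols %in% names(design))) {
    abort_hg("design lacks feature/control metadata; use build_design()",
             "design_error")
  }
  y <- design[[spec$outcome]]
  X <- as.matrix(design[, xcols, drop = FALSE])
  w <- weights %||% design[[spec$weight_col]]
  fe <- design[, spec$fe_dims, drop = FALSE]
  cl <- design[[spec$cluster_dim]]

  # unit-scale columns so the demeaning tolerance is scale-free
  s <- apply(X, 2, function(col) max(abs(col)))
  s[s == 0] <- 1
  M <- cbind(y = y / max(abs(y), 1), sweep(X, 2, s, "/"))
  Md <- within_transform(M, fe, w, tol = spec$demean_tol,
                         max_iter = spec$max_iter)
  yd <- Md[, 1] * max(abs(y), 1)
  Xs <- Md[, -1, drop = FALSE]
  colnames(Xs) <- xcols

  # Rank check after demeaning (pivoted QR): control columns absorbed by,
  # or collinear given, the fixed effects are dropped with a warning —
  # common in small subsamples where cluster-level controls exceed the
  # residual degrees of freedom. A redundant temperature feature means the
  # design cannot identify the effect and is an error.
  qrx <- qr(Xs * sqrt(w))
  if (qrx$rank < ncol(Xs)) {
    bad <- xcols[qrx$pivot[(qrx$rank + 1):ncol(Xs)]]
    if (any(bad %in% feat)) {
      abort_hg(paste("temperature features collinear after FE absorption:",
                     paste(intersect(bad, feat), collapse = ", ")),
               "fe_rank_error")
    }
    warning(sprintf("controls collinear with fixed effects dropped: %s",
                    paste(bad, collapse = ", ")))
    keep_col <- !(xcols %in% bad)
    xcols <- xcols[keep_col]
    ctl <- setdiff(xcols, feat)
    Xs <- Xs[, keep_col, drop = FALSE]
    s <- s[keep_col]
  }
  Xd <- sweep(Xs, 2, s, "*")
  colnames(Xd) <- xcols

  beta <- wls_solve(yd, Xd, w)
  e <- yd - as.vector(Xd %*% beta)

  n_levels <- vapply(fe, function(f) length(unique(f)), integer(1))
  n_fe <- sum(n_levels) - (length(n_levels) - 1L)
  # dof for the CR1 correction: absorbed FE dimensions nested within the
  # clusters do not reduce the effective cluster-level degrees of freedom
  # (the convention of standard HDFE software)
  nested <- vapply(fe, function(f) {
    all(rowSums(table(f, cl) > 0) == 1)
  }, logical(1))
  n_counted <- sum(n_levels[!nested])
  if (any(!nested)) n_counted <- n_counted - (sum(!nested) - 1L)
  K <- length(beta) + n_counted
  V <- cluster_robust_vcov(Xd, e, cl, w, cr1 = cr1, K = K)
  dimnames(V) <- list(xcols, xcols)

  structure(list(
    beta = beta, vcov = V, se = sqrt(diag(V)),
    n_obs = nrow(design), n_clusters = length(unique(cl)),
    n_fe_absorbed = n_fe, df_K = K,
    converged = TRUE, iter = attr(Md, "iter"),
    demean_max_dev = attr(Md, "max_dev"),
    feature_names = feat, control_names = ctl, spec = spec,
    weights_used = if (is.null(weights)) spec$weight_col else "custom"),
    class = "fe_fit")
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf(
    "<fe_fit> %s ~ %s(%s) | %s  (n = %d, clusters = %d, FE absorbed = %d)\n",
    x$spec$outcome, x$spec$form, x$spec$window,
    paste(x$spec$fe_dims, collapse = " + "),
    x$n_obs, x$n_clusters, x$n_fe_absorbed))
  tt <- cbind(estimate = x$beta[x$feature_names],
              std.error = x$se[x$feature_names])
  print(round(tt, 6))
  invisible(x)
}

#' Tidy and glance methods for fitted temperature regressions
#'
#' `tidy()` returns one row per coefficient with cluster-robust standard
#' errors, t statistics and p-values on `G - 1` degrees of freedom (G =
#' number of clusters). `glance()` returns one row of fit metadata.
#'
#' @param x An `fe_fit`.
#' @param conf.int Add a confidence interval?
#' @param conf.level Coverage for the interval.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @method tidy fe_fit
#' @export
tidy.fe_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  df <- x$n_clusters - 1
  out <- tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = 2 * stats::pt(abs(unname(x$beta / x$se)), df, lower.tail = FALSE))
  if (conf.int) {
    q <- stats::qt(1 - (1 - conf.level) / 2, df)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  out
}

#' @rdname tidy.fe_fit
#' @importFrom generics glance
#' @method glance fe_fit
#' @export
glance.fe_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
                 n_fe_absorbed = x$n_fe_absorbed, df_K = x$df_K,
                 converged = x$converged, demean_sweeps = x$iter)
}

#' @export
confint.fe_fit <- function(object, parm = NULL, level = 0.95, ...) {
  td <- tidy.fe_fit(object, conf.int = TRUE, conf.level = level)
  if (!is.null(parm)) td <- td[td$term %in% parm, ]
  m <- cbind(td$conf.low, td$conf.high)
  dimnames(m) <- list(td$term,
                      paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %"))
  m
}

#' Joint Wald test on a coefficient subset
#'
#' `W = b_s' V_s^{-1} b_s` for the selected coefficients with their
#' cluster-robust covariance block, referred to a chi-square distribution
#' with `|s|` degrees of freedom. Used for the joint significance of the
#' polynomial temperature terms.
#'
#' @param fit An `fe_fit`.
#' @param terms Coefficient names; default the temperature features.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
wald_joint_test <- function(fit, terms = fit$feature_names) {
  if (length(terms) == 0) abort_hg("empty coefficient subset", "wald_error")
  if (!all(terms %in% names(fit$beta))) {
    abort_hg("unknown coefficient names", "wald_error")
  }
  b <- fit$beta[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  # solve in correlation form: W is invariant to diagonal rescaling and the
  # raw quartic block is badly scaled
  s <- sqrt(diag(V))
  if (any(s == 0)) abort_hg("singular covariance block in Wald test", "wald_error")
  R <- V / tcrossprod(s)
  W <- tryCatch(as.numeric(crossprod(b / s, solve(R, b / s))),
                error = function(e) {
                  abort_hg("singular covariance block in Wald test", "wald_error")
                })
  tibble::tibble(statistic = W, df = length(terms),
                 p.value = stats::pchisq(W, length(terms), lower.tail = FALSE))
}
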