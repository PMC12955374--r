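#' Centered natural cubic spline basis for the lag-response function
#'
#' The lag-response over the four decade windows is modeled by a natural
#' cubic spline with internal knots at windows 2 and 3 and boundary knots at
#' 1 and 4, without an intercept (basis dimension 3). The basis is then
#' centered at window 1 (`b_k(t) <- b_k(t) - b_k(1)`) so that every basis
#' function vanishes exactly at the first window: exposures in the 1--10-year
#' prodromal period are constrained to a null effect.
#'
#' @param knots Internal knots (default `c(2, 3)`).
#' @param boundary Boundary knots (default `c(1, 4)`).
#' @return A `lag_basis` object with the 4 x 3 window matrix (`$matrix`), an
#'   `$eval(t)` function for arbitrary points in `[1, 4]`, and the knots.
#' @export
lag_basis <- function(knots = c(2, 3), boundary = c(1, 4)) {
  if (any(knots <= boundary[1]) || any(knots >= boundary[2]))
    stop_config("internal knots must lie strictly inside the boundary knots")
  ns_obj <- splines::ns(seq(boundary[1], boundary[2]), knots = knots,
                        Boundary.knots = boundary)
  at1 <- predict(ns_obj, boundary[1])
  B <- predict(ns_obj, 1:4)
  B <- sweep(B, 2, at1)
  B[1, ] <- 0  # exact, not just numerically zero
  dimnames(B) <- list(paste0("window", 1:4), paste0("b", 1:3))
  ev <- function(t) {
    stopifnot(all(t >= boundary[1] & t <= boundary[2]))
    sweep(predict(ns_obj, t), 2, at1)
  }
  structure(list(matrix = B, knots = knots, boundary = boundary, eval = ev),
            class = "lag_basis")
}

#' Cross-basis of window exposures with the lag basis
#'
#' Linear exposure-response tensored with the spline lag-response: column
#' `k` is `sum_w x_w b_k(w)`. A participant with all-zero window exposure has
#' an all-zero row.
#'
#' @param wx Numeric n x 4 matrix of window exposures (no NAs).
#' @param basis A [lag_basis()].
#' @return n x 3 numeric matrix.
#' @export
cross_basis <- function(wx, basis) {
  stopifnot(ncol(wx) == 4L, !anyNA(wx))
  CB <- wx %*% basis$matrix
  colnames(CB) <- colnames(basis$matrix)
  CB
}

pooled_window_sd <- function(wx) {
  s <- sd(as.vector(wx), na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop_config("window exposures have zero variance; cannot scale")
  s
}

#' Constrained distributed-lag logistic model over pre-diagnostic windows
#'
#' Fits the covariate-adjusted logistic model on the three cross-basis
#' columns and reports, for each 10-year window, the log-OR for a 1-SD
#' increase in window exposure (`s * sum_k beta_k b_k(w)`, with `s` the
#' pooled SD over all window-exposure values of the pesticide), with
#' delta-method standard errors from the basis-coefficient covariance. The
#' first window's effect is structurally zero. Residential window exposures
#' only; windows without address coverage (NA) are imputed as zero exposure
#' and counted, or dropped listwise with `impute_missing = FALSE`.
#'
#' @param wx n x 4 matrix of residential window exposures (NA = no coverage).
#' @param y Binary outcome.
#' @param covariates Covariate matrix (see [build_covariate_matrix()]).
#' @param basis A [lag_basis()].
#' @param scale_sd Common exposure SD; default pooled over `wx`.
#' @param impute_missing Impute uncovered windows as zero (default) or drop
#'   participants with any uncovered window.
#' @return A `dlm_fit`: window table (`window`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`), basis coefficients and covariance, the scale `s`, a
#'   `lag_curve(t)` function, `converged`, `n_imputed`.
#' @export
fit_dlm <- function(wx, y, covariates, basis = lag_basis(), scale_sd = NULL,
                    impute_missing = TRUE) {
  wx <- as.matrix(wx)
  s <- scale_sd %||% pooled_window_sd(wx)
  if (impute_missing) {
    n_imputed <- sum(is.na(wx))
    wx[is.na(wx)] <- 0
    keep <- rep(TRUE, nrow(wx))
  } else {
    keep <- stats::complete.cases(wx)
    n_imputed <- 0L
    wx <- wx[keep, , drop = FALSE]
  }
  covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  if (!"(Intercept)" %in% colnames(covariates))
    covariates <- cbind(`(Intercept)` = 1, covariates)
  y <- as.numeric(y)[keep]
  CB <- cross_basis(wx, basis)
  X <- cbind(covariates, CB)
  fit <- logistic_irls(X, y)
  bk <- colnames(basis$matrix)
  beta_cb <- fit$coefficients[bk]
  V_cb <- fit$vcov[bk, bk, drop = FALSE]
  B <- basis$matrix
  est <- as.vector(s * (B %*% beta_cb))
  se <- s * sqrt(pmax(diag(B %*% V_cb %*% t(B)), 0))
  win <- data.table(
    window = 1:4, beta = est, se = se, or = exp(est),
    ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se)
  )
  structure(list(
    windows = win, basis_coefficients = beta_cb, basis_vcov = V_cb,
    scale_sd = s, converged = fit$converged, n_imputed = n_imputed,
    n = length(y),
    lag_curve = function(t) as.vector(s * (basis$eval(t) %*% beta_cb))
  ), class = "dlm_fit")
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat("<dlm_fit> n =", x$n, "; pooled SD =", signif(x$scale_sd, 4),
      "; imputed window cells:", x$n_imputed, "\n")
  print(x$windows)
  invisible(x)
}

#' Per-window logistic sensitivity models
#'
#' Either one logistic model per window (`adjusted = FALSE`) or a single
#' joint model with free coefficients for all four windows
#' (`adjusted = TRUE`, mutually adjusted). Estimates are reported per 1 SD of
#' the common pooled exposure scale so they are comparable with [fit_dlm()].
#' Collinear window columns in the joint model are dropped with a flag and
#' the design's condition number is reported.
#'
#' @inheritParams fit_dlm
#' @param adjusted Jointly adjust windows for each other (default TRUE).
#' @return `data.table` with `window`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `dropped`; attributes `model`, `condition_number`.
#' @export
fit_window_logistic <- function(wx, y, covariates, adjusted = TRUE,
                                scale_sd = NULL) {
  wx <- as.matrix(wx)
  s <- scale_sd %||% pooled_window_sd(wx)
  wx[is.na(wx)] <- 0
  covariates <- as.matrix(covariates)
  if (!"(Intercept)" %in% colnames(covariates))
    covariates <- cbind(`(Intercept)` = 1, covariates)
  y <- as.numeric(y)
  wn <- paste0("window", 1:4)
  colnames(wx) <- wn
  if (adjusted) {
    X <- cbind(covariates, wx)
    qrX <- qr(X)
    dropped <- character(0)
    if (qrX$rank < ncol(X)) {
      keep_cols <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- setdiff(colnames(X), colnames(X)[keep_cols])
      dropped <- intersect(dropped, wn)
      X <- X[, sort(keep_cols), drop = FALSE]
    }
    cn <- kappa(X, exact = FALSE)
    fit <- logistic_irls(X, y)
    out <- data.table(window = 1:4, beta = NA_real_, se = NA_real_,
                      dropped = wn %in% dropped)
    for (w in 1:4) {
      nm <- wn[w]
      if (nm %in% colnames(X)) {
        out[w, `:=`(beta = s * fit$coefficients[nm],
                    se = s * sqrt(fit$vcov[nm, nm]))]
      }
    }
  } else {
    cn <- NA_real_
    out <- data.table(window = 1:4, beta = NA_real_, se = NA_real_,
                      dropped = FALSE)
    for (w in 1:4) {
      xw <- wx[, w]
      if (sd(xw) == 0) { out[w, dropped := TRUE]; next }
      fit <- logistic_irls(cbind(covariates, xw = xw), y)
      out[w, `:=`(beta = s * fit$coefficients["xw"],
                  se = s * sqrt(fit$vcov["xw", "xw"]))]
    }
  }
  out[, or := exp(beta)]
  out[, ci_low := exp(beta - 1.96 * se)]
  out[, ci_high := exp(beta + 1.96 * se)]
  setattr(out, "model", if (adjusted) "window_adj" else "window_unadj")
  setattr(out, "condition_number", cn)
  out[]
}

# penalized binomial IRLS: minimizes -loglik + (lambda/2) * sum(beta_pen^2)
ridge_irls <- function(X, y, penalized, lambda, tol = 1e-10, maxit = 100) {
  k <- ncol(X)
  D <- numeric(k); D[penalized] <- 1
  beta <- numeric(k)
  obj <- function(b) {
    eta <- drop(X %*% b)
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -sum(y * eta - lse) + lambda / 2 * sum(D * b^2)
  }
  f0 <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    g <- drop(crossprod(X, y - p)) - lambda * D * beta
    H <- crossprod(X * w, X) + diag(lambda * D, k)
    delta <- solve(H, g)
    step <- 1
    repeat {
      f1 <- obj(beta + step * delta)
      if (f1 <= f0 + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    f0 <- f1
    if (max(abs(step * delta)) < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

#' Ridge-penalized per-window logistic model with cross-validated penalty
#'
#' L2-penalizes the four window coefficients only (covariates remain
#' unpenalized), choosing the penalty from a log-spaced grid by minimizing
#' mean out-of-fold binomial deviance over stratified folds (deterministic
#' given `seed`). Window exposures are pre-scaled by the pooled SD so the
#' returned window coefficients are per 1 SD. In the `lambda -> 0` limit the
#' fit equals the unpenalized joint model; as `lambda -> Inf` the window
#' coefficients shrink to zero while the covariate fit persists.
#'
#' @inheritParams fit_dlm
#' @param n_folds Number of CV folds (default 20).
#' @param seed Seed for the stratified fold assignment.
#' @param lambda Optional fixed penalty (skips CV).
#' @param lambda_grid Penalty grid for CV (default `10^seq(2, -6, length 40)`).
#' @return List with `window_beta` (per-SD), `covariate_beta`, `lambda`,
#'   `cv` (grid, mean out-of-fold deviance; NULL for fixed lambda),
#'   `scale_sd`.
#' @export
fit_ridge_windows <- function(wx, y, covariates, n_folds = 20, seed = 1,
                              lambda = NULL, lambda_grid = NULL,
                              scale_sd = NULL) {
  wx <- as.matrix(wx)
  s <- scale_sd %||% pooled_window_sd(wx)
  wx[is.na(wx)] <- 0
  xs <- wx / s
  colnames(xs) <- paste0("window", 1:4)
  covariates <- as.matrix(covariates)
  if (!"(Intercept)" %in% colnames(covariates))
    covariates <- cbind(`(Intercept)` = 1, covariates)
  X <- cbind(covariates, xs)
  y <- as.numeric(y)
  penalized <- which(colnames(X) %in% colnames(xs))
  cv_tab <- NULL
  if (is.null(lambda)) {
    if (sum(y == 1) < n_folds || sum(y == 0) < n_folds)
      stop_config("need at least n_folds cases and controls for stratified CV")
    lambda_grid <- lambda_grid %||% 10^seq(2, -6, length.out = 40)
    set.seed(derive_seed(seed, "ridge_folds"))
    foldid <- integer(length(y))
    for (cls in c(0, 1)) {
      ix <- which(y == cls)
      foldid[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    dev <- matrix(NA_real_, length(lambda_grid), n_folds)
    for (f in seq_len(n_folds)) {
      tr <- foldid != f
      for (li in seq_along(lambda_grid)) {
        b <- ridge_irls(X[tr, , drop = FALSE], y[tr], penalized, lambda_grid[li])
        eta <- drop(X[!tr, , drop = FALSE] %*% b)
        p <- plogis(eta)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        dev[li, f] <- -2 * mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
      }
    }
    mean_dev <- rowMeans(dev)
    lambda <- lambda_grid[which.min(mean_dev)]
    cv_tab <- data.table(lambda = lambda_grid, mean_deviance = mean_dev)
  }
  b <- ridge_irls(X, y, penalized, lambda)
  list(window_beta = b[colnames(xs)],
       covariate_beta = b[setdiff(colnames(X), colnames(xs))],
       lambda = lambda, cv = cv_tab, scale_sd = s)
}
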