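# Independent oracles and small in-code fixtures shared across test files.

# Direct Newton optimizer of the binomial log-likelihood with step halving.
# Deliberately independent of the package's IRLS path (explicit gradient and
# Hessian, no glm machinery).
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  ll0 <- loglik(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p))
    H <- crossprod(X * pmax(p * (1 - p), 1e-12), X)
    delta <- solve(H, grad)
    step <- 1
    repeat {
      ll1 <- loglik(beta + step * delta)
      if (ll1 >= ll0 - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll0 <- ll1
    if (max(abs(step * delta)) < tol) break
  }
  beta
}

# Brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} m * p_(j) / j, capped
# at 1, mapped back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Expand a binary 2x2 table (a = exposed cases, b = unexposed cases,
# c = exposed controls, d = unexposed controls) into y/x vectors.
table_2x2 <- function(a, b, c_, d) {
  list(y = c(rep(1, a + b), rep(0, c_ + d)),
       x = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)))
}

# A tiny deterministic covariate frame for model tests.
toy_covariates <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    age = round(runif(n, 40, 85), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    ethnicity = sample(c("white", "hispanic", "other"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1)),
    education_years = sample(8:20, n, replace = TRUE),
    smoking = sample(c("non", "former", "current"), n, replace = TRUE),
    wave = sample(c("PEG1", "PEG2"), n, replace = TRUE),
    index_year = sample(1998:2016, n, replace = TRUE)
  )
}

# Hand-built single-participant world: one address, applications at known
# distances/years. Returns the tables annual_exposure() consumes.
toy_world <- function(app_years, distances, pounds, loc_type = "R",
                      start_year = 1980, end_year = 2010) {
  stopifnot(length(app_years) == length(distances),
            length(pounds) == length(distances))
  addresses <- data.frame(participant_id = "S1", loc_type = loc_type,
                          x_m = 0, y_m = 0,
                          start_year = start_year, end_year = end_year)
  applications <- data.frame(pesticide_id = "P001", year = app_years,
                             x_m = distances, y_m = 0, pounds = pounds,
                             field_acres = 40)
  list(applications = applications, addresses = addresses)
}

# Small simulated dataset for logistic fits: covariates + exposure + outcome
# drawn from a known model.
sim_logistic_data <- function(n, beta_x, seed) {
  set.seed(seed)
  cov <- toy_covariates(n, seed = seed + 1)
  X <- build_covariate_matrix(cov)
  x <- rnorm(n)
  eta <- -0.3 + beta_x * x + 0.02 * scale(X[, "age"])[, 1]
  y <- as.integer(runif(n) < plogis(eta))
  list(y = y, x = x, covariates = cov, X = X)
}

# Simulated window-exposure matrices with controllable cross-window
# correlation (Gaussian copula over zero-inflated exposures).
sim_windows <- function(n, rho, seed, zero_frac = 0.5) {
  set.seed(seed)
  S <- matrix(rho, 4, 4); diag(S) <- 1
  L <- chol(S)
  Z <- matrix(rnorm(n * 4), n, 4) %*% L
  U <- pnorm(Z)
  W <- matrix(0, n, 4)
  pos <- U > zero_frac
  W[pos] <- (U[pos] - zero_frac) / (1 - zero_frac)
  colnames(W) <- paste0("window", 1:4)
  W
}
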