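#' Covariate design matrix for the adjusted logistic models
#'
#' Dummy-codes the confounder set used throughout the scans: age (continuous),
#' sex (reference female), ethnicity (reference non-Hispanic White), education
#' years (continuous), smoking status (reference non-smoker), study wave
#' (reference wave 1) and index year (continuous). Categorical levels are
#' fixed and ordered; missing values are an error.
#'
#' @param participants Table with columns `age`, `sex`, `ethnicity`,
#'   `education_years`, `smoking`, `wave`, `index_year`.
#' @return Numeric design matrix including an `(Intercept)` column.
#' @export
build_covariate_matrix <- function(participants) {
  p <- as.data.frame(participants)
  need <- c("age", "sex", "ethnicity", "education_years", "smoking", "wave",
            "index_year")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop_config("missing covariate columns: ",
                                paste(miss, collapse = ", "))
  if (anyNA(p[need])) stop_config("missing values in the analytic covariates")
  p$sex <- factor(p$sex, levels = c("F", "M"))
  p$ethnicity <- factor(p$ethnicity, levels = c("white", "hispanic", "other"))
  p$smoking <- factor(p$smoking, levels = c("non", "former", "current"))
  p$wave <- factor(p$wave, levels = c("PEG1", "PEG2"))
  if (anyNA(p$sex) || anyNA(p$ethnicity) || anyNA(p$smoking) || anyNA(p$wave))
    stop_config("unrecognised categorical covariate level")
  model.matrix(~ age + sex + ethnicity + education_years + smoking + wave +
                 index_year, data = p)
}

#' Maximum-likelihood logistic regression for one exposure
#'
#' Fits `logit P(y = 1) = a0 + a_x x + a_z Z` by binomial iteratively
#' reweighted least squares and returns the Wald inference for the exposure
#' term (standard error from the inverse observed information, two-sided
#' normal p-value). Rank-deficient designs are an error; separation or
#' non-convergence is flagged via `converged = FALSE` so the result can be
#' excluded from meta-analysis rather than aborting a scan.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Exposure vector (typically z-scaled).
#' @param covariates Optional covariate matrix (with or without an intercept
#'   column; one is added if absent).
#' @return List with `beta`, `se`, `z`, `p`, `converged`, `n`, and the full
#'   `coefficients` and `vcov`.
#' @export
fit_logistic_mle <- function(y, x, covariates = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_config("outcome has a single class")
  if (is.null(covariates)) {
    X <- cbind(`(Intercept)` = 1, exposure = x)
  } else {
    covariates <- as.matrix(covariates)
    if (!"(Intercept)" %in% colnames(covariates))
      covariates <- cbind(`(Intercept)` = 1, covariates)
    X <- cbind(covariates, exposure = x)
  }
  if (qr(X)$rank < ncol(X)) stop_config("rank-deficient design matrix")
  fit <- logistic_irls(X, y)
  beta <- fit$coefficients["exposure"]
  se <- sqrt(fit$vcov["exposure", "exposure"])
  converged <- fit$converged && is.finite(se) && se < 50
  z <- beta / se
  list(beta = unname(beta), se = unname(se), z = unname(z),
       p = unname(2 * pnorm(-abs(z))), converged = converged,
       n = length(y), coefficients = fit$coefficients, vcov = fit$vcov)
}

# binomial IRLS core shared by the scan and the lag models; returns the MLE,
# the unscaled inverse observed information (unpivoted), and a convergence flag
logistic_irls <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-12, maxit = 100))
  )
  k <- ncol(X)
  V <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  Vp <- tryCatch(chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]),
                 error = function(e) matrix(NA_real_, r, r))
  V[piv, piv] <- Vp
  list(coefficients = fit$coefficients, vcov = V,
       converged = isTRUE(fit$converged) && r == k &&
         all(is.finite(fit$coefficients)),
       fitted = fit$fitted.values, deviance = fit$deviance, rank = r)
}

#' Fixed-effect (inverse-variance) meta-analysis of location strata
#'
#' Combines the residential and occupational per-pesticide estimates with
#' weights `1/se^2`. If only one stratum is valid it is passed through and
#' tagged `single_stratum`.
#'
#' @param beta Numeric vector of stratum log-ORs (NAs allowed).
#' @param se Matching standard errors.
#' @return List with `beta`, `se`, `z`, `p`, `single_stratum`, `n_strata`, or
#'   `NULL` when no stratum is valid.
#' @export
meta_fixed <- function(beta, se) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(ok)) return(NULL)
  beta <- beta[ok]; se <- se[ok]
  if (length(beta) == 1L) {
    z <- beta / se
    return(list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                single_stratum = TRUE, n_strata = 1L))
  }
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)),
       single_stratum = FALSE, n_strata = length(beta))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped
#' back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p P-values in (0, 1].
#' @return Q-values in input order.
#' @export
fdr_bh <- function(p) p.adjust(p, method = "BH")

#' Run the pesticide-wide association scan
#'
#' For every pesticide passing the >= `min_exposed` eligibility filter:
#' z-scale the chosen exposure metric separately per location type over that
#' location's analytic sample, fit the covariate-adjusted logistic model per
#' location, combine locations by fixed-effect meta-analysis, and control the
#' FDR across the scan's meta-analytic p-values by Benjamini-Hochberg. The
#' scan never aborts on a single pesticide: non-converged or zero-variance
#' strata are flagged and dropped from the meta stage.
#'
#' @param em An `exposure_metrics` object.
#' @param participants Participant table with `case` and the covariates of
#'   [build_covariate_matrix()].
#' @param metric `"duration"`, `"weighted_duration"` or `"intensity"`.
#' @param min_exposed Pesticide eligibility threshold (default 25).
#' @param min_history Short-history exclusion threshold (0, 5 or 10).
#' @param fdr Nominal FDR level recorded for the discovery flag.
#' @return A `pwas_result`: `data.table` with per-location rows
#'   (`loc_type` R/O) and meta rows (`loc_type` "meta", carrying `q` and
#'   `discovery`), sorted by meta q; attributes record filter counts.
#' @export
run_pwas <- function(em, participants, metric = "duration", min_exposed = 25,
                     min_history = 0, fdr = 0.05) {
  stopifnot(metric %in% c("duration", "weighted_duration", "intensity"))
  participants <- as.data.table(participants)
  shx <- short_history_exclusion(em, min_history)
  pt <- participants[participant_id %in% shx$keep]
  pest <- pesticide_filter_on(em, pt$participant_id, min_exposed)
  np <- length(pest)
  per_loc_list <- list()
  n_nonconv <- 0L
  for (loc in c("R", "O")) {
    elig_ids <- em$eligibility[loc_type == loc & T_years >= 1, participant_id]
    ploc <- pt[participant_id %in% elig_ids]
    if (nrow(ploc) < 10L || np == 0L) next
    Xc <- build_covariate_matrix(ploc)
    if (qr(Xc)$rank < ncol(Xc)) stop_config("rank-deficient covariate design")
    y <- as.numeric(ploc$case)
    base <- logistic_irls(Xc, y)  # warm start for every pesticide fit
    sub <- em$metrics[loc_type == loc & pesticide_id %in% pest &
                        participant_id %in% ploc$participant_id]
    xmat <- matrix(0, nrow(ploc), np)
    xmat[cbind(match(sub$participant_id, ploc$participant_id),
               match(sub$pesticide_id, pest))] <- sub[[metric]]
    beta_v <- se_v <- rep(NA_real_, np)
    conv_v <- rep(NA, np)
    nexp_v <- colSums(xmat > 0)
    k <- ncol(Xc) + 1L
    X <- cbind(Xc, exposure = 0)
    start <- c(base$coefficients, exposure = 0)
    for (j in seq_len(np)) {
      zs <- zscore_exposure(xmat[, j])
      if (!zs$ok) next  # zero-variance stratum dropped
      X[, k] <- zs$z
      fit <- suppressWarnings(
        glm.fit(X, y, family = binomial(), start = start,
                control = list(epsilon = 1e-12, maxit = 100))
      )
      r <- fit$rank
      if (r < k) next  # collinear with covariates: stratum dropped
      piv <- fit$qr$pivot[seq_len(r)]
      Vp <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
      vx <- Vp[which(piv == k), which(piv == k)]
      beta_v[j] <- fit$coefficients[k]
      se_v[j] <- sqrt(vx)
      conv_v[j] <- isTRUE(fit$converged) && is.finite(se_v[j]) && se_v[j] < 50
      if (!conv_v[j]) n_nonconv <- n_nonconv + 1L
    }
    keep <- !is.na(beta_v)
    if (any(keep)) {
      per_loc_list[[loc]] <- data.table(
        pesticide_id = pest[keep], metric = metric, loc_type = loc,
        beta = beta_v[keep], se = se_v[keep],
        p = 2 * pnorm(-abs(beta_v[keep] / se_v[keep])),
        n_used = nrow(ploc), n_exposed = nexp_v[keep], converged = conv_v[keep]
      )
    }
  }
  per_loc <- rbindlist(per_loc_list)
  meta <- data.table()
  if (nrow(per_loc)) {
    meta <- per_loc[converged == TRUE,
                    c(meta_fixed(beta, se),
                      list(n_used = if (.N) max(n_used) else NA_integer_,
                           n_exposed = if (.N) max(n_exposed) else NA_real_)),
                    by = pesticide_id]
    if (nrow(meta)) {
      meta[, c("z", "n_strata") := NULL]
      meta[, `:=`(metric = metric, loc_type = "meta", converged = TRUE)]
    }
  }
  if (nrow(meta)) {
    meta[, q := fdr_bh(p)]
    setorder(meta, q, pesticide_id)
  } else meta <- data.table()
  if (nrow(per_loc)) per_loc[, `:=`(q = NA_real_, single_stratum = NA)]
  out <- rbind(meta, per_loc, fill = TRUE)
  if (nrow(out)) {
    out[, or := exp(beta)]
    out[, ci_low := exp(beta - 1.96 * se)]
    out[, ci_high := exp(beta + 1.96 * se)]
  }
  setattr(out, "class", c("pwas_result", class(out)))
  setattr(out, "metric", metric)
  setattr(out, "fdr_level", fdr)
  setattr(out, "counts", list(
    n_participants = nrow(pt), n_excluded_short_history = shx$n_excluded,
    n_pesticides_eligible = length(pest), n_nonconverged = n_nonconv
  ))
  out
}

# eligibility filter restricted to a participant subset
pesticide_filter_on <- function(em, ids, min_exposed) {
  counts <- em$metrics[N > 0 & participant_id %in% ids,
                       .(n_exposed = uniqueN(participant_id)), by = pesticide_id]
  sort(counts[n_exposed >= min_exposed, pesticide_id])
}

#' @export
print.pwas_result <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("<pwas_result> metric:", attr(x, "metric"), "\n")
  cat("  participants:", ct$n_participants,
      "(", ct$n_excluded_short_history, "excluded for short history )\n")
  cat("  eligible pesticides:", ct$n_pesticides_eligible,
      "; non-converged strata:", ct$n_nonconverged, "\n")
  meta <- x[x$loc_type == "meta", ]
  if (nrow(meta)) {
    cat("  discoveries at q <", attr(x, "fdr_level"), ":",
        sum(meta$q < attr(x, "fdr_level"), na.rm = TRUE), "\n")
    print(head(as.data.table(meta)[, .(pesticide_id, or, ci_low, ci_high, p, q)], 5))
  }
  invisible(x)
}
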