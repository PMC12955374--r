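#' Landscape configuration for the synthetic application-record generator
#'
#' Describes the agricultural landscape that the synthetic use-reporting
#' records are drawn from: a planar region (meters), spatially clustered
#' fields, a set of pesticide active ingredients partitioned into
#' co-application groups (pesticides in the same group are applied to the same
#' fields, which induces positive correlation of their downstream exposure
#' metrics), and per field-pesticide-year application probabilities.
#'
#' The defaults mirror the study conditions the pipeline emulates: 287 active
#' ingredients with mandatory-reporting records spanning 1974--2016. Fields are
#' assigned to groups cyclically after a seeded shuffle so every group receives
#' fields even when groups outnumber what a multinomial draw would cover.
#'
#' @param region_extent Numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param n_fields Number of fields (>= 0).
#' @param field_cluster_sd Spatial clustering scale of fields, meters.
#' @param n_pesticides Number of active ingredients.
#' @param co_application_groups List of integer vectors partitioning
#'   `1:n_pesticides`; default one singleton group per pesticide (independent
#'   exposures).
#' @param years Inclusive calendar span of the records (default 1974:2016).
#' @param annual_application_prob Per field-pesticide-year probability of an
#'   application.
#' @param pounds_meanlog,pounds_sdlog Log-normal parameters for pounds applied
#'   per application.
#' @param acres_meanlog,acres_sdlog Log-normal parameters for field acreage.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(region_extent = c(0, 18000, 0, 18000),
                             n_fields = 1435,
                             field_cluster_sd = 1500,
                             n_pesticides = 287,
                             co_application_groups = NULL,
                             years = 1974:2016,
                             annual_application_prob = 0.25,
                             pounds_meanlog = log(30), pounds_sdlog = 1,
                             acres_meanlog = log(40), acres_sdlog = 0.6) {
  if (length(region_extent) != 4L ||
      region_extent[2] <= region_extent[1] || region_extent[4] <= region_extent[3])
    stop_config("region_extent must be c(xmin, xmax, ymin, ymax) with positive area")
  if (n_fields < 0 || n_pesticides < 1)
    stop_config("n_fields must be >= 0 and n_pesticides >= 1")
  if (annual_application_prob < 0 || annual_application_prob > 1)
    stop_config("annual_application_prob must lie in [0, 1]")
  if (length(years) < 1L) stop_config("years span must cover at least one year")
  if (is.null(co_application_groups))
    co_application_groups <- as.list(seq_len(n_pesticides))
  ids <- sort(unlist(co_application_groups))
  if (!identical(as.integer(ids), seq_len(n_pesticides)))
    stop_config("co_application_groups must partition 1:n_pesticides")
  structure(list(
    region_extent = as.numeric(region_extent), n_fields = as.integer(n_fields),
    field_cluster_sd = field_cluster_sd, n_pesticides = as.integer(n_pesticides),
    co_application_groups = lapply(co_application_groups, as.integer),
    years = as.integer(years),
    annual_application_prob = annual_application_prob,
    pounds_meanlog = pounds_meanlog, pounds_sdlog = pounds_sdlog,
    acres_meanlog = acres_meanlog, acres_sdlog = acres_sdlog
  ), class = "landscape_config")
}

pesticide_ids <- function(n) sprintf("P%03d", seq_len(n))

#' Generate the synthetic field landscape
#'
#' Fields are scattered around seeded cluster centers (emulating the spatial
#' clustering of production agriculture) and clamped to the region. Each field
#' carries an acreage attribute and a co-application group; pesticides of a
#' group are applied only to that group's fields.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed; generation is a pure function of (config, seed).
#' @return `data.table` with columns `field_id`, `x`, `y`, `acres`, `group`.
#' @export
generate_landscape <- function(config, seed) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(derive_seed(seed, "landscape"))
  n <- config$n_fields
  ext <- config$region_extent
  if (n == 0L)
    return(data.table(field_id = integer(), x = numeric(), y = numeric(),
                      acres = numeric(), group = integer()))
  n_clusters <- max(1L, as.integer(round(n / 12)))
  cx <- runif(n_clusters, ext[1], ext[2])
  cy <- runif(n_clusters, ext[3], ext[4])
  k <- sample.int(n_clusters, n, replace = TRUE)
  x <- cx[k] + rnorm(n, 0, config$field_cluster_sd)
  y <- cy[k] + rnorm(n, 0, config$field_cluster_sd)
  # resample out-of-extent fields around their cluster rather than clamping,
  # which would pile mass onto the boundary; fall back to uniform placement
  for (it in 1:25) {
    bad <- which(x < ext[1] | x > ext[2] | y < ext[3] | y > ext[4])
    if (!length(bad)) break
    x[bad] <- cx[k[bad]] + rnorm(length(bad), 0, config$field_cluster_sd)
    y[bad] <- cy[k[bad]] + rnorm(length(bad), 0, config$field_cluster_sd)
  }
  bad <- which(x < ext[1] | x > ext[2] | y < ext[3] | y > ext[4])
  if (length(bad)) {
    x[bad] <- runif(length(bad), ext[1], ext[2])
    y[bad] <- runif(length(bad), ext[3], ext[4])
  }
  acres <- rlnorm(n, config$acres_meanlog, config$acres_sdlog)
  n_groups <- length(config$co_application_groups)
  group <- rep_len(seq_len(n_groups), n)[sample.int(n)]
  data.table(field_id = seq_len(n), x = x, y = y, acres = acres, group = group)
}

#' Generate synthetic pesticide application records
#'
#' For every field, each pesticide in the field's co-application group is
#' applied in a given year with probability `annual_application_prob`;
#' poundage is log-normal. The output mimics a use-reporting extract: active
#' ingredient, year, location, pounds.
#'
#' @param landscape Field table from [generate_landscape()].
#' @param config The [landscape_config()] used to build it.
#' @param seed Integer seed.
#' @return `data.table` with columns `pesticide_id`, `year`, `x_m`, `y_m`,
#'   `pounds`, `field_acres`.
#' @export
generate_applications <- function(landscape, config, seed) {
  stopifnot(inherits(config, "landscape_config"))
  if (nrow(landscape) == 0L) stop_config("landscape is empty")
  set.seed(derive_seed(seed, "applications"))
  pid <- pesticide_ids(config$n_pesticides)
  # field x (pesticides in its group) grid
  grp_sizes <- lengths(config$co_application_groups)
  per_field <- grp_sizes[landscape$group]
  grid <- data.table(
    field_row = rep(seq_len(nrow(landscape)), per_field),
    pesticide = unlist(config$co_application_groups[landscape$group])
  )
  ny <- length(config$years)
  cells <- grid[rep(seq_len(.N), each = ny)]
  cells[, year := rep(config$years, times = nrow(grid))]
  hit <- runif(nrow(cells)) < config$annual_application_prob
  cells <- cells[hit]
  if (nrow(cells) == 0L)
    return(data.table(pesticide_id = character(), year = integer(),
                      x_m = numeric(), y_m = numeric(), pounds = numeric(),
                      field_acres = numeric()))
  out <- data.table(
    pesticide_id = pid[cells$pesticide],
    year = cells$year,
    x_m = landscape$x[cells$field_row],
    y_m = landscape$y[cells$field_row],
    pounds = rlnorm(nrow(cells), config$pounds_meanlog, config$pounds_sdlog),
    field_acres = landscape$acres[cells$field_row]
  )
  setorder(out, pesticide_id, year, x_m, y_m)
  out[]
}

#' Cohort configuration for the synthetic case-control study
#'
#' Participant counts, the index-year span (diagnosis year for cases,
#' enrollment year for controls), address mobility, occupational structure,
#' and covariate distributions. Defaults follow the emulated study: 829 cases,
#' 824 controls, two enrollment waves, index years 1998--2016, and covariate
#' marginals in the range of the published demographic table (cases on average
#' slightly older; magnitudes configurable).
#'
#' `occupational_cessation_years` models the tendency of patients to reduce or
#' stop working before diagnosis: occupational intervals of (design-label)
#' cases end at least that many years before the index year.
#'
#' @param n_cases,n_controls Participant counts (> 0).
#' @param index_year_range Inclusive span of index years (default 1998--2016;
#'   wave 1 indexes fall in the lower half, wave 2 in the upper).
#' @param address_move_rate Per-year probability of relocation.
#' @param occupational_cessation_years Nonnegative integer; see above.
#' @param p_occupational Probability a participant has any occupational
#'   address history.
#' @param region_extent Planar region participants live in (must share the
#'   landscape's coordinate frame).
#' @param covariates List of covariate distribution parameters; see defaults.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 829, n_controls = 824,
                          index_year_range = c(1998, 2016),
                          address_move_rate = 0.04,
                          occupational_cessation_years = 3,
                          p_occupational = 0.65,
                          region_extent = c(0, 18000, 0, 18000),
                          covariates = list()) {
  if (n_cases <= 0 || n_controls <= 0) stop_config("participant counts must be > 0")
  if (address_move_rate < 0 || address_move_rate > 1)
    stop_config("address_move_rate must lie in [0, 1]")
  if (p_occupational < 0 || p_occupational > 1)
    stop_config("p_occupational must lie in [0, 1]")
  if (occupational_cessation_years < 0)
    stop_config("occupational_cessation_years must be >= 0")
  cov_def <- list(
    age_mean = 66, age_sd = 11, age_case_shift = 1.8,
    p_male = 0.55,
    ethnicity_probs = c(white = 0.73, hispanic = 0.17, other = 0.10),
    education_mean = 13.8, education_sd = 4.2,
    smoking_probs = c(non = 0.51, former = 0.41, current = 0.08),
    p_wave1 = 0.46
  )
  cov_def[names(covariates)] <- covariates
  # YAML deserialization yields named lists; keep probability vectors numeric
  cov_def$ethnicity_probs <- unlist(cov_def$ethnicity_probs)
  cov_def$smoking_probs <- unlist(cov_def$smoking_probs)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    index_year_range = as.integer(index_year_range),
    address_move_rate = address_move_rate,
    occupational_cessation_years = as.integer(occupational_cessation_years),
    p_occupational = p_occupational,
    region_extent = as.numeric(region_extent),
    covariates = cov_def
  ), class = "cohort_config")
}

# split a continuous span [a, b] into move-delimited abutting intervals
split_intervals <- function(a, b, move_rate) {
  if (b < a) return(integer(0))
  yrs <- a:b
  if (length(yrs) == 1L) return(list(start = a, end = b))
  moves <- yrs[-1][runif(length(yrs) - 1L) < move_rate]
  starts <- c(a, moves)
  ends <- c(moves - 1L, b)
  list(start = starts, end = ends)
}

#' Generate a synthetic case-control cohort with address histories
#'
#' Assigns design case labels (exactly `n_cases` cases), covariates drawn from
#' the configured distributions, and residential/occupational address
#' histories on the planar region. Every participant has continuous
#' residential coverage from the start of the record era (1974) through the
#' index year; occupational histories, when present, end early for design
#' cases per the configured cessation. Intervals for one participant and
#' location type never overlap (moves yield abutting intervals).
#'
#' The design label drives structural features that in the real world precede
#' outcome ascertainment (occupational cessation, the slightly older age of
#' cases); the analysis case status is drawn afterwards by
#' [simulate_outcomes()] from exposure and planted effects.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `participants` (columns `participant_id`, `case`,
#'   `index_year`, `age`, `sex`, `ethnicity`, `education_years`, `smoking`,
#'   `wave`) and `addresses` (columns `participant_id`, `loc_type` (R|O),
#'   `x_m`, `y_m`, `start_year`, `end_year`, years inclusive).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(seed, "cohort"))
  n <- config$n_cases + config$n_controls
  cc <- config$covariates
  ids <- sprintf("S%04d", seq_len(n))
  case <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))

  iyr <- config$index_year_range
  split_yr <- floor((iyr[1] + iyr[2]) / 2)
  wave <- ifelse(runif(n) < cc$p_wave1, "PEG1", "PEG2")
  r1 <- iyr[1]:split_yr
  r2 <- if (split_yr < iyr[2]) (split_yr + 1L):iyr[2] else r1
  index_year <- ifelse(
    wave == "PEG1",
    r1[sample.int(length(r1), n, replace = TRUE)],
    r2[sample.int(length(r2), n, replace = TRUE)]
  )

  age <- rnorm(n, cc$age_mean + cc$age_case_shift * case, cc$age_sd)
  age <- round(pmin(pmax(age, 35), 95), 1)
  sex <- ifelse(runif(n) < cc$p_male, "M", "F")
  ethnicity <- sample(names(cc$ethnicity_probs), n, replace = TRUE,
                      prob = cc$ethnicity_probs)
  education_years <- round(pmin(pmax(rnorm(n, cc$education_mean, cc$education_sd), 0), 22))
  smoking <- sample(names(cc$smoking_probs), n, replace = TRUE,
                    prob = cc$smoking_probs)

  participants <- data.table(
    participant_id = ids, case = case, index_year = as.integer(index_year),
    age = age, sex = sex, ethnicity = ethnicity,
    education_years = as.numeric(education_years), smoking = smoking, wave = wave
  )

  ext <- config$region_extent
  has_occ <- runif(n) < config$p_occupational
  addr <- vector("list", n)
  for (i in seq_len(n)) {
    res <- split_intervals(1974L, index_year[i], config$address_move_rate)
    k <- length(res$start)
    rows <- data.table(
      participant_id = ids[i], loc_type = "R",
      x_m = runif(k, ext[1], ext[2]), y_m = runif(k, ext[3], ext[4]),
      start_year = as.integer(res$start), end_year = as.integer(res$end)
    )
    if (has_occ[i]) {
      occ_end <- index_year[i] -
        if (case[i] == 1L) config$occupational_cessation_years else 0L
      if (occ_end >= 1974L) {
        occ <- split_intervals(1974L, occ_end, config$address_move_rate)
        k2 <- length(occ$start)
        rows <- rbind(rows, data.table(
          participant_id = ids[i], loc_type = "O",
          x_m = runif(k2, ext[1], ext[2]), y_m = runif(k2, ext[3], ext[4]),
          start_year = as.integer(occ$start), end_year = as.integer(occ$end)
        ))
      }
    }
    addr[[i]] <- rows
  }
  list(participants = participants, addresses = rbindlist(addr))
}

#' Specify a planted exposure effect
#'
#' Ground truth for simulation studies: a per-1-SD log odds ratio attached to
#' one pesticide's duration or intensity metric, optionally confined to
#' specific pre-diagnostic 10-year windows (1 = lags 1--10, ..., 4 = lags
#' 31--40). An empty `active_windows` plants the effect on the cumulative
#' metric.
#'
#' @param pesticide_id Pesticide identifier (e.g. `"P001"`).
#' @param metric `"duration"` or `"intensity"`.
#' @param log_or_per_sd Finite log odds ratio per SD of the metric.
#' @param active_windows Integer subset of 1:4 (default none = cumulative).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(pesticide_id, metric = c("duration", "intensity"),
                        log_or_per_sd, active_windows = integer(0)) {
  metric <- match.arg(metric)
  if (!is.finite(log_or_per_sd)) stop_config("log_or_per_sd must be finite")
  if (length(active_windows) && !all(active_windows %in% 1:4))
    stop_config("active_windows must be a subset of 1:4")
  structure(list(pesticide_id = pesticide_id, metric = metric,
                 log_or_per_sd = log_or_per_sd,
                 active_windows = as.integer(active_windows)),
            class = "effect_spec")
}

# z-score a vector for outcome generation; zero-variance -> all zeros
gen_z <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate case-control outcomes from exposure with planted effects
#'
#' Draws case status from a linear-logistic model on the true (pre-outcome)
#' z-scaled exposure metrics: `P(case) = invlogit(a0 + sum(effect * z) +
#' covariate terms)`. The intercept `a0` is calibrated by bisection so the
#' expected case fraction matches `target_fraction` to within 0.5% (the
#' implementation tightens this to 1e-4).
#'
#' Cumulative effects use the residential metric; window-confined effects use
#' residential window durations/intensities (the lag analyses are
#' residential-based), z-scaled per window.
#'
#' @param participants Participant table from [generate_cohort()].
#' @param exposure_metrics An `exposure_metrics` object
#'   (see [compute_exposure_metrics()]).
#' @param effects List of [effect_spec()] objects (may be empty: global null).
#' @param covariate_log_ors Optional named numeric of log-ORs applied to
#'   columns of the covariate design matrix (see [build_covariate_matrix()]).
#' @param seed Integer seed.
#' @param target_fraction Expected case fraction; defaults to
#'   `mean(participants$case)`.
#' @return Integer 0/1 vector of simulated case status, aligned with
#'   `participants`, with the calibrated intercept as attribute `"intercept"`.
#' @export
simulate_outcomes <- function(participants, exposure_metrics, effects = list(),
                              covariate_log_ors = NULL, seed = 1,
                              target_fraction = NULL) {
  n <- nrow(participants)
  target <- target_fraction %||% mean(participants$case)
  lp <- rep(0, n)
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    if (length(ef$active_windows) == 0L) {
      x <- exposure_vector(exposure_metrics, ef$pesticide_id, "R", ef$metric,
                           participants$participant_id)
      lp <- lp + ef$log_or_per_sd * gen_z(x)
    } else {
      wm <- window_matrix(exposure_metrics, ef$pesticide_id,
                          participants$participant_id, metric = ef$metric)
      for (w in ef$active_windows) {
        x <- wm[, w]
        x[is.na(x)] <- 0
        lp <- lp + ef$log_or_per_sd * gen_z(x)
      }
    }
  }
  if (!is.null(covariate_log_ors)) {
    X <- build_covariate_matrix(participants)
    miss <- setdiff(names(covariate_log_ors), colnames(X))
    if (length(miss)) stop_config("unknown covariate terms: ",
                                  paste(miss, collapse = ", "))
    for (nm in names(covariate_log_ors))
      lp <- lp + covariate_log_ors[[nm]] * X[, nm]
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor in outcome simulation")
  # bisection for the intercept
  f <- function(a0) mean(invlogit(a0 + lp)) - target
  lo <- -30; hi <- 30
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < 1e-4) break
  }
  a0 <- (lo + hi) / 2
  set.seed(derive_seed(seed, "outcomes"))
  y <- as.integer(runif(n) < invlogit(a0 + lp))
  attr(y, "intercept") <- a0
  y
}
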