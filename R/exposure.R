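#' Annual buffer-based exposure series from application records
#'
#' For every participant-year with an address of a given type, a pesticide
#' counts as applied nearby if any recorded application of that pesticide in
#' that year lies at Euclidean distance at most `radius_m` from the address
#' (membership is inclusive at exactly the radius). Pounds of all in-buffer
#' applications are summed and divided by the buffer area in acres
#' (`pi * radius_m^2 / 4046.856`) to give annual pounds per acre.
#'
#' In a move year a participant may hold two same-type addresses; the year
#' counts once, a field is counted once even if inside both buffers, and the
#' year is exposed if any of that year's addresses is exposed. Same-type
#' intervals overlapping by more than the shared move year are an input error.
#'
#' @param applications `data.table`/data.frame with `pesticide_id`, `year`,
#'   `x_m`, `y_m`, `pounds`.
#' @param addresses Address intervals with `participant_id`, `loc_type`,
#'   `x_m`, `y_m`, `start_year`, `end_year` (years inclusive).
#' @param radius_m Buffer radius in meters (> 0), default 500.
#' @param years Optional allowed calendar span; records outside it are dropped
#'   with a warning.
#' @return An `annual_exposure` list: `exposure` (sparse table of exposed
#'   participant-years: `participant_id`, `loc_type`, `pesticide_id`, `year`,
#'   `pounds`, `pounds_per_acre`; absent rows mean no nearby application),
#'   `address_years` (`participant_id`, `loc_type`, `year`), `radius_m`,
#'   `buffer_acres`.
#' @export
annual_exposure <- function(applications, addresses, radius_m = 500,
                            years = NULL) {
  stopifnot(radius_m > 0)
  applications <- as.data.table(applications)
  addresses <- as.data.table(addresses)
  if (!is.null(years)) {
    bad <- !(applications$year %in% years)
    if (any(bad)) {
      warning(sum(bad), " application record(s) outside the configured year span; ignored")
      applications <- applications[!bad]
    }
  }
  # interval validation: within participant x loc_type, intervals may share at
  # most one boundary year (a move year)
  iv <- copy(addresses)[order(participant_id, loc_type, start_year)]
  if (any(iv$end_year < iv$start_year)) stop("address interval with end_year < start_year")
  iv[, overlap := start_year - shift(end_year), by = .(participant_id, loc_type)]
  if (any(iv$overlap < 0, na.rm = TRUE))
    stop("overlapping same-type address intervals for a participant")
  buffer_acres <- pi * radius_m^2 / 4046.856

  # expand to address-point-years
  ay <- addresses[, .(year = seq.int(start_year, end_year)),
                  by = .(participant_id, loc_type, x_m, y_m, start_year, end_year)]
  ay[, c("start_year", "end_year") := NULL]
  address_years <- unique(ay[, .(participant_id, loc_type, year)])

  empty <- data.table(participant_id = character(), loc_type = character(),
                      pesticide_id = character(), year = integer(),
                      pounds = numeric(), pounds_per_acre = numeric())
  if (nrow(applications) == 0L || nrow(ay) == 0L) {
    return(structure(list(exposure = empty, address_years = address_years,
                          radius_m = radius_m, buffer_acres = buffer_acres),
                     class = "annual_exposure"))
  }

  apts <- unique(ay[, .(x_m, y_m)])
  apts[, apt_id := .I]
  lpts <- unique(applications[, .(x_m, y_m)])
  lpts[, loc_id := .I]
  pairs <- points_within(apts$x_m, apts$y_m, lpts$x_m, lpts$y_m, radius_m)
  if (nrow(pairs) == 0L) {
    return(structure(list(exposure = empty, address_years = address_years,
                          radius_m = radius_m, buffer_acres = buffer_acres),
                     class = "annual_exposure"))
  }
  setnames(pairs, c("i", "j"), c("apt_id", "loc_id"))

  apps <- merge(applications, lpts, by = c("x_m", "y_m"))
  apps <- apps[, .(pounds = sum(pounds)), by = .(loc_id, pesticide_id, year)]
  ay <- merge(ay, apts, by = c("x_m", "y_m"))

  hits <- merge(ay[, .(participant_id, loc_type, year, apt_id)], pairs,
                by = "apt_id", allow.cartesian = TRUE)
  exp_rows <- merge(hits, apps, by = c("loc_id", "year"), allow.cartesian = TRUE)
  if (nrow(exp_rows) == 0L) {
    return(structure(list(exposure = empty, address_years = address_years,
                          radius_m = radius_m, buffer_acres = buffer_acres),
                     class = "annual_exposure"))
  }
  # a field (loc_id) counts once per participant-year even if two move-year
  # addresses both cover it
  exp_rows <- unique(exp_rows[, .(participant_id, loc_type, pesticide_id, year,
                                  loc_id, pounds)])
  exposure <- exp_rows[, .(pounds = sum(pounds)),
                       by = .(participant_id, loc_type, pesticide_id, year)]
  exposure[, pounds_per_acre := pounds / buffer_acres]
  setorder(exposure, participant_id, loc_type, pesticide_id, year)
  structure(list(exposure = exposure, address_years = address_years,
                 radius_m = radius_m, buffer_acres = buffer_acres),
            class = "annual_exposure")
}

#' Eligible exposure years for the cumulative metrics
#'
#' A year is eligible when the participant has an address of the relevant
#' type, the year falls inside the record era (`>= start_year`), and it
#' precedes the index year by at least `min_lag` years (the prodromal lag:
#' the default 11 keeps the cumulative period strictly beyond the excluded
#' 1--10-year window).
#'
#' @param address_years Integer vector of years with an address.
#' @param index_year Index year (diagnosis for cases, enrollment for controls).
#' @param min_lag Minimum lag (default 11).
#' @param start_year First year of the record era (default 1974).
#' @return Sorted integer vector of eligible years (possibly empty).
#' @export
eligible_years <- function(address_years, index_year, min_lag = 11,
                           start_year = 1974) {
  stopifnot(index_year >= start_year)
  y <- unique(as.integer(address_years))
  sort(y[y >= start_year & (index_year - y) >= min_lag])
}

#' Duration metric: proportion of eligible years with any nearby application
#'
#' @param exposed_years Years with any in-buffer application of the pesticide.
#' @param eligible Eligible year set (see [eligible_years()]).
#' @return List with `N` (exposed eligible years), `T` (eligible years) and
#'   `duration = N/T` (NA when `T == 0`, in which case the participant is
#'   ineligible for this location type).
#' @export
duration_metric <- function(exposed_years, eligible) {
  T_ <- length(eligible)
  N <- length(intersect(as.integer(exposed_years), as.integer(eligible)))
  list(N = N, T = T_, duration = if (T_ > 0) N / T_ else NA_real_)
}

#' Weighted duration metric
#'
#' The proportion-of-years duration damped by the (natural) log-transformed
#' number of exposed years offset by one: `(N/T) * log(N + 1)`. This reduces
#' the influence of short observation windows, where a single exposed year
#' can already yield a proportion of 1.
#'
#' @param N Number of exposed eligible years (`0 <= N <= T`).
#' @param T_ Number of eligible years (>= 1).
#' @return Nonnegative real.
#' @export
weighted_duration_metric <- function(N, T_) {
  stopifnot(all(T_ >= 1), all(N >= 0), all(N <= T_))
  (N / T_) * log(N + 1)
}

#' Intensity metric: mean annual pounds per acre over eligible years
#'
#' Zero years are included in the denominator, so duration 0 implies
#' intensity 0.
#'
#' @param ppa Named numeric of pounds-per-acre values, names = years.
#' @param eligible Eligible year set.
#' @return Nonnegative real (NA when the eligible set is empty).
#' @export
intensity_metric <- function(ppa, eligible) {
  T_ <- length(eligible)
  if (T_ == 0L) return(NA_real_)
  sel <- names(ppa) %in% as.character(as.integer(eligible))
  sum(ppa[sel]) / T_
}

#' Per-window exposure metrics over 10-year pre-diagnostic lag windows
#'
#' Lag = index year minus exposure year; windows are lags 1--10, 11--20,
#' 21--30 and 31--40. Within each window the duration is `N_w / T_w` with
#' `T_w` the address-years in the window (inside the record era); windows
#' without address coverage are flagged missing (NA). Lags beyond 40 are
#' excluded.
#'
#' @param exposed_years Years with any in-buffer application.
#' @param ppa Named pounds-per-acre by year.
#' @param address_years Years with an address of the relevant type.
#' @param index_year Index year.
#' @param start_year First record-era year (default 1974).
#' @return `data.table` with `window`, `N`, `T_years`, `duration`, `intensity`.
#' @export
window_exposures <- function(exposed_years, ppa, address_years, index_year,
                             start_year = 1974) {
  ay <- unique(as.integer(address_years))
  ay <- ay[ay >= start_year]
  lag_of <- function(y) index_year - y
  win_of <- function(lag) ifelse(lag >= 1 & lag <= 40, (lag - 1) %/% 10 + 1, NA_integer_)
  out <- vector("list", 4L)
  ex <- as.integer(exposed_years)
  for (w in 1:4) {
    yw <- ay[win_of(lag_of(ay)) %in% w]
    T_ <- length(yw)
    exw <- intersect(ex, yw)
    N <- length(exw)
    sel <- names(ppa) %in% as.character(yw)
    out[[w]] <- data.table(
      window = w, N = N, T_years = T_,
      duration = if (T_ > 0) N / T_ else NA_real_,
      intensity = if (T_ > 0) sum(ppa[sel]) / T_ else NA_real_
    )
  }
  rbindlist(out)
}

#' Compute cumulative and window exposure metrics for a study
#'
#' Runs the buffer model over all participants and pesticides and derives,
#' per participant x pesticide x location type, the eligible-year counts and
#' the duration, weighted-duration and intensity metrics, plus residential
#' per-window metrics for the lag analyses. Storage is sparse: rows are kept
#' only where any exposure occurred; eligibility tables carry the
#' denominators, and [exposure_vector()] / [window_matrix()] materialise
#' dense per-participant vectors with implicit zeros.
#'
#' @param applications Application records (see [annual_exposure()]).
#' @param addresses Address intervals.
#' @param participants Table with `participant_id` and `index_year`.
#' @param radius_m Buffer radius, meters (default 500).
#' @param min_lag Prodromal lag for the cumulative metrics (default 11).
#' @param start_year First record-era year (default 1974).
#' @param years Optional allowed application-year span.
#' @return An `exposure_metrics` object: `metrics` (sparse cumulative),
#'   `eligibility` (per participant x loc `T_years`), `windows` (sparse
#'   residential per-window), `window_eligibility` (per participant x window
#'   `T_w`), plus parameters.
#' @export
compute_exposure_metrics <- function(applications, addresses, participants,
                                     radius_m = 500, min_lag = 11,
                                     start_year = 1974, years = NULL) {
  participants <- as.data.table(participants)
  ae <- annual_exposure(applications, addresses, radius_m = radius_m, years = years)
  idx <- participants[, .(participant_id, index_year)]

  ay <- merge(ae$address_years, idx, by = "participant_id")
  ay <- ay[year >= start_year]
  ay[, lag := index_year - year]

  # cumulative eligibility (both location types)
  elig_years <- ay[lag >= min_lag]
  eligibility <- elig_years[, .(T_years = uniqueN(year)),
                            by = .(participant_id, loc_type)]

  # residential window eligibility
  wy <- ay[loc_type == "R" & lag >= 1 & lag <= 40]
  wy[, window := (lag - 1L) %/% 10L + 1L]
  window_eligibility <- wy[, .(T_w = uniqueN(year)), by = .(participant_id, window)]

  ex <- merge(ae$exposure, idx, by = "participant_id")
  ex <- ex[year >= start_year]
  ex[, lag := index_year - year]

  # cumulative metrics (sparse: exposed pairs only)
  exc <- ex[lag >= min_lag]
  metrics <- exc[, .(N = uniqueN(year), ppa_sum = sum(pounds_per_acre)),
                 by = .(participant_id, pesticide_id, loc_type)]
  metrics <- merge(metrics, eligibility, by = c("participant_id", "loc_type"))
  metrics[, duration := N / T_years]
  metrics[, weighted_duration := duration * log(N + 1)]
  metrics[, intensity := ppa_sum / T_years]
  metrics[, ppa_sum := NULL]

  # residential window metrics (sparse)
  exw <- ex[loc_type == "R" & lag >= 1 & lag <= 40]
  exw[, window := (lag - 1L) %/% 10L + 1L]
  windows <- exw[, .(N_w = uniqueN(year), ppa_sum = sum(pounds_per_acre)),
                 by = .(participant_id, pesticide_id, window)]
  windows <- merge(windows, window_eligibility, by = c("participant_id", "window"))
  windows[, duration := N_w / T_w]
  windows[, intensity := ppa_sum / T_w]
  windows[, ppa_sum := NULL]

  structure(list(
    metrics = metrics, eligibility = eligibility,
    windows = windows, window_eligibility = window_eligibility,
    participant_ids = participants$participant_id,
    params = list(radius_m = radius_m, min_lag = min_lag,
                  start_year = start_year)
  ), class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat("<exposure_metrics>\n")
  cat("  participants:", length(x$participant_ids), "\n")
  cat("  pesticides with any exposure:", uniqueN(x$metrics$pesticide_id), "\n")
  cat("  radius:", x$params$radius_m, "m; min lag:", x$params$min_lag,
      "; record era from", x$params$start_year, "\n")
  invisible(x)
}

#' Dense per-participant vector of one cumulative metric
#'
#' @param em An `exposure_metrics` object.
#' @param pesticide Pesticide id.
#' @param loc `"R"` or `"O"`.
#' @param metric One of `duration`, `weighted_duration`, `intensity`, `N`.
#' @param participant_ids Participant ids defining order and length.
#' @return Numeric vector; implicit zeros for unexposed participants
#'   (including those without eligible years, who are excluded from analysis
#'   by the eligibility table, not by this accessor).
#' @export
exposure_vector <- function(em, pesticide, loc, metric = "duration",
                            participant_ids) {
  m <- em$metrics[pesticide_id == pesticide & loc_type == loc]
  out <- numeric(length(participant_ids))
  if (nrow(m)) {
    ix <- match(m$participant_id, participant_ids)
    ok <- !is.na(ix)
    out[ix[ok]] <- m[[metric]][ok]
  }
  out
}

#' Dense participant x window matrix of residential window metrics
#'
#' @param em An `exposure_metrics` object.
#' @param pesticide Pesticide id.
#' @param participant_ids Participant ids defining row order.
#' @param metric `"duration"` or `"intensity"`.
#' @return Numeric matrix `length(participant_ids)` x 4; `NA` where the
#'   participant has no address coverage in the window (`T_w == 0`), zero
#'   where covered but unexposed.
#' @export
window_matrix <- function(em, pesticide, participant_ids, metric = "duration") {
  n <- length(participant_ids)
  out <- matrix(NA_real_, n, 4)
  we <- em$window_eligibility
  ix <- match(we$participant_id, participant_ids)
  ok <- !is.na(ix)
  out[cbind(ix[ok], we$window[ok])] <- 0
  w <- em$windows[pesticide_id == pesticide]
  if (nrow(w)) {
    ix <- match(w$participant_id, participant_ids)
    ok <- !is.na(ix)
    out[cbind(ix[ok], w$window[ok])] <- w[[metric]][ok]
  }
  colnames(out) <- paste0("window", 1:4)
  out
}

#' Pesticide eligibility filter
#'
#' A pesticide is retained when at least `min_exposed` participants have any
#' exposure (`N > 0`) at either the residential or the workplace address.
#'
#' @param em An `exposure_metrics` object.
#' @param min_exposed Threshold (default 25).
#' @return Character vector of retained pesticide ids.
#' @export
pesticide_filter <- function(em, min_exposed = 25) {
  counts <- em$metrics[N > 0, .(n_exposed = uniqueN(participant_id)),
                       by = pesticide_id]
  sort(counts[n_exposed >= min_exposed, pesticide_id])
}

#' Z-scale an exposure vector over the analytic sample
#'
#' Centers to mean 0 and scales by the sample (n-1) standard deviation, so a
#' unit change is one SD of the metric in the analytic sample. Strata with
#' zero variance cannot be scaled and are flagged for dropping.
#'
#' @param x Numeric vector (length >= 2).
#' @return List with `ok`, `z`, `mean`, `sd`. When `ok` is `FALSE` (zero or
#'   undefined variance) `z` is `NULL`.
#' @export
zscore_exposure <- function(x) {
  if (length(x) < 2L) return(list(ok = FALSE, z = NULL, mean = NA_real_, sd = NA_real_))
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(list(ok = FALSE, z = NULL, mean = m, sd = s))
  list(ok = TRUE, z = (x - m) / s, mean = m, sd = s)
}

#' Exclude participants with short observable exposure histories
#'
#' Removes participants whose observable exposure period (largest `T` over
#' location types) is strictly below `min_years` ("fewer than" semantics: a
#' participant with exactly `min_years` is retained).
#'
#' @param em An `exposure_metrics` object.
#' @param min_years 0 (no exclusion), 5 or 10.
#' @return List with `keep` (participant ids retained), `excluded` (ids
#'   removed) and `n_excluded`.
#' @export
short_history_exclusion <- function(em, min_years = 0) {
  tmax <- em$eligibility[, .(T_years = max(T_years)), by = participant_id]
  all_ids <- em$participant_ids
  t_by_id <- setNames(rep(0L, length(all_ids)), all_ids)
  t_by_id[tmax$participant_id] <- tmax$T_years
  keep <- all_ids[t_by_id >= min_years]
  excluded <- setdiff(all_ids, keep)
  list(keep = keep, excluded = excluded, n_excluded = length(excluded))
}

#' Flatten exposure metrics to a dense export table
#'
#' One row per participant x pesticide x location type with all cumulative and
#' (residential) window metrics, zeros filled in for unexposed covered cells.
#' Intended for CSV export of small studies; large studies should stay sparse.
#'
#' @param em An `exposure_metrics` object.
#' @param pesticides Pesticide ids to include (default: all with any exposure).
#' @return A `data.table`.
#' @export
exposure_metrics_table <- function(em, pesticides = NULL) {
  pesticides <- pesticides %||% sort(unique(em$metrics$pesticide_id))
  grid <- CJ(participant_id = em$participant_ids, pesticide_id = pesticides,
             loc_type = c("R", "O"))
  out <- merge(grid, em$eligibility, by = c("participant_id", "loc_type"))
  out <- merge(out, em$metrics,
               by = c("participant_id", "pesticide_id", "loc_type"),
               all.x = TRUE, suffixes = c("", ".m"))
  out[, T_years := fifelse(is.na(get("T_years.m")), T_years, get("T_years.m"))]
  out[, "T_years.m" := NULL]
  for (cl in c("N", "duration", "weighted_duration", "intensity"))
    out[is.na(get(cl)), (cl) := 0]
  wg <- CJ(participant_id = em$participant_ids, pesticide_id = pesticides,
           window = 1:4)
  ww <- merge(wg, em$window_eligibility, by = c("participant_id", "window"))
  ww <- merge(ww, em$windows,
              by = c("participant_id", "pesticide_id", "window"), all.x = TRUE,
              suffixes = c("", ".m"))
  ww[, duration := fifelse(is.na(duration), 0, duration)]
  ww[, intensity := fifelse(is.na(intensity), 0, intensity)]
  wd <- dcast(ww, participant_id + pesticide_id ~ window,
              value.var = c("duration", "intensity"))
  setnames(wd, old = setdiff(names(wd), c("participant_id", "pesticide_id")),
           new = c(paste0("window", 1:4, "_duration"),
                   paste0("window", 1:4, "_intensity")))
  out <- merge(out, wd, by = c("participant_id", "pesticide_id"), all.x = TRUE)
  setorder(out, pesticide_id, participant_id, loc_type)
  out[]
}
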