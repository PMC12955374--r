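test_that("buffer membership is inclusive at the radius", {
  w_in <- toy_world(app_years = 1990, distances = 499, pounds = 10)
  w_out <- toy_world(app_years = 1990, distances = 501, pounds = 10)
  ae_in <- annual_exposure(w_in$applications, w_in$addresses, radius_m = 500)
  ae_out <- annual_exposure(w_out$applications, w_out$addresses, radius_m = 500)
  expect_equal(nrow(ae_in$exposure), 1)
  expect_equal(ae_in$exposure$year, 1990)
  expect_equal(nrow(ae_out$exposure), 0)
  w_at <- toy_world(app_years = 1990, distances = 500, pounds = 10)
  expect_equal(nrow(annual_exposure(w_at$applications, w_at$addresses)$exposure), 1)
})

test_that("pounds per acre uses the buffer area in acres", {
  w <- toy_world(app_years = 1990, distances = 100, pounds = 100)
  ae <- annual_exposure(w$applications, w$addresses, radius_m = 500)
  expect_equal(ae$buffer_acres, pi * 500^2 / 4046.856)
  expect_equal(ae$exposure$pounds_per_acre, 100 / 194.0771, tolerance = 1e-4)
})

test_that("move years count once and shared fields are not double counted", {
  addresses <- data.frame(
    participant_id = "S1", loc_type = "R", x_m = c(0, 100), y_m = 0,
    start_year = c(1980, 1990), end_year = c(1990, 2000)  # 1990 shared
  )
  applications <- data.frame(pesticide_id = "P001", year = 1990, x_m = 50,
                             y_m = 0, pounds = 10, field_acres = 40)
  ae <- annual_exposure(applications, addresses)
  expect_equal(nrow(ae$exposure), 1)  # field in both buffers counted once
  expect_equal(ae$exposure$pounds, 10)
  expect_equal(sum(ae$address_years$year == 1990), 1)

  bad <- addresses; bad$start_year[2] <- 1985  # interior overlap
  expect_error(annual_exposure(applications, bad), "overlapping")
})

test_that("records outside the configured span are dropped with a warning", {
  w <- toy_world(app_years = c(1990, 1950), distances = c(100, 100),
                 pounds = c(10, 10))
  expect_warning(
    ae <- annual_exposure(w$applications, w$addresses, years = 1974:2016),
    "outside the configured year span"
  )
  expect_equal(ae$exposure$year, 1990)
})

test_that("eligible years implement the prodromal lag and record era", {
  expect_equal(eligible_years(1980:2010, 2005), 1980:1994)  # lag >= 11
  expect_length(eligible_years(1980:2010, 2005), 15)
  expect_length(eligible_years(1974:1984, 1984), 0)  # window precedes records
  expect_equal(eligible_years(1990:1992, 2005), 1990:1992)
  expect_equal(eligible_years(1960:2000, 2000, start_year = 1974), 1974:1989)
  expect_error(eligible_years(1980:1990, 1970), ">=")
})

test_that("duration, weighted duration and intensity match hand arithmetic", {
  el <- 1980:2001  # T = 22
  d <- duration_metric(c(1980, 1985, 1990, 1995, 2000), el)
  expect_equal(d$N, 5)
  expect_equal(d$T, 22)
  expect_equal(d$duration, 5 / 22)
  expect_equal(duration_metric(el, el)$duration, 1)     # exposed every year
  expect_equal(duration_metric(integer(0), el)$duration, 0)
  expect_true(is.na(duration_metric(1980, integer(0))$duration))

  expect_equal(weighted_duration_metric(0, 10), 0)
  expect_equal(weighted_duration_metric(1, 1), log(2))
  expect_equal(weighted_duration_metric(10, 20), 0.5 * log(11))
  expect_error(weighted_duration_metric(5, 4))

  expect_equal(intensity_metric(c(`1985` = 2.0), 1980:1989), 0.2)
  expect_equal(intensity_metric(numeric(0), 1980:1989), 0)
  expect_true(is.na(intensity_metric(c(`1985` = 2.0), integer(0))))
})

test_that("window binning, clipping and exclusion beyond lag 40", {
  # exposure year 1990 with index 2005 -> lag 15 -> window 2
  we <- window_exposures(1990, c(`1990` = 1), 1974:2004, 2005)
  expect_equal(we$N, c(0, 1, 0, 0))
  # index 2016, address from 1974: windows 1-3 have T=10, window 4 covers
  # lags 31-40 -> years 1976-1985 -> T = 10
  we2 <- window_exposures(integer(0), numeric(0), 1974:2016, 2016)
  expect_equal(we2$T_years, c(10, 10, 10, 10))
  # index 2010: window 4 = 1970-1979 clipped to record era -> T = 6
  we3 <- window_exposures(integer(0), numeric(0), 1974:2010, 2010)
  expect_equal(we3$T_years[4], 6)
  # lag 41 excluded from every window
  we4 <- window_exposures(1974, c(`1974` = 5), 1974:2016, 2015)
  expect_equal(sum(we4$N), 0)
  # windows without coverage flagged missing
  we5 <- window_exposures(integer(0), numeric(0), 1996:2005, 2006)
  expect_true(all(is.na(we5$duration[2:4])))
  expect_equal(we5$T_years, c(10, 0, 0, 0))
})

test_that("pesticide filter and short-history exclusion thresholds", {
  mk_em <- function(n_exposed) {
    ids <- sprintf("S%03d", 1:40)
    metrics <- data.table::data.table(
      participant_id = ids[seq_len(n_exposed)], pesticide_id = "P001",
      loc_type = "R", N = 1L, T_years = 20L, duration = 0.05,
      weighted_duration = 0.05 * log(2), intensity = 0.1
    )
    structure(list(
      metrics = metrics,
      eligibility = data.table::data.table(participant_id = ids,
                                           loc_type = "R", T_years = 20L),
      windows = data.table::data.table(), window_eligibility = data.table::data.table(),
      participant_ids = ids,
      params = list(radius_m = 500, min_lag = 11, start_year = 1974)
    ), class = "exposure_metrics")
  }
  expect_length(pesticide_filter(mk_em(24)), 0)
  expect_equal(pesticide_filter(mk_em(25)), "P001")
  expect_equal(pesticide_filter(mk_em(1), min_exposed = 1), "P001")
  em0 <- mk_em(5)
  em0$metrics <- em0$metrics[0]
  expect_length(pesticide_filter(em0), 0)

  em <- mk_em(10)
  em$eligibility$T_years <- c(rep(9L, 10), rep(20L, 30))
  shx10 <- short_history_exclusion(em, 10)
  expect_equal(shx10$n_excluded, 10)            # T = 9 < 10 removed
  em$eligibility$T_years <- rep(5L, 40)
  expect_equal(short_history_exclusion(em, 5)$n_excluded, 0)  # exactly 5 kept
  expect_equal(short_history_exclusion(em, 0)$n_excluded, 0)
})

test_that("z-scaling uses the n-1 convention and flags degenerate strata", {
  zs <- zscore_exposure(c(0, 0, 1, 1))
  expect_true(zs$ok)
  expect_equal(zs$sd, sd(c(0, 0, 1, 1)))
  expect_equal(zs$z, c(-0.866, -0.866, 0.866, 0.866), tolerance = 1e-3)
  expect_equal(mean(zs$z), 0)
  # affine invariance
  x <- rnorm(50)
  expect_equal(zscore_exposure(x)$z, zscore_exposure(3 * x + 7)$z)
  expect_false(zscore_exposure(rep(2, 10))$ok)
  expect_false(zscore_exposure(1)$ok)
})

test_that("splitting an interval at the same coordinates changes nothing", {
  apps <- data.frame(pesticide_id = "P001",
                     year = c(1980, 1985, 1992, 1999),
                     x_m = 200, y_m = 0, pounds = c(5, 7, 9, 11),
                     field_acres = 40)
  one <- data.frame(participant_id = "S1", loc_type = "R", x_m = 0, y_m = 0,
                    start_year = 1975, end_year = 2005)
  two <- data.frame(participant_id = "S1", loc_type = "R", x_m = 0, y_m = 0,
                    start_year = c(1975, 1991), end_year = c(1990, 2005))
  pp <- data.frame(participant_id = "S1", index_year = 2016)
  em1 <- compute_exposure_metrics(apps, one, pp)
  em2 <- compute_exposure_metrics(apps, two, pp)
  expect_equal(em1$metrics, em2$metrics)
  expect_equal(em1$windows, em2$windows)
  expect_equal(em1$eligibility, em2$eligibility)
})

test_that("increasing the radius never decreases N, duration or intensity", {
  set.seed(99)
  apps <- data.frame(pesticide_id = "P001", year = sample(1974:2000, 30, TRUE),
                     x_m = runif(30, 0, 2000), y_m = runif(30, 0, 2000),
                     pounds = runif(30, 1, 50), field_acres = 40)
  addr <- data.frame(participant_id = "S1", loc_type = "R", x_m = 1000,
                     y_m = 1000, start_year = 1974, end_year = 2005)
  pp <- data.frame(participant_id = "S1", index_year = 2016)
  get <- function(r) {
    em <- compute_exposure_metrics(apps, addr, pp, radius_m = r)
    if (nrow(em$metrics) == 0)
      return(c(N = 0, duration = 0, intensity_scaled = 0))
    m <- em$metrics[1]
    # compare total in-buffer pounds (intensity x fixed T), not per-acre rate,
    # since the buffer area grows with the radius
    c(N = m$N, duration = m$duration,
      intensity_scaled = m$intensity * pi * r^2 / 4046.856)
  }
  r300 <- get(300); r600 <- get(600); r1200 <- get(1200)
  expect_true(all(r600 >= r300))
  expect_true(all(r1200 >= r600))
})

test_that("duration bounds, zero equivalence and window partition hold on
           generated worlds", {
  lc <- landscape_config(region_extent = c(0, 6000, 0, 6000), n_fields = 25,
                         n_pesticides = 3,
                         co_application_groups = list(1L, 2L, 3L))
  cc <- cohort_config(n_cases = 40, n_controls = 40,
                      region_extent = c(0, 6000, 0, 6000))
  for (seed in c(1, 2, 3)) {
    ls <- generate_landscape(lc, seed)
    ap <- generate_applications(ls, lc, seed)
    co <- generate_cohort(cc, seed)
    em <- compute_exposure_metrics(ap, co$addresses, co$participants)
    m <- em$metrics
    expect_true(all(m$duration >= 0 & m$duration <= 1))
    expect_true(all(m$N <= m$T_years))
    expect_true(all(m$weighted_duration >= 0))
    # sparse rows exist iff exposed: duration > 0 <=> intensity > 0
    expect_true(all((m$duration > 0) == (m$intensity > 0)))
    w <- em$windows
    expect_true(all(w$duration > 0 & w$duration <= 1))

    # partition conservation: residential exposed address-years at lags 1-40
    # equal the sum of window counts
    ae <- annual_exposure(ap, co$addresses)
    ex <- merge(ae$exposure, co$participants[, c("participant_id", "index_year")],
                by = "participant_id")
    ex <- ex[ex$loc_type == "R" & ex$year >= 1974, ]
    lag <- ex$index_year - ex$year
    expect_equal(sum(lag >= 1 & lag <= 40), sum(w$N_w))
  }
})
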