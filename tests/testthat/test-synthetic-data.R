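test_that("generators are pure functions of (config, seed)", {
  lc <- landscape_config(region_extent = c(0, 8000, 0, 8000), n_fields = 50,
                         n_pesticides = 4)
  expect_identical(generate_landscape(lc, 11), generate_landscape(lc, 11))
  expect_false(identical(generate_landscape(lc, 11), generate_landscape(lc, 12)))
  ls <- generate_landscape(lc, 11)
  expect_identical(generate_applications(ls, lc, 11),
                   generate_applications(ls, lc, 11))
  cc <- cohort_config(n_cases = 40, n_controls = 40,
                      region_extent = c(0, 8000, 0, 8000))
  expect_identical(generate_cohort(cc, 3), generate_cohort(cc, 3))
})

test_that("landscape respects counts, extent and validation", {
  lc <- landscape_config(region_extent = c(0, 20000, 0, 20000), n_fields = 500,
                         n_pesticides = 10)
  ls <- generate_landscape(lc, 5)
  expect_equal(nrow(ls), 500)
  expect_true(all(ls$x >= 0 & ls$x <= 20000 & ls$y >= 0 & ls$y <= 20000))
  expect_true(all(ls$acres > 0))
  expect_setequal(unique(ls$group), 1:10)  # cyclic assignment covers groups

  empty <- generate_landscape(landscape_config(n_fields = 0, n_pesticides = 2), 1)
  expect_equal(nrow(empty), 0)

  expect_error(landscape_config(region_extent = c(0, 0, 0, 10)), "positive area")
  expect_error(landscape_config(annual_application_prob = 1.2), "\\[0, 1\\]")
  expect_error(landscape_config(n_pesticides = 3,
                                co_application_groups = list(1:2)),
               "partition")
})

test_that("application records follow the configured probability and span", {
  lc0 <- landscape_config(region_extent = c(0, 1000, 0, 1000), n_fields = 5,
                          n_pesticides = 2, annual_application_prob = 0)
  ls0 <- generate_landscape(lc0, 1)
  expect_equal(nrow(generate_applications(ls0, lc0, 1)), 0)

  lc1 <- landscape_config(region_extent = c(0, 1000, 0, 1000), n_fields = 1,
                          n_pesticides = 1, years = 1974:1983,
                          annual_application_prob = 1)
  ls1 <- generate_landscape(lc1, 1)
  ap1 <- generate_applications(ls1, lc1, 1)
  expect_equal(nrow(ap1), 10)  # one forced record per year
  expect_setequal(ap1$year, 1974:1983)
  expect_true(all(ap1$pounds > 0))

  expect_error(generate_applications(generate_landscape(
    landscape_config(n_fields = 0, n_pesticides = 1), 1), lc1, 1), "empty")
})

test_that("cohort structure: intervals, moves, occupational cessation", {
  cc <- cohort_config(n_cases = 30, n_controls = 30, address_move_rate = 0,
                      region_extent = c(0, 5000, 0, 5000))
  co <- generate_cohort(cc, 2)
  res <- co$addresses[co$addresses$loc_type == "R", ]
  expect_equal(nrow(res), 60)  # exactly one residential interval each
  expect_true(all(res$start_year == 1974))
  expect_equal(res$end_year[match(co$participants$participant_id,
                                  res$participant_id)],
               co$participants$index_year)

  cc5 <- cohort_config(n_cases = 50, n_controls = 10,
                       occupational_cessation_years = 5, p_occupational = 1,
                       region_extent = c(0, 5000, 0, 5000))
  co5 <- generate_cohort(cc5, 4)
  pp <- co5$participants
  occ <- co5$addresses[co5$addresses$loc_type == "O", ]
  occ_end <- tapply(occ$end_year, occ$participant_id, max)
  cases <- pp[pp$case == 1, ]
  have <- intersect(cases$participant_id, names(occ_end))
  expect_true(all(occ_end[have] <=
                    cases$index_year[match(have, cases$participant_id)] - 5))

  # same-type intervals never overlap
  dt <- data.table::as.data.table(co5$addresses)
  dt <- dt[order(participant_id, loc_type, start_year)]
  gap <- dt[, start_year - data.table::shift(end_year),
            by = .(participant_id, loc_type)]$V1
  expect_true(all(gap[!is.na(gap)] >= 1))
})

test_that("cohort counts and covariate marginals match the configuration", {
  co <- generate_cohort(cohort_config(n_cases = 829, n_controls = 824), 9)
  expect_equal(nrow(co$participants), 1653)
  expect_equal(sum(co$participants$case), 829)
  expect_true(all(co$participants$index_year %in% 1998:2016))
  # cases drawn slightly older on average (configured shift direction)
  expect_gt(mean(co$participants$age[co$participants$case == 1]),
            mean(co$participants$age[co$participants$case == 0]) - 0.5)
  expect_setequal(unique(co$participants$smoking), c("non", "former", "current"))
})

test_that("outcome simulation calibrates the case fraction and is reproducible", {
  cc <- cohort_config(n_cases = 829, n_controls = 824,
                      region_extent = c(0, 5000, 0, 5000), p_occupational = 0)
  co <- generate_cohort(cc, 5)
  y1 <- simulate_outcomes(co$participants, NULL, list(), seed = 8)
  y2 <- simulate_outcomes(co$participants, NULL, list(), seed = 8)
  expect_identical(y1, y2)
  target <- 829 / 1653
  se_bin <- sqrt(target * (1 - target) / 1653)
  expect_lt(abs(mean(y1) - target), 3 * se_bin)

  expect_error(
    simulate_outcomes(co$participants, NULL, list(),
                      covariate_log_ors = c(nope = 1), seed = 1),
    "unknown covariate"
  )
  expect_error(effect_spec("P001", "duration", Inf), "finite")
  expect_error(effect_spec("P001", "duration", 0.1, active_windows = 5),
               "subset")
})

test_that("co-application groups induce positive exposure correlation,
           disjoint groups do not", {
  # near-uniform fields: co-clustering of fields with homes would otherwise
  # correlate even disjoint pesticides through shared geography
  base <- list(region_extent = c(0, 8000, 0, 8000), n_fields = 40,
               n_pesticides = 2, field_cluster_sd = 8000)
  # single fixed address and common index year: differential mobility and
  # observation length would otherwise correlate exposure to everything
  cc <- cohort_config(n_cases = 250, n_controls = 250,
                      region_extent = c(0, 8000, 0, 8000),
                      address_move_rate = 0, p_occupational = 0,
                      index_year_range = c(2016, 2016))
  # single worlds carry regional structure (clustered fields near clustered
  # homes), so the disjoint-group correlation is centered at zero across
  # worlds rather than negligible in each one
  cors <- sapply(21:24, function(seed) {
    co <- generate_cohort(cc, seed)
    sapply(list(shared = list(1:2), disjoint = list(1L, 2L)), function(g) {
      lc <- do.call(landscape_config, c(base, list(co_application_groups = g)))
      ls <- generate_landscape(lc, seed)
      ap <- generate_applications(ls, lc, seed)
      em <- compute_exposure_metrics(ap, co$addresses, co$participants)
      ids <- co$participants$participant_id
      cor(exposure_vector(em, "P001", "R", "duration", ids),
          exposure_vector(em, "P002", "R", "duration", ids))
    })
  })
  expect_true(all(cors["shared", ] > 0))
  expect_lt(abs(mean(cors["disjoint", ])), 0.15)
  expect_gt(mean(cors["shared", ]), mean(cors["disjoint", ]) + 0.1)
})
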