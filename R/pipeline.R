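#' Assemble a full study configuration
#'
#' Bundles the generator configs, planted effects, exposure-engine and scan
#' parameters, and the master seed into one serializable object. Every run
#' writes the resolved configuration beside its results.
#'
#' @param scenario Free-text scenario name (see [scenario_config()] for
#'   presets).
#' @param landscape A [landscape_config()].
#' @param cohort A [cohort_config()].
#' @param effects List of [effect_spec()] objects.
#' @param master_seed Master seed; per-stage seeds are derived from it.
#' @param radius_m,min_lag,start_year Exposure-engine parameters.
#' @param min_exposed,min_history,fdr Scan parameters.
#' @param dlm_max_pesticides Cap on pesticides carried into the lag models.
#' @param ridge Run the ridge sensitivity model in the pipeline.
#' @return A `study_config` list.
#' @export
study_config <- function(scenario = "custom",
                         landscape = landscape_config(),
                         cohort = cohort_config(),
                         effects = list(),
                         master_seed = 1,
                         radius_m = 500, min_lag = 11, start_year = 1974,
                         min_exposed = 25, min_history = 0, fdr = 0.05,
                         dlm_max_pesticides = 5, ridge = TRUE) {
  stopifnot(inherits(landscape, "landscape_config"),
            inherits(cohort, "cohort_config"))
  for (ef in effects) stopifnot(inherits(ef, "effect_spec"))
  structure(list(
    scenario = scenario, landscape = landscape, cohort = cohort,
    effects = effects, master_seed = master_seed, radius_m = radius_m,
    min_lag = min_lag, start_year = start_year, min_exposed = min_exposed,
    min_history = min_history, fdr = fdr,
    dlm_max_pesticides = dlm_max_pesticides, ridge = ridge
  ), class = "study_config")
}

#' Preset study scenarios
#'
#' Named configurations exercising distinct pipeline behaviours:
#' \describe{
#'   \item{null_scan}{The full-size study under the global null: 287
#'     independent pesticides (singleton co-application groups), 1653
#'     participants, no planted effects. Used for scan calibration.}
#'   \item{single_effect}{One pesticide on a small dense landscape, a
#'     residential-only cohort, and a planted cumulative duration effect of
#'     log(1.25) per SD — the magnitude of the strongest association the
#'     scan is designed to detect.}
#'   \item{window_effect}{As `single_effect` but the effect (log(1.5) per SD)
#'     is confined to window 3 (lags 21--30), the latency pattern the
#'     distributed-lag models target.}
#'   \item{co_exposure}{Six pesticides of which three share a co-application
#'     group, inducing correlated exposures; no planted effects.}
#' }
#'
#' @param name Scenario name.
#' @param master_seed Master seed.
#' @return A [study_config()].
#' @export
scenario_config <- function(name = c("null_scan", "single_effect",
                                     "window_effect", "co_exposure"),
                            master_seed = 1) {
  name <- match.arg(name)
  small_landscape <- landscape_config(
    region_extent = c(0, 6000, 0, 6000), n_fields = 20, n_pesticides = 1,
    field_cluster_sd = 1200
  )
  small_cohort <- cohort_config(p_occupational = 0,
                                region_extent = c(0, 6000, 0, 6000))
  switch(name,
    null_scan = study_config("null_scan", master_seed = master_seed,
                             dlm_max_pesticides = 3),
    single_effect = study_config(
      "single_effect", landscape = small_landscape, cohort = small_cohort,
      effects = list(effect_spec("P001", "duration", log(1.25))),
      master_seed = master_seed, dlm_max_pesticides = 1
    ),
    window_effect = study_config(
      "window_effect", landscape = small_landscape, cohort = small_cohort,
      effects = list(effect_spec("P001", "duration", log(1.5),
                                 active_windows = 3L)),
      master_seed = master_seed, dlm_max_pesticides = 1
    ),
    co_exposure = study_config(
      "co_exposure",
      landscape = landscape_config(
        region_extent = c(0, 8000, 0, 8000), n_fields = 60, n_pesticides = 6,
        co_application_groups = list(1:3, 4L, 5L, 6L), field_cluster_sd = 1200
      ),
      cohort = cohort_config(region_extent = c(0, 8000, 0, 8000)),
      master_seed = master_seed, dlm_max_pesticides = 2
    )
  )
}

config_schema <- list(
  top = c("scenario", "landscape", "cohort", "effects", "master_seed",
          "radius_m", "min_lag", "start_year", "min_exposed", "min_history",
          "fdr", "dlm_max_pesticides", "ridge"),
  landscape = c("region_extent", "n_fields", "field_cluster_sd",
                "n_pesticides", "co_application_groups", "years",
                "annual_application_prob", "pounds_meanlog", "pounds_sdlog",
                "acres_meanlog", "acres_sdlog"),
  cohort = c("n_cases", "n_controls", "index_year_range", "address_move_rate",
             "occupational_cessation_years", "p_occupational",
             "region_extent", "covariates"),
  effect = c("pesticide_id", "metric", "log_or_per_sd", "active_windows")
)

#' Write a study configuration to YAML
#'
#' @param config A [study_config()].
#' @param path Output file path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$landscape <- unclass(x$landscape)
  x$cohort <- unclass(x$cohort)
  # yaml drops names of atomic vectors; keep probability names via mappings
  x$cohort$covariates$ethnicity_probs <-
    as.list(x$cohort$covariates$ethnicity_probs)
  x$cohort$covariates$smoking_probs <-
    as.list(x$cohort$covariates$smoking_probs)
  x$effects <- lapply(x$effects, unclass)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Unknown keys at any level are errors, so typos never silently change a
#' study.
#'
#' @param path YAML file written by [write_study_config()] (or by hand with
#'   the same keys).
#' @return A validated [study_config()].
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  check_keys <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad)) stop_config("unknown config key(s) in ", where, ": ",
                                 paste(bad, collapse = ", "))
  }
  check_keys(names(x), config_schema$top, "top level")
  check_keys(names(x$landscape), config_schema$landscape, "landscape")
  check_keys(names(x$cohort), config_schema$cohort, "cohort")
  ls_cfg <- do.call(landscape_config, x$landscape %||% list())
  co_cfg <- do.call(cohort_config, x$cohort %||% list())
  effects <- lapply(x$effects %||% list(), function(e) {
    check_keys(names(e), config_schema$effect, "effect")
    effect_spec(e$pesticide_id, e$metric, e$log_or_per_sd,
                e$active_windows %||% integer(0))
  })
  args <- x[setdiff(names(x), c("landscape", "cohort", "effects"))]
  do.call(study_config, c(list(landscape = ls_cfg, cohort = co_cfg,
                               effects = effects), args))
}

#' Run the full synthetic study pipeline
#'
#' Simulate, build exposures, scan, fit lag models, and compare metrics, all
#' from one configuration and one master seed. Deterministic: the same
#' config and seed give byte-identical output files. Each stage logs to
#' stderr; a stage failure aborts with a stage-tagged message, retaining the
#' outputs already written.
#'
#' @param config A [study_config()] or preset name for [scenario_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param seed Override of `config$master_seed`.
#' @param quiet Suppress stage logging.
#' @return (Invisibly) list with all intermediate and final artifacts:
#'   `landscape`, `applications`, `cohort`, `exposure`, `scan_duration`,
#'   `scan_intensity`, `dlm`, `comparison`, `agreement`, `manifest`.
#' @export
run_full_study <- function(config, out_dir = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- scenario_config(config)
  stopifnot(inherits(config, "study_config"))
  seed <- seed %||% config$master_seed
  say <- function(...) if (!quiet) message("[pestwas] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(name, " (", sprintf("%.1fs", proc.time()[["elapsed"]] - t0), ")")
    out
  }

  landscape <- stage("landscape", generate_landscape(config$landscape, seed))
  applications <- stage("applications",
                        generate_applications(landscape, config$landscape, seed))
  cohort <- stage("cohort", generate_cohort(config$cohort, seed))
  participants <- cohort$participants
  em <- stage("exposure", compute_exposure_metrics(
    applications, cohort$addresses, participants,
    radius_m = config$radius_m, min_lag = config$min_lag,
    start_year = config$start_year, years = config$landscape$years
  ))
  participants$case <- stage("outcomes", simulate_outcomes(
    participants, em, config$effects, seed = seed
  ))

  scan_d <- stage("scan duration", run_pwas(
    em, participants, "duration", min_exposed = config$min_exposed,
    min_history = config$min_history, fdr = config$fdr
  ))
  scan_i <- stage("scan intensity", run_pwas(
    em, participants, "intensity", min_exposed = config$min_exposed,
    min_history = config$min_history, fdr = config$fdr
  ))

  # lag models for the leading pesticides (planted ones always included)
  meta_d <- as.data.table(scan_d)[loc_type == "meta"]
  lead <- meta_d[q < config$fdr][order(q), pesticide_id]
  planted <- vapply(config$effects, `[[`, "", "pesticide_id")
  dlm_pest <- unique(c(planted, head(lead, config$dlm_max_pesticides)))
  dlm_pest <- head(dlm_pest, max(config$dlm_max_pesticides, length(planted)))
  dlm_rows <- stage("lag models", {
    Xc <- build_covariate_matrix(participants)
    rows <- list()
    for (pid in dlm_pest) {
      for (met in c("duration", "intensity")) {
        wm <- window_matrix(em, pid, participants$participant_id, metric = met)
        s <- tryCatch(pooled_window_sd(wm), error = function(e) NA_real_)
        if (!is.finite(s)) next
        d <- fit_dlm(wm, participants$case, Xc)
        add <- function(tab, model)
          data.table(pesticide_id = pid, metric = met, model = model,
                     tab[, .(window, or, ci_low, ci_high)])
        rows[[length(rows) + 1L]] <- add(d$windows, "dlm")
        rows[[length(rows) + 1L]] <-
          add(fit_window_logistic(wm, participants$case, Xc, adjusted = TRUE),
              "window_adj")
        rows[[length(rows) + 1L]] <-
          add(fit_window_logistic(wm, participants$case, Xc, adjusted = FALSE),
              "window_unadj")
        if (isTRUE(config$ridge)) {
          rg <- fit_ridge_windows(wm, participants$case, Xc, seed = seed)
          rows[[length(rows) + 1L]] <- data.table(
            pesticide_id = pid, metric = met, model = "ridge",
            window = 1:4, or = exp(unname(rg$window_beta)),
            ci_low = NA_real_, ci_high = NA_real_
          )
        }
      }
    }
    rbindlist(rows, fill = TRUE)
  })

  comparison <- stage("comparison", {
    pairs <- tryCatch(paired_or_table(scan_d, scan_i, "intersection",
                                      fdr = config$fdr),
                      error = function(e) NULL)
    if (is.null(pairs) || nrow(pairs) < 3L)
      pairs <- tryCatch(paired_or_table(scan_d, scan_i, "all"),
                        error = function(e) NULL)
    if (is.null(pairs) || nrow(pairs) < 3L) list(pairs = pairs, agreement = NULL)
    else list(pairs = pairs, agreement = agreement_summary(pairs))
  })

  counts_d <- attr(scan_d, "counts")
  manifest <- list(
    package = "pestwas",
    version = as.character(utils::packageVersion("pestwas")),
    scenario = config$scenario, master_seed = seed,
    n_participants = nrow(participants),
    n_cases_simulated = sum(participants$case),
    n_application_records = nrow(applications),
    n_no_eligible_years = list(
      R = nrow(participants) - em$eligibility[loc_type == "R", .N],
      O = nrow(participants) - em$eligibility[loc_type == "O", .N]
    ),
    n_excluded_short_history = counts_d$n_excluded_short_history,
    n_pesticides_eligible = counts_d$n_pesticides_eligible,
    n_nonconverged_duration = counts_d$n_nonconverged,
    discoveries_duration = meta_d[q < config$fdr, .N],
    discoveries_intensity = as.data.table(scan_i)[loc_type == "meta" &
                                                    q < config$fdr, .N],
    dlm_pesticides = as.list(dlm_pest)
  )

  if (!is.null(out_dir)) {
    stage("write outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(x, f) fwrite(x, file.path(out_dir, f))
      wr(applications, "applications.csv")
      wr(cohort$addresses, "addresses.csv")
      wr(participants, "participants.csv")
      wr(em$metrics, "exposure_metrics.csv")
      wr(em$windows, "exposure_windows.csv")
      wr(rbind(as.data.table(scan_d), as.data.table(scan_i)),
         "pwas_results.csv")
      if (nrow(dlm_rows)) wr(dlm_rows, "dlm_results.csv")
      if (!is.null(comparison$pairs)) wr(comparison$pairs, "comparison.csv")
      if (!is.null(comparison$agreement))
        jsonlite::write_json(comparison$agreement,
                             file.path(out_dir, "agreement.json"),
                             auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      write_study_config(config, file.path(out_dir, "config.yaml"))
    })
  }

  invisible(list(
    landscape = landscape, applications = applications, cohort = cohort,
    participants = participants, exposure = em, scan_duration = scan_d,
    scan_intensity = scan_i, dlm = dlm_rows, comparison = comparison,
    manifest = manifest, config = config
  ))
}
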