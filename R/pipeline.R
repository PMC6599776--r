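#' Configuration for a full pipeline run
#'
#' Bundles every stage's settings: the simulation ground truth (or paths
#' to input tables), windowing and classification choices, the candidate
#' model set, scenario orders and the displacement comparison. All
#' randomness derives from `seed`.
#'
#' @param truth a [truth_config()] describing the simulated study, or
#'   `NULL` when `paths` supplies real input tables.
#' @param paths optional named list of CSV paths (`detections`, `events`,
#'   `ais`, `sites`) in the dialects written by [write_simulation()].
#' @param duration_h window durations to analyse (subset of `c(12, 24)`).
#' @param threshold response threshold on the proportional decrease.
#' @param min_gap_h eligibility gap, 96 or 192 (robustness variant).
#' @param exclude_within_km site-exclusion radius around piling (0 = off;
#'   1 km is the robustness variant).
#' @param null_draws resampling draws for the null distribution.
#' @param n_reference_sites number of far-field sites used for the null.
#' @param scenario_orders raw piling-order values for threshold curves.
#' @param add_orders length-2 vector: order values for the with-ADD /
#'   without-ADD 12-h contrast.
#' @param density porpoise density (individuals per km^2).
#' @param guidance_radius_km guidance radius for displacement comparison.
#' @param ci_draws fixed-effects draws for CIs.
#' @param coverage_margin_h monitoring margin before the first and after
#'   the last event (also hosts the null-distribution reference periods).
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(truth = truth_config(), paths = NULL,
                       duration_h = c(24, 12), threshold = 0.5,
                       min_gap_h = 96, exclude_within_km = 0,
                       null_draws = 1000, n_reference_sites = 12,
                       scenario_orders = NULL, add_orders = c(62, 61),
                       density = 0.274, guidance_radius_km = 26,
                       ci_draws = 2000, coverage_margin_h = 240,
                       seed = 1L) {
  if (!min_gap_h %in% c(96, 192)) {
    stop_input("min_gap_h must be 96 or 192")
  }
  if (!all(duration_h %in% c(12, 24))) stop_input("duration_h must be 12/24")
  structure(list(truth = truth, paths = paths, duration_h = duration_h,
                 threshold = threshold, min_gap_h = min_gap_h,
                 exclude_within_km = exclude_within_km,
                 null_draws = null_draws,
                 n_reference_sites = n_reference_sites,
                 scenario_orders = scenario_orders, add_orders = add_orders,
                 density = density,
                 guidance_radius_km = guidance_radius_km,
                 ci_draws = ci_draws, coverage_margin_h = coverage_margin_h,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> detection-positive hours -> null
#' distribution -> response classification -> model selection ->
#' 50%-response thresholds -> displacement, writing every intermediate and
#' result as CSV/JSON into `out_dir` together with a machine-readable
#' manifest. Given the same configuration and seed, output files are
#' byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and only returns the result bundle.
#' @return (invisibly) a list with the intermediate and final objects:
#'   `sim`, `dph`, `null`, `records` (per duration), `models`,
#'   `model_tables`, `thresholds`, `add_contrast`, `displacement`,
#'   `exclusions`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  ## ---- inputs -----------------------------------------------------------
  if (!is.null(config$paths)) {
    records_raw <- read_detections_csv(config$paths$detections)
    events <- tibble::as_tibble(read.csv(config$paths$events))
    events$start <- as.POSIXct(events$start, format = "%Y-%m-%dT%H:%M:%OSZ",
                               tz = "UTC")
    events$end <- as.POSIXct(events$end, format = "%Y-%m-%dT%H:%M:%OSZ",
                             tz = "UTC")
    sites <- tibble::as_tibble(read.csv(config$paths$sites))
    ais <- if (!is.null(config$paths$ais)) {
      a <- tibble::as_tibble(read.csv(config$paths$ais))
      a$timestamp <- as.POSIXct(a$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                                tz = "UTC")
      a
    } else NULL
    t_start <- floor_hour(min(records_raw$timestamp))
    t_end <- floor_hour(max(records_raw$timestamp)) + 3600
    truth <- config$truth %||% truth_config(seed = seed)
    sels <- compute_event_sels(sites, events,
      source_spectrum = default_piling_spectrum(truth$source_level),
      spreading_coeff = truth$spreading_coeff,
      absorption_db_per_km = truth$absorption_db_per_km)
    sim <- list(config = truth, sites = sites, events = events, ais = ais,
                records = records_raw, sels = sels, truth = NULL,
                t_start = t_start, t_end = t_end)
  } else {
    truth <- config$truth
    truth$seed <- child_seed(seed, "simulate")
    # coverage extends before the first and after the last event so that
    # pre- and post-construction reference periods exist for the null
    sched <- generate_schedule(truth)
    sim <- simulate_study(truth,
      t_start = floor_hour(sched$start[1] - hours(config$coverage_margin_h)),
      t_end = floor_hour(max(sched$end) + hours(config$coverage_margin_h)))
  }

  ## ---- detection-positive hours ----------------------------------------
  dph <- compute_dph(sim$records, sim$t_start, sim$t_end)
  daily <- daily_occurrence_summary(dph)

  ## ---- null distribution from far-field reference sites ----------------
  ref_ids <- sim$sels |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(min_km = min(.data$distance_km), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$min_km)) |>
    dplyr::slice_head(n = config$n_reference_sites)
  ref_dph <- dph[dph$site_id %in% ref_ids$site_id, ]
  first_start <- min(sim$events$start); last_end <- max(sim$events$end)
  null_periods <- tibble::tibble(
    start = c(sim$t_start + hours(48), floor_hour(last_end) + hours(48)),
    end = c(floor_hour(first_start) - hours(24), sim$t_end - hours(24)))
  null_periods <- null_periods[null_periods$end > null_periods$start, ]
  null <- build_null_distribution(ref_dph, null_periods,
                                  n_draws = config$null_draws,
                                  seed = child_seed(seed, "null"),
                                  threshold = config$threshold)

  ## ---- response records -------------------------------------------------
  records <- list()
  exclusions <- list()
  for (dh in config$duration_h) {
    r <- assemble_records(dph, sim$events, sim$sels, sites = sim$sites,
                          ais = sim$ais, duration_h = dh,
                          threshold = config$threshold,
                          min_gap_h = config$min_gap_h,
                          coverage_start = sim$t_start,
                          exclude_within_km = config$exclude_within_km)
    records[[as.character(dh)]] <- r
    exclusions[[as.character(dh)]] <- attr(r, "exclusions")
  }

  ## ---- model selection --------------------------------------------------
  # drop the vessel term when the simulated counts carry no variation
  vessel_term <- function(rec, preferred) {
    if (sd(rec[[preferred]]) > 0) preferred else "none"
  }
  models <- list(); model_tables <- list()
  if ("24" %in% names(records)) {
    v24 <- vessel_term(records[["24"]], "vessels_1km")
    specs24 <- list(
      dist_x_order = model_spec("log_distance", interaction = TRUE,
                                vessel = v24),
      dist_no_int = model_spec("log_distance", interaction = FALSE,
                               vessel = v24),
      asel_x_order = model_spec("sel_audiogram", interaction = TRUE,
                                vessel = v24),
      usel_x_order = model_spec("sel_unweighted", interaction = TRUE,
                                vessel = v24))
    model_tables[["24"]] <- model_table(records[["24"]], specs24)
    fits <- attr(model_tables[["24"]], "fits")
    if (inherits(fits$dist_x_order, "error")) {
      stop_input("model-selection stage failed for the 24-h records: ",
                 conditionMessage(fits$dist_x_order))
    }
    models[["24"]] <- fits$dist_x_order
    models[["24_sel"]] <- fits$asel_x_order
  }
  if ("12" %in% names(records)) {
    has_add_var <- length(unique(records[["12"]]$add_used)) > 1
    v12 <- vessel_term(records[["12"]], "vessels_500m")
    spec12 <- model_spec("log_distance", interaction = TRUE,
                         add = has_add_var, vessel = v12)
    models[["12"]] <- fit_probit_glmm(records[["12"]], spec12)
    if (has_add_var) {
      m12_noadd <- fit_probit_glmm(records[["12"]],
        model_spec("log_distance", interaction = TRUE, add = FALSE,
                   vessel = v12))
      models[["12_add_lrt"]] <- lrt(m12_noadd, models[["12"]])
    }
  }

  ## ---- thresholds and displacement --------------------------------------
  orders <- config$scenario_orders %||%
    unique(round(quantile7(sim$events$order, c(0, 0.5, 1))))
  thresholds <- NULL; displacement <- NULL; addc <- NULL
  if (!is.null(models[["24"]])) {
    thresholds <- dplyr::bind_rows(lapply(orders, function(o) {
      th <- threshold_50(models[["24"]], scenario(o),
                         draws = config$ci_draws,
                         seed = child_seed(seed, paste0("thr", o)))
      tibble::tibble(duration_h = 24, axis = th$axis, order = o,
                     estimate = th$estimate, ci_low = th$ci_low,
                     ci_high = th$ci_high)
    }))
    displacement <- dplyr::bind_rows(lapply(
      orders[c(1, length(orders))], function(o) {
        d <- displaced_individuals(models[["24"]], scenario(o),
                                   density = config$density,
                                   radius_km = config$guidance_radius_km,
                                   draws = config$ci_draws,
                                   seed = child_seed(seed, paste0("disp", o)))
        tibble::tibble(order = o, n_displaced = d$n_displaced,
                       n_rounded = d$n_rounded, ci_low = d$ci_low,
                       ci_high = d$ci_high, guidance_n = d$guidance_n,
                       pct_of_guidance = d$pct_of_guidance)
      }))
  }
  if (!is.null(models[["12"]]) &&
      "add_used" %in% names(models[["12"]]$coefficients)) {
    addc <- add_contrast(models[["12"]], config$add_orders[1],
                         config$add_orders[2], draws = config$ci_draws,
                         seed = child_seed(seed, "addc"))
  }

  bundle <- list(sim = sim, dph = dph, daily = daily, null = null,
                 records = records, models = models,
                 model_tables = model_tables, thresholds = thresholds,
                 add_contrast = addc, displacement = displacement,
                 exclusions = exclusions, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

serialize_model <- function(m) {
  list(coefficients = as.list(m$coefficients),
       fixed_cov = unname(as.data.frame(m$fixed_cov)),
       re_variance = m$re_variance, re_sd = m$re_sd,
       loglik = m$loglik, aic = m$aic, n_obs = m$n_obs,
       n_groups = m$n_groups, n_par = m$n_par,
       scaling = as.data.frame(m$scaling),
       exposure = m$exposure, residual_acf1 = m$residual_acf1,
       converged = m$converged, ridge_used = m$ridge_used)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, nm) write.csv(x, file.path(out_dir, nm),
                                    row.names = FALSE)
  wjson <- function(x, nm) jsonlite::write_json(
    x, file.path(out_dir, nm), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")

  daily <- bundle$daily; daily$day <- format(daily$day)
  wcsv(daily, "dph_daily.csv")
  wcsv(tibble::tibble(prop_change = bundle$null$samples),
       "null_samples.csv")
  wjson(list(n_draws = bundle$null$n_draws,
             quantile_1pct = bundle$null$quantile_1pct,
             threshold = bundle$null$threshold,
             n_redrawn = bundle$null$n_redrawn), "null_summary.json")
  for (dh in names(bundle$records)) {
    r <- bundle$records[[dh]]
    wcsv(r, sprintf("records_%sh.csv", dh))
    wcsv(bundle$exclusions[[dh]], sprintf("exclusions_%sh.csv", dh))
  }
  for (dh in names(bundle$model_tables)) {
    tab <- bundle$model_tables[[dh]]
    wcsv(as.data.frame(tab), sprintf("model_table_%sh.csv", dh))
  }
  for (nm in names(bundle$models)) {
    m <- bundle$models[[nm]]
    if (inherits(m, "probit_glmm")) {
      wjson(serialize_model(m), sprintf("model_%s.json", nm))
    } else {
      wjson(m, sprintf("model_%s.json", nm))
    }
  }
  if (!is.null(bundle$thresholds)) wcsv(bundle$thresholds, "thresholds.csv")
  if (!is.null(bundle$add_contrast)) wcsv(bundle$add_contrast,
                                          "add_contrast.csv")
  if (!is.null(bundle$displacement)) wcsv(bundle$displacement,
                                          "displacement.csv")
  cfg <- bundle$config
  cfg_json <- jsonlite::toJSON(prep_config(cfg), auto_unbox = TRUE,
                               digits = NA, na = "null")
  manifest <- list(
    package = "piledose",
    version = as.character(utils::packageVersion("piledose")),
    seed = cfg$seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                        (seq_len(nchar(cfg_json)) %% 97 + 1))),
    config = prep_config(cfg),
    excluded_counts = lapply(bundle$exclusions, function(e)
      as.list(table(e$reason))))
  wjson(manifest, "manifest.json")
  invisible(out_dir)
}

prep_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$truth)) {
    tr <- unclass(out$truth)
    tr$start_time <- format(tr$start_time, "%Y-%m-%dT%H:%M:%SZ")
    tr$site_positions <- NULL
    out$truth <- tr
  }
  out
}
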