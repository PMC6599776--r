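#' Ground-truth configuration for the study simulator
#'
#' Collects every parameter of the synthetic study: the piling schedule,
#' the monitoring array, baseline detection rates and their diel/seasonal
#' structure, and the ground-truth probit dose-response curve whose
#' recovery the downstream pipeline is validated against.
#'
#' The truth curve at piling order `o` (interpolation position
#' `s = (o - o_first)/(o_last - o_first)`) is
#' `p_true = Phi( a(s) - b(s) log d + beta_add (add - 1) + beta_v v/100 )`,
#' with the probit intercept `a(s)` and the log-distance slope `b(s)` both
#' linearly interpolated between first/last-event anchors
#' (`a = b * log ed50` at each anchor). Both the 50%-response distance and
#' the steepness of the curve therefore attenuate over the construction
#' period, and the truth lies exactly in the model family
#' `exposure * order` that the fitting stage assumes. `p_true` at the
#' first-event ED50 distance (ADD used, no vessels) is exactly 0.5, and at
#' the last-event ED50 it is also exactly 0.5.
#'
#' @param n_sites number of monitoring sites (one device per site).
#' @param site_positions optional data frame `site_id`, `x_km`, `y_km`;
#'   defaults to `n_sites` positions at log-uniform ranges 0.5-40 km from
#'   the piling field at uniform bearings.
#' @param n_events number of piling events (each a set of four piles).
#' @param event_interval_h nominal gap between consecutive events, hours.
#' @param piling_duration_mean_h mean duration of active piling per event.
#' @param order_indices cumulative piling-order index of each event
#'   (default spread over 1..86).
#' @param ed50_first_km,ed50_last_km ground-truth 50%-response distances at
#'   the first and last event (`ed50_first_km >= ed50_last_km > 0`).
#' @param probit_slope_per_logkm,probit_slope_last_per_logkm truth probit
#'   slope per unit natural-log km at the first and last event.
#' @param add_effect_probit probit-scale reduction in response when no ADD
#'   is used before piling (applied as `add_effect * (add_used - 1)`).
#' @param vessel_effect_probit probit-scale effect per 100 AIS position
#'   reports within 1 km during the response window.
#' @param no_add_event index (into the event sequence) of the single event
#'   piled without ADD mitigation; `NA` for none.
#' @param baseline_dph_rate expected detection-positive hours per 24 h in
#'   the absence of piling (0-24).
#' @param diel_amplitude,seasonal_amplitude fractional amplitude in [0, 1)
#'   of the diel and seasonal sinusoids modulating detection probability.
#' @param site_sd_probit SD of the per-site probit-scale detection
#'   intercept (device sensitivity / site differences).
#' @param lo_quality_rate expected low-quality (non-porpoise class) trains
#'   per device-hour.
#' @param n_ambient_vessels number of roaming background vessels in the
#'   AIS simulation.
#' @param source_level,spreading_coeff,absorption_db_per_km acoustic
#'   stand-in parameters used to simulate received levels (see
#'   [propagate_sel()]).
#' @param start_time POSIXct (or string, UTC) start of the first piling
#'   event.
#' @param seed master integer seed; all sub-streams derive from it.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(n_sites = 60, site_positions = NULL,
                         n_events = 17, event_interval_h = 120,
                         piling_duration_mean_h = 5.0,
                         order_indices = NULL,
                         ed50_first_km = 7.4, ed50_last_km = 1.3,
                         probit_slope_per_logkm = 0.8,
                         probit_slope_last_per_logkm = 0.35,
                         add_effect_probit = 0.9,
                         vessel_effect_probit = 0.2,
                         no_add_event = NULL,
                         baseline_dph_rate = 11,
                         diel_amplitude = 0.3, seasonal_amplitude = 0.2,
                         site_sd_probit = 0.3,
                         lo_quality_rate = 0.1,
                         n_ambient_vessels = 2,
                         source_level = 220, spreading_coeff = 1.8,
                         absorption_db_per_km = 0.3,
                         start_time = "2017-04-02 00:00:00",
                         seed = 1L) {
  if (n_events < 1) stop_input("n_events must be >= 1")
  if (piling_duration_mean_h <= 0 || event_interval_h <= 0) {
    stop_input("piling durations and intervals must be positive")
  }
  if (!(ed50_first_km >= ed50_last_km && ed50_last_km > 0)) {
    stop_input("need ed50_first_km >= ed50_last_km > 0")
  }
  if (baseline_dph_rate < 0 || baseline_dph_rate > 24) {
    stop_input("baseline_dph_rate must be in [0, 24]")
  }
  if (site_sd_probit < 0) stop_input("site_sd_probit must be >= 0")
  if (any(c(diel_amplitude, seasonal_amplitude) < 0) ||
      any(c(diel_amplitude, seasonal_amplitude) >= 1)) {
    stop_input("amplitudes must lie in [0, 1)")
  }
  order_indices <- order_indices %||% round(seq(1, 86, length.out = n_events))
  if (length(order_indices) != n_events ||
      is.unsorted(order_indices, strictly = n_events > 1)) {
    stop_input("order_indices must be strictly increasing, one per event")
  }
  if (is.null(no_add_event)) {
    # by default the event nearest piling order 61 is the unmitigated one
    no_add_event <- if (n_events > 1) which.min(abs(order_indices - 61)) else NA
  }
  structure(list(
    n_sites = n_sites, site_positions = site_positions,
    n_events = n_events, event_interval_h = event_interval_h,
    piling_duration_mean_h = piling_duration_mean_h,
    order_indices = order_indices,
    ed50_first_km = ed50_first_km, ed50_last_km = ed50_last_km,
    probit_slope_per_logkm = probit_slope_per_logkm,
    probit_slope_last_per_logkm = probit_slope_last_per_logkm,
    add_effect_probit = add_effect_probit,
    vessel_effect_probit = vessel_effect_probit,
    no_add_event = no_add_event,
    baseline_dph_rate = baseline_dph_rate,
    diel_amplitude = diel_amplitude,
    seasonal_amplitude = seasonal_amplitude,
    site_sd_probit = site_sd_probit,
    lo_quality_rate = lo_quality_rate,
    n_ambient_vessels = n_ambient_vessels,
    source_level = source_level, spreading_coeff = spreading_coeff,
    absorption_db_per_km = absorption_db_per_km,
    start_time = utc(start_time), seed = as.integer(seed)
  ), class = "truth_config")
}

# interpolation position of a raw piling-order index in [0, 1]
order_position <- function(cfg, order) {
  o <- cfg$order_indices
  if (length(o) == 1 || max(o) == min(o)) return(rep(0, length(order)))
  (order - min(o)) / (max(o) - min(o))
}

#' Ground-truth response probability
#'
#' Evaluates the simulator's probit dose-response curve (see
#' [truth_config()]).
#'
#' @param cfg a [truth_config()].
#' @param distance_km distance from piling, km (> 0).
#' @param order raw cumulative piling-order index.
#' @param add_used 1 if an ADD was used before piling (the default
#'   condition), 0 otherwise.
#' @param vessels AIS position reports within 1 km during the response
#'   window.
#' @return response probability in (0, 1).
#' @export
truth_response_prob <- function(cfg, distance_km, order, add_used = 1,
                                vessels = 0) {
  s <- order_position(cfg, order)
  b <- cfg$probit_slope_per_logkm +
    (cfg$probit_slope_last_per_logkm - cfg$probit_slope_per_logkm) * s
  a0 <- cfg$probit_slope_per_logkm * log(cfg$ed50_first_km)
  a1 <- cfg$probit_slope_last_per_logkm * log(cfg$ed50_last_km)
  eta <- (a0 + (a1 - a0) * s) - b * log(distance_km) +
    cfg$add_effect_probit * (add_used - 1) +
    cfg$vessel_effect_probit * vessels / 100
  pnorm(eta)
}

default_site_positions <- function(cfg) {
  with_seed(child_seed(cfg$seed, "sites"), {
    r <- exp(runif(cfg$n_sites, log(0.5), log(40)))
    th <- runif(cfg$n_sites, 0, 2 * pi)
    tibble::tibble(
      site_id = sprintf("S%02d", seq_len(cfg$n_sites)),
      x_km = r * cos(th), y_km = r * sin(th))
  })
}

#' Simulate a piling schedule
#'
#' Draws event start times with gaps around `event_interval_h` (uniform
#' jitter of -12 to +24 h, keeping every gap comfortably above the 96-h
#' eligibility rule at the default interval) and gamma-distributed piling
#' durations with the configured mean. Event times are rounded to whole
#' hours to match hourly detection binning. Exactly one configurable event
#' is flagged as piled without ADD mitigation.
#'
#' @param cfg a [truth_config()].
#' @return a tibble of events: `event_id`, `order`, `x_km`, `y_km`,
#'   `start`, `end`, `add_used`, `hammer_kj`, time-ordered.
#' @export
generate_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  with_seed(child_seed(cfg$seed, "schedule"), {
    n <- cfg$n_events
    gaps <- cfg$event_interval_h + runif(n - 1, -12, 24)
    if (any(gaps <= 0)) stop_input("event_interval_h too short: non-positive gap")
    shape <- 12
    dur <- pmax(1, rgamma2(n, mean = cfg$piling_duration_mean_h, shape = shape))
    starts <- cfg$start_time + hours(c(0, cumsum(gaps)))
    starts <- floor_hour(starts)
    ends <- floor_hour(starts + hours(dur) + 1800)  # round duration to hour
    ends <- pmax(ends, starts + 3600)
    # piling positions: within a ~6 km construction field around the origin
    px <- runif(n, -3, 3); py <- runif(n, -3, 3)
    add <- rep(TRUE, n)
    if (!is.na(cfg$no_add_event)) add[cfg$no_add_event] <- FALSE
    tibble::tibble(
      event_id = seq_len(n), order = cfg$order_indices,
      x_km = px, y_km = py, start = starts, end = ends,
      add_used = add,
      hammer_kj = sample(c(1800, 2400), n, replace = TRUE))
  })
}

rgamma2 <- function(n, mean, shape) stats::rgamma(n, shape = shape,
                                                  rate = shape / mean)

#' Simulate AIS vessel position reports
#'
#' Produces position reports at a 5-minute cadence: roaming background
#' vessels performing a random walk over the study area, plus one
#' construction vessel stationed at each piling location from 6 h before
#' the start to 6 h after the end of piling.
#'
#' @param cfg a [truth_config()].
#' @param events schedule from [generate_schedule()].
#' @param t_start,t_end POSIXct bounds of the report series.
#' @return a tibble `timestamp`, `x_km`, `y_km`, `vessel_id`, time-ordered.
#' @export
generate_ais <- function(cfg, events, t_start, t_end) {
  stopifnot(inherits(cfg, "truth_config"))
  t_start <- utc(t_start); t_end <- utc(t_end)
  with_seed(child_seed(cfg$seed, "ais"), {
    times <- seq(t_start, t_end, by = 300)
    nt <- length(times)
    out <- list()
    for (v in seq_len(cfg$n_ambient_vessels)) {
      x <- cumsum(c(runif(1, -30, 30), rnorm(nt - 1, 0, 0.5)))
      y <- cumsum(c(runif(1, -30, 30), rnorm(nt - 1, 0, 0.5)))
      x <- pmin(pmax(x, -45), 45); y <- pmin(pmax(y, -45), 45)
      out[[v]] <- tibble::tibble(timestamp = times, x_km = x, y_km = y,
                                 vessel_id = sprintf("AMB%02d", v))
    }
    for (i in seq_len(nrow(events))) {
      keep <- times >= events$start[i] - hours(6) &
        times <= events$end[i] + hours(6)
      if (!any(keep)) next
      nk <- sum(keep)
      out[[length(out) + 1L]] <- tibble::tibble(
        timestamp = times[keep],
        x_km = events$x_km[i] + rnorm(nk, 0, 0.05),
        y_km = events$y_km[i] + rnorm(nk, 0, 0.05),
        vessel_id = sprintf("CON%02d", i))
    }
    if (!length(out)) {
      return(tibble::tibble(timestamp = utc(character()), x_km = numeric(),
                            y_km = numeric(), vessel_id = character()))
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$timestamp, .data$vessel_id)
  })
}

#' Simulate click-train detection records
#'
#' Draws an hourly detection indicator per site with probability shaped by
#' a diel sinusoid, a seasonal sinusoid and a per-site probit-scale
#' intercept, then suppresses detections after piling according to the
#' ground-truth dose-response curve: each site x event draws a displacement
#' indicator with probability `p_true(d, order, ADD, vessels)`; displaced
#' site-events have detections fully suppressed for the 24 h following the
#' end of piling (so the expected proportional reduction in occurrence at
#' distance d equals `p_true(d)`). Detected hours are materialized as
#' high/moderate-quality click-train records, with additional low-quality
#' (non-porpoise class) records at `lo_quality_rate`.
#'
#' @param cfg a [truth_config()].
#' @param events schedule from [generate_schedule()]; may have zero rows.
#' @param t_start,t_end POSIXct hour-aligned bounds of the simulated
#'   monitoring period.
#' @param ais optional AIS reports used for the vessel term of the truth
#'   curve (counted within 1 km during the response window).
#' @param sites optional site table; defaults to the configured positions.
#' @return a tibble of click-train records (`site_id`, `device_id`,
#'   `timestamp`, `quality`) with attributes `sites` (site table) and
#'   `truth` (site x event tibble: `p_true`, `responded`).
#' @export
generate_detections <- function(cfg, events, t_start, t_end, ais = NULL,
                                sites = NULL) {
  stopifnot(inherits(cfg, "truth_config"))
  t_start <- utc(t_start); t_end <- utc(t_end)
  if (!is_hour_aligned(c(t_start, t_end))) {
    stop_input("monitoring period must be hour-aligned")
  }
  sites <- sites %||% cfg$site_positions %||% default_site_positions(cfg)
  ns <- nrow(sites)
  hrs <- seq(t_start, t_end - 3600, by = 3600)
  nh <- length(hrs)

  with_seed(child_seed(cfg$seed, "detections"), {
    # baseline hourly detection probability
    q0 <- cfg$baseline_dph_rate / 24
    eps <- rnorm(ns, 0, cfg$site_sd_probit)
    q_site <- if (q0 <= 0) rep(0, ns) else if (q0 >= 1) rep(1, ns) else
      pnorm(qnorm(q0) + eps)
    hod <- (as.numeric(hrs) / 3600) %% 24
    doy <- as.POSIXlt(hrs, tz = "UTC")$yday
    mod_h <- (1 + cfg$diel_amplitude * sin(2 * pi * (hod - 3) / 24)) *
      (1 + cfg$seasonal_amplitude * sin(2 * pi * (doy - 120) / 365))
    # site-major layout: ns blocks of nh hours
    q <- pmin(pmax(rep(q_site, each = nh) * rep(mod_h, times = ns), 0), 1)

    # ground-truth displacement per site x event
    truth <- NULL
    if (!is.null(events) && nrow(events) > 0) {
      tr <- tidyr::crossing(site_id = sites$site_id,
                            event_id = events$event_id)
      tr <- dplyr::left_join(tr, sites, by = "site_id")
      tr <- dplyr::left_join(tr, dplyr::rename(
        events[, c("event_id", "order", "x_km", "y_km", "end", "add_used")],
        ex = "x_km", ey = "y_km"), by = "event_id")
      tr$distance_km <- pmax(sqrt((tr$x_km - tr$ex)^2 + (tr$y_km - tr$ey)^2),
                             1e-3)
      tr$vessels <- 0L
      if (!is.null(ais) && nrow(ais) > 0) {
        for (e in seq_len(nrow(events))) {
          w0 <- events$end[e]; w1 <- w0 + hours(24)
          a <- ais[ais$timestamp >= w0 & ais$timestamp < w1, , drop = FALSE]
          if (nrow(a) == 0) next
          ri <- which(tr$event_id == events$event_id[e])
          d2 <- outer(tr$x_km[ri], a$x_km, "-")^2 +
            outer(tr$y_km[ri], a$y_km, "-")^2
          tr$vessels[ri] <- as.integer(rowSums(d2 <= 1))
        }
      }
      tr$p_true <- truth_response_prob(cfg, tr$distance_km, tr$order,
                                       as.integer(tr$add_used), tr$vessels)
      tr$responded <- rbinom(nrow(tr), 1, tr$p_true) == 1
      # full suppression for 24 h after piling end at displaced site-events
      hnum <- as.numeric(hrs)
      for (r in which(tr$responded)) {
        si <- match(tr$site_id[r], sites$site_id)
        e0 <- as.numeric(tr$end[r])
        hit <- which(hnum >= e0 & hnum < e0 + 24 * 3600)
        if (length(hit)) q[(si - 1L) * nh + hit] <- 0
      }
      truth <- tibble::as_tibble(
        tr[, c("site_id", "event_id", "order", "distance_km", "add_used",
               "vessels", "p_true", "responded")])
    }

    detected <- rbinom(length(q), 1, q) == 1

    # materialize Hi/Mod trains in detected hours
    idx <- which(detected)
    n_tr <- 1L + rpois(length(idx), 1.5)
    hour_of <- rep(hrs[((idx - 1L) %% nh) + 1L], times = n_tr)
    site_of <- rep(sites$site_id[((idx - 1L) %/% nh) + 1L], times = n_tr)
    rec <- tibble::tibble(
      site_id = site_of,
      timestamp = hour_of + runif(length(hour_of), 0, 3600 - 1e-3),
      quality = sample(c("Hi", "Mod"), length(hour_of), replace = TRUE))

    # low-quality (non-porpoise class) trains scattered uniformly
    n_lo <- rpois(1, cfg$lo_quality_rate * ns * nh)
    if (n_lo > 0) {
      rec <- dplyr::bind_rows(rec, tibble::tibble(
        site_id = sample(sites$site_id, n_lo, replace = TRUE),
        timestamp = t_start + runif(n_lo, 0, nh * 3600 - 1e-3),
        quality = "Lo"))
    }
    rec$device_id <- paste0("POD-", rec$site_id)
    rec <- dplyr::arrange(rec[, c("site_id", "device_id", "timestamp",
                                  "quality")],
                          .data$site_id, .data$timestamp)
    attr(rec, "sites") <- sites
    attr(rec, "truth") <- truth
    rec
  })
}

#' Run the full study simulator
#'
#' Generates the piling schedule, AIS tracks, click-train records and the
#' per site x event received-level table under one configuration, covering
#' from `coverage_margin_h` hours before the first event to 24 h plus one
#' day after the last.
#'
#' @param cfg a [truth_config()].
#' @param t_start,t_end optional POSIXct monitoring bounds; defaults cover
#'   all baseline and response windows.
#' @param coverage_margin_h hours of monitoring before the first piling
#'   start (default 120, enough for the 96-h eligibility rule).
#' @return a list: `config`, `sites`, `events`, `ais`, `records`, `truth`,
#'   `sels`, `t_start`, `t_end`.
#' @export
simulate_study <- function(cfg, t_start = NULL, t_end = NULL,
                           coverage_margin_h = 120) {
  events <- generate_schedule(cfg)
  t_start <- utc(t_start %||% floor_hour(events$start[1] -
                                           hours(coverage_margin_h)))
  t_end <- utc(t_end %||% floor_hour(events$end[nrow(events)] + hours(48)))
  ais <- generate_ais(cfg, events, t_start, t_end)
  records <- generate_detections(cfg, events, t_start, t_end, ais = ais)
  sites <- attr(records, "sites")
  sels <- compute_event_sels(
    sites, events,
    source_spectrum = default_piling_spectrum(cfg$source_level),
    spreading_coeff = cfg$spreading_coeff,
    absorption_db_per_km = cfg$absorption_db_per_km)
  list(config = cfg, sites = sites, events = events, ais = ais,
       records = records, truth = attr(records, "truth"), sels = sels,
       t_start = t_start, t_end = t_end)
}

#' Write a simulated study to disk
#'
#' Writes `detections.csv`, `events.csv`, `ais.csv`, `sites.csv` (ISO-8601
#' UTC timestamps) and a `truth.yaml` sidecar recording every
#' configuration value.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  det <- sim$records; det$timestamp <- fmt(det$timestamp)
  ev <- sim$events; ev$start <- fmt(ev$start); ev$end <- fmt(ev$end)
  ais <- sim$ais; ais$timestamp <- fmt(ais$timestamp)
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(ais, file.path(dir, "ais.csv"), row.names = FALSE)
  write.csv(sim$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  cfg <- sim$config
  cfg$start_time <- fmt(cfg$start_time)
  cfg$site_positions <- if (is.null(cfg$site_positions)) NULL else
    as.list(cfg$site_positions)
  yaml::write_yaml(unclass(cfg), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read click-train records written by [write_simulation()]
#'
#' @param path path to a detections CSV with columns `site_id`,
#'   `device_id`, `timestamp` (ISO-8601 UTC), `quality`.
#' @return a tibble of click-train records.
#' @export
read_detections_csv <- function(path) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                            tz = "UTC")
  if (any(is.na(d$timestamp))) stop_input("malformed timestamp in ", path)
  d
}
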