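#' Select piling events eligible for baseline-response analysis
#'
#' An event is eligible when the quiet interval between the end of piling
#' at the previous location and the start of piling at the current one
#' strictly exceeds `min_gap_h`, so that a 48-h-lagged baseline window is
#' undisturbed. The first event is eligible when monitoring coverage begins
#' at least `min_gap_h` before its start (`coverage_start`); if
#' `coverage_start` is omitted, prior coverage is assumed ample.
#'
#' @param events data frame of piling events ordered in time, with columns
#'   `event_id`, `order`, `start`, `end` (see [generate_schedule()]).
#' @param min_gap_h minimum quiet gap in hours (default 96; use 192 for the
#'   stricter robustness subset).
#' @param coverage_start optional POSIXct start of monitoring coverage.
#' @return the eligible subset of `events`, with a `gap_h` column (hours of
#'   quiet before each event; `NA` for the first).
#' @export
eligible_events <- function(events, min_gap_h = 96, coverage_start = NULL) {
  if (nrow(events) == 0) return(events)
  if (is.unsorted(as.numeric(events$start), strictly = TRUE) ||
      is.unsorted(events$order, strictly = TRUE)) {
    stop_input("events must be strictly ordered in time and piling order")
  }
  gap_h <- c(NA_real_,
             as.numeric(difftime(events$start[-1],
                                 events$end[-nrow(events)], units = "hours")))
  keep <- !is.na(gap_h) & gap_h > min_gap_h
  keep[1] <- if (is.null(coverage_start)) TRUE else {
    as.numeric(difftime(events$start[1], utc(coverage_start),
                        units = "hours")) >= min_gap_h
  }
  out <- events
  out$gap_h <- gap_h
  out[keep, , drop = FALSE]
}

#' Baseline and response windows for one piling event
#'
#' Builds the diel-matched window pair around a piling event. The response
#' window always starts at the end of piling. For the 24-h duration the
#' baseline starts 48 h before the *start* of piling (avoiding pre-piling
#' vessel activity; both windows span a full diel cycle). For the 12-h
#' duration the baseline starts 48 h before the *end* of piling, so
#' baseline and response share the same clock start time (48 = 2 x 24 h).
#'
#' @param event one-row data frame (or list) with POSIXct `start` and `end`.
#' @param duration_h window length in hours, 12 or 24.
#' @return a list with `duration_h`, `baseline_start`, `baseline_end`,
#'   `response_start`, `response_end` (all POSIXct, UTC).
#' @export
build_windows <- function(event, duration_h) {
  if (!duration_h %in% c(12, 24)) stop_input("duration_h must be 12 or 24")
  start <- utc(event$start); end <- utc(event$end)
  baseline_start <- if (duration_h == 24) start - hours(48) else end - hours(48)
  response_start <- end
  list(
    duration_h = duration_h,
    baseline_start = baseline_start,
    baseline_end = baseline_start + hours(duration_h),
    response_start = response_start,
    response_end = response_start + hours(duration_h)
  )
}

#' Proportional change in occurrence
#'
#' `(response - baseline) / baseline`; undefined (NA) when the baseline has
#' zero detection-positive hours, in which case the record must be excluded
#' from analysis.
#'
#' @param baseline_dph,response_dph detection-positive hours in the
#'   baseline and response windows (vectorized).
#' @return proportional change, `>= -1`; `NA` where `baseline_dph == 0`.
#' @export
proportional_change <- function(baseline_dph, response_dph) {
  ifelse(baseline_dph > 0, (response_dph - baseline_dph) / baseline_dph,
         NA_real_)
}

#' Binarize a proportional change into a behavioural response
#'
#' A response is scored when the proportional *decrease* in occurrence is
#' strictly greater than `threshold`, i.e. `prop_change < -threshold`. A
#' decrease exactly equal to the threshold is a non-response. The same
#' threshold is applied to 12-h and 24-h records.
#'
#' @param prop_change proportional change (vectorized, finite).
#' @param threshold response threshold on the proportional decrease
#'   (default 0.5, the operative 1st-percentile-based cut-off).
#' @return integer 0/1.
#' @export
classify_response <- function(prop_change, threshold = 0.5) {
  if (any(!is.finite(prop_change))) stop_input("prop_change must be finite")
  as.integer(prop_change < -threshold)
}

#' Resampled null distribution of proportional change
#'
#' Characterizes undisturbed day-to-day variability in occurrence by
#' repeatedly sampling a monitoring device and a random whole-hour start
#' time `t` inside reference periods, and computing the proportional change
#' between the 24-h window starting at `t` and the 24-h baseline two days
#' earlier (`[t - 48h, t - 24h)`). Draws with a zero baseline are redrawn.
#' Draws are pooled over devices and periods into a single distribution
#' whose 1% quantile provides an evidence-based response threshold.
#'
#' @param series hourly detection series ([compute_dph()]) for the
#'   reference (non-impact) devices.
#' @param sample_periods data frame with POSIXct columns `start`, `end`:
#'   the periods from which start times are drawn.
#' @param n_draws number of resampling draws (default 1000).
#' @param seed optional integer seed for reproducible draws.
#' @param per_site if `TRUE`, draw `n_draws` times for every device instead
#'   of `n_draws` pooled draws.
#' @param threshold the operative response threshold stored alongside the
#'   computed quantile (default 0.5).
#' @return an object of class `null_distribution`: list with `samples`,
#'   `n_draws`, `quantile_1pct`, `threshold`, `n_redrawn`.
#' @export
build_null_distribution <- function(series, sample_periods, n_draws = 1000,
                                    seed = NULL, per_site = FALSE,
                                    threshold = 0.5) {
  devs <- dplyr::distinct(series[, c("site_id", "device_id")])
  tab <- null_change_table(series, sample_periods)
  if (nrow(tab) == 0) {
    stop_input("sample periods too short to host any valid draw")
  }
  dev_keys <- paste(devs$site_id, devs$device_id, sep = "\r")
  by_dev <- split(seq_len(nrow(tab)), factor(tab$key, levels = dev_keys))
  with_seed(seed, {
    n_total <- if (per_site) n_draws * nrow(devs) else n_draws
    samples <- numeric(0)
    n_redrawn <- 0L
    dev_seq <- if (per_site) rep(seq_along(dev_keys), each = n_draws)
               else integer(0)
    while (length(samples) < n_total) {
      need <- n_total - length(samples)
      ks <- if (per_site) dev_seq[seq_len(need)]
            else sample.int(length(dev_keys), need, replace = TRUE)
      idx <- vapply(ks, function(k) {
        cand <- by_dev[[k]]
        if (length(cand) == 0) NA_integer_
        else cand[sample.int(length(cand), 1)]
      }, integer(1))
      pc <- tab$prop_change[idx]
      ok <- !is.na(pc)
      n_redrawn <- n_redrawn + sum(!ok)
      if (n_redrawn > 100 * n_total + 100) {
        stop_input("too many zero-baseline redraws")
      }
      samples <- c(samples, pc[ok])
      if (per_site) dev_seq <- c(dev_seq[seq_len(need)][!ok],
                                 dev_seq[-seq_len(need)])
    }
    structure(
      list(samples = samples, n_draws = n_total,
           quantile_1pct = quantile7(samples, 0.01),
           threshold = threshold, n_redrawn = n_redrawn),
      class = "null_distribution")
  })
}

# all (device, whole-hour start) pairs valid for a null draw, with their
# baseline/response DPH and proportional change (NA when baseline is 0)
null_change_table <- function(series, sample_periods) {
  key <- paste(series$site_id, series$device_id, sep = "\r")
  parts <- lapply(split(seq_len(nrow(series)), key), function(ii) {
    hrs <- as.numeric(series$hour_start[ii])
    o <- order(hrs); hrs <- hrs[o]
    det <- series$detected[ii][o]
    lo <- min(hrs); hi <- max(hrs) + 3600
    if (length(hrs) != (hi - lo) / 3600) {
      stop_input("detection series must be a contiguous hourly grid")
    }
    cand <- unlist(lapply(seq_len(nrow(sample_periods)), function(j) {
      seq(as.numeric(utc(sample_periods$start[j])),
          as.numeric(utc(sample_periods$end[j])) - 3600, by = 3600)
    }))
    cand <- cand[cand - 48 * 3600 >= lo & cand + 24 * 3600 <= hi]
    if (length(cand) == 0) return(NULL)
    cs <- c(0, cumsum(det))
    pos <- function(t) (t - lo) / 3600  # contiguous hourly grid index
    wsum <- function(t0, t1) cs[pos(t1) + 1] - cs[pos(t0) + 1]
    base <- vapply(cand, function(t) wsum(t - 48 * 3600, t - 24 * 3600),
                   numeric(1))
    resp <- vapply(cand, function(t) wsum(t, t + 24 * 3600), numeric(1))
    tibble::tibble(key = key[ii[1]], start = cand, baseline_dph = base,
                   response_dph = resp,
                   prop_change = proportional_change(base, resp))
  })
  dplyr::bind_rows(parts)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Resampled null distribution of proportional change\n")
  cat(sprintf("  draws: %d (redrawn on zero baseline: %d)\n",
              x$n_draws, x$n_redrawn))
  cat(sprintf("  1%% quantile: %.3f   operative threshold: -%.2f\n",
              x$quantile_1pct, x$threshold))
  invisible(x)
}

#' Vessel-proximity covariate from AIS position reports
#'
#' Counts AIS position reports (or unique vessels) within a radius of a
#' monitoring site during a time window. Reports exactly at the radius are
#' included.
#'
#' @param ais data frame with `timestamp` (POSIXct), `x_km`, `y_km`,
#'   `vessel_id`; may be empty or `NULL`.
#' @param site_x,site_y site position, planar km.
#' @param radius_m counting radius in metres (500 or 1000 in the standard
#'   analysis).
#' @param window_start,window_end POSIXct bounds of the (half-open) window.
#' @param unique_vessels count distinct vessels instead of position reports.
#' @return integer count.
#' @export
vessel_covariate <- function(ais, site_x, site_y, radius_m,
                             window_start, window_end,
                             unique_vessels = FALSE) {
  if (radius_m <= 0) stop_input("radius_m must be positive")
  if (is.null(ais) || nrow(ais) == 0) return(0L)
  inside <- ais$timestamp >= utc(window_start) & ais$timestamp < utc(window_end)
  a <- ais[inside, , drop = FALSE]
  if (nrow(a) == 0) return(0L)
  d_km <- sqrt((a$x_km - site_x)^2 + (a$y_km - site_y)^2)
  hit <- d_km <= radius_m / 1000
  if (unique_vessels) length(unique(a$vessel_id[hit])) else as.integer(sum(hit))
}

#' Assemble the response-record table for modelling
#'
#' Builds one row per monitoring device x eligible piling event x window
#' duration, with the binary response, exposure covariates and vessel
#' counts the probit mixed models use. Records with missing window coverage
#' or a zero baseline are skipped and logged in the `exclusions` attribute.
#'
#' @param series hourly detection series ([compute_dph()]).
#' @param events piling events table ([generate_schedule()]); filtered
#'   through [eligible_events()] internally.
#' @param sels per site x event exposure table from [compute_event_sels()].
#' @param sites data frame `site_id`, `x_km`, `y_km` (needed for vessel
#'   counts; may be omitted when `ais` is `NULL`).
#' @param ais AIS position reports, or `NULL` for zero vessel covariates.
#' @param duration_h 12 or 24.
#' @param threshold response threshold (default 0.5).
#' @param min_gap_h eligibility gap in hours (default 96).
#' @param coverage_start optional POSIXct monitoring start, passed to
#'   [eligible_events()].
#' @param exclude_within_km drop devices whose site lies within this
#'   distance (km) of any piling location (0 disables; 1 km is the standard
#'   robustness variant).
#' @return a tibble of response records with attribute `exclusions`.
#' @export
assemble_records <- function(series, events, sels, sites = NULL, ais = NULL,
                             duration_h = 24, threshold = 0.5,
                             min_gap_h = 96, coverage_start = NULL,
                             exclude_within_km = 0) {
  elig <- eligible_events(events, min_gap_h = min_gap_h,
                          coverage_start = coverage_start)
  devs <- dplyr::distinct(series[, c("site_id", "device_id")])
  excl <- list()

  if (exclude_within_km > 0) {
    min_d <- sels |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(min_km = min(.data$distance_km), .groups = "drop")
    near <- min_d$site_id[min_d$min_km < exclude_within_km]
    if (length(near)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        site_id = near, device_id = NA_character_, event_id = NA,
        reason = "within exclusion distance of piling")
      devs <- devs[!devs$site_id %in% near, , drop = FALSE]
    }
  }

  key <- paste(series$site_id, series$device_id, sep = "\r")
  det_by_dev <- split(series$detected, key)
  hour_by_dev <- split(as.numeric(series$hour_start), key)
  sel_idx <- setNames(seq_len(nrow(sels)),
                      paste(sels$site_id, sels$event_id, sep = "\r"))
  if (!is.null(ais) && is.null(sites)) {
    stop_input("sites table required when ais is supplied")
  }
  site_xy <- if (!is.null(sites)) {
    m <- as.matrix(sites[, c("x_km", "y_km")])
    rownames(m) <- sites$site_id
    m
  }

  rows <- list()
  for (i in seq_len(nrow(elig))) {
    ev <- elig[i, ]
    w <- build_windows(ev, duration_h)
    # vessel counts for all sites over this event's response window
    v500_per_site <- v1000_per_site <- NULL
    if (!is.null(ais)) {
      a <- ais[ais$timestamp >= w$response_start &
                 ais$timestamp < w$response_end, , drop = FALSE]
      if (nrow(a) > 0) {
        d2 <- outer(site_xy[, 1], a$x_km, "-")^2 +
          outer(site_xy[, 2], a$y_km, "-")^2
        v500_per_site <- setNames(as.integer(rowSums(d2 <= 0.5^2)),
                                  rownames(site_xy))
        v1000_per_site <- setNames(as.integer(rowSums(d2 <= 1)),
                                   rownames(site_xy))
      }
    }
    b0 <- as.numeric(w$baseline_start); b1 <- as.numeric(w$baseline_end)
    r0 <- as.numeric(w$response_start); r1 <- as.numeric(w$response_end)
    # hours fully inside the window; for hour-aligned events this is
    # exactly duration_h hours, otherwise duration_h - 1
    n_full <- function(w0, w1) floor((w1 - 3600 * ceiling(w0 / 3600)) / 3600)
    for (j in seq_len(nrow(devs))) {
      k <- paste(devs$site_id[j], devs$device_id[j], sep = "\r")
      hrs <- hour_by_dev[[k]]; det <- det_by_dev[[k]]
      ib <- hrs >= b0 & (hrs + 3600) <= b1
      ir <- hrs >= r0 & (hrs + 3600) <= r1
      if (sum(ib) != n_full(b0, b1) || sum(ir) != n_full(r0, r1)) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          site_id = devs$site_id[j], device_id = devs$device_id[j],
          event_id = ev$event_id, reason = "missing window coverage")
        next
      }
      base <- sum(det[ib]); resp <- sum(det[ir])
      if (base == 0) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          site_id = devs$site_id[j], device_id = devs$device_id[j],
          event_id = ev$event_id, reason = "zero baseline DPH")
        next
      }
      pc <- proportional_change(base, resp)
      si <- sel_idx[[paste(devs$site_id[j], ev$event_id, sep = "\r")]]
      if (is.null(si) || is.na(si)) {
        stop_input("exposure table must have one row per site x event")
      }
      s <- sels[si, ]
      v500 <- v500_per_site[[devs$site_id[j]]] %||% 0L
      v1000 <- v1000_per_site[[devs$site_id[j]]] %||% 0L
      rows[[length(rows) + 1L]] <- list(
        site_id = devs$site_id[j], device_id = devs$device_id[j],
        event_id = ev$event_id, duration_h = duration_h,
        baseline_dph = base, response_dph = resp, prop_change = pc,
        response = classify_response(pc, threshold),
        distance_km = s$distance_km, log_distance = log(s$distance_km),
        sel_unweighted = s$sel_unweighted, sel_m = s$sel_m,
        sel_noaa = s$sel_noaa, sel_audiogram = s$sel_audiogram,
        order = ev$order, add_used = as.integer(ev$add_used),
        vessels_500m = v500, vessels_1km = v1000)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl)
    else tibble::tibble(site_id = character(), device_id = character(),
                        event_id = integer(), reason = character())
  out
}
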