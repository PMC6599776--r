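#' Hourly detection-positive series from click-train records
#'
#' Collapses classified echolocation click-train records into an hourly
#' binary detection indicator per monitoring device. An hour scores 1 when
#' at least one train of high (`Hi`) or moderate (`Mod`) quality starts in
#' the half-open hour bin `[t, t + 1h)`; hours with only `Lo`/`Other`
#' trains, or none, score 0. Records outside the grid are dropped and
#' counted in the `n_ignored` attribute.
#'
#' @param records data frame with columns `site_id`, `device_id`,
#'   `timestamp` (POSIXct, UTC) and `quality` (one of `"Hi"`, `"Mod"`,
#'   `"Lo"`, `"Other"`).
#' @param grid_start,grid_end POSIXct bounds of the hourly grid; both must
#'   be aligned to clock hours (UTC). The grid covers hour starts
#'   `[grid_start, grid_end)`.
#' @param devices optional data frame of `site_id`, `device_id` pairs that
#'   must appear in the output even if they produced no records.
#' @return a tibble with columns `site_id`, `device_id`, `hour_start`,
#'   `detected` (0/1), one row per device-hour, with attribute `n_ignored`.
#' @export
compute_dph <- function(records, grid_start, grid_end, devices = NULL) {
  grid_start <- utc(grid_start); grid_end <- utc(grid_end)
  if (!is_hour_aligned(c(grid_start, grid_end))) {
    stop_input("grid bounds must be aligned to clock hours (UTC)")
  }
  if (grid_end <= grid_start) stop_input("empty hour grid")
  if (nrow(records) > 0 && any(!is.finite(as.numeric(records$timestamp)))) {
    stop_input("malformed timestamp in click-train records")
  }
  hrs <- seq(grid_start, grid_end - 3600, by = 3600)

  if (is.null(devices)) {
    devices <- dplyr::distinct(records[, c("site_id", "device_id")])
  }
  devices <- dplyr::distinct(tibble::as_tibble(devices[, c("site_id", "device_id")]))

  keep <- records$quality %in% c("Hi", "Mod")
  inside <- records$timestamp >= grid_start & records$timestamp < grid_end
  n_ignored <- sum(!inside)
  rec <- records[keep & inside, , drop = FALSE]

  hit <- dplyr::distinct(tibble::tibble(
    site_id = rec$site_id, device_id = rec$device_id,
    hour_start = floor_hour(rec$timestamp), detected = 1L
  ))
  out <- tidyr::crossing(devices, hour_start = hrs)
  out <- dplyr::left_join(out, hit, by = c("site_id", "device_id", "hour_start"))
  out$detected <- ifelse(is.na(out$detected), 0L, 1L)
  out <- dplyr::arrange(out, .data$site_id, .data$device_id, .data$hour_start)
  attr(out, "n_ignored") <- n_ignored
  out
}

#' Count detection-positive hours in a window
#'
#' Sums the hourly detection indicator of one device series over the
#' half-open window `[window_start, window_end)`. The window must be a
#' whole number of hours and fully covered by the series.
#'
#' @param series hourly series for a single device (columns `hour_start`,
#'   `detected`), as produced by [compute_dph()].
#' @param window_start,window_end POSIXct window bounds (hour-aligned).
#' @return integer count of detection-positive hours.
#' @export
window_dph <- function(series, window_start, window_end) {
  window_start <- utc(window_start); window_end <- utc(window_end)
  if (!is_hour_aligned(c(window_start, window_end)) || window_end <= window_start) {
    stop_input("window must be a positive whole number of hours")
  }
  idx <- series$hour_start >= window_start & series$hour_start < window_end
  n_expected <- as.numeric(difftime(window_end, window_start, units = "hours"))
  if (sum(idx) != n_expected) {
    stop_input(sprintf(
      "window [%s, %s) not fully covered by series (%d of %d hours present)",
      format(window_start), format(window_end), sum(idx), n_expected))
  }
  as.integer(sum(series$detected[idx]))
}

#' Daily occurrence summary across devices
#'
#' Summarizes daily detection-positive hours (DPH per UTC calendar day)
#' across devices: per-day median and interquartile range. Quantiles use
#' linear interpolation between order statistics with plotting position
#' (k-1)/(n-1).
#'
#' @param series hourly detection series from [compute_dph()].
#' @return a tibble with columns `day`, `n_devices`, `median_dph`,
#'   `iqr_dph`, `q25`, `q75`.
#' @export
daily_occurrence_summary <- function(series) {
  if (nrow(series) == 0) stop_input("empty detection series")
  daily <- series |>
    dplyr::mutate(day = as.Date(.data$hour_start, tz = "UTC")) |>
    dplyr::group_by(.data$site_id, .data$device_id, .data$day) |>
    dplyr::summarise(dph = sum(.data$detected), .groups = "drop")
  daily |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n_devices = dplyr::n(),
      median_dph = quantile7(.data$dph, 0.5),
      q25 = quantile7(.data$dph, 0.25),
      q75 = quantile7(.data$dph, 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr_dph = .data$q75 - .data$q25) |>
    dplyr::select("day", "n_devices", "median_dph", "iqr_dph", "q25", "q75")
}
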