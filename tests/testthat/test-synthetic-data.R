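test_that("configuration invariants are enforced", {
  expect_error(truth_config(ed50_first_km = 1, ed50_last_km = 2), "ed50")
  expect_error(truth_config(baseline_dph_rate = 30), "baseline_dph_rate")
  expect_error(truth_config(site_sd_probit = -1), "site_sd")
  expect_error(truth_config(diel_amplitude = 1.2), "amplitudes")
  expect_error(truth_config(piling_duration_mean_h = 0), "positive")
  expect_error(truth_config(n_events = 0), "n_events")
})

test_that("schedules are ordered, gapped, ADD-flagged and reproducible", {
  cfg <- truth_config(n_events = 3, event_interval_h = 120, seed = 42)
  ev <- generate_schedule(cfg)
  expect_equal(nrow(ev), 3)
  expect_true(all(diff(as.numeric(ev$start)) > 0))
  gaps <- as.numeric(difftime(ev$start[-1], ev$end[-3], units = "hours"))
  expect_true(all(gaps >= 96))
  expect_true(all(ev$end > ev$start))
  # identical seed, identical table
  expect_identical(ev, generate_schedule(cfg))
  # different seed, different times
  expect_false(identical(ev$start,
                         generate_schedule(truth_config(n_events = 3,
                                                        seed = 43))$start))
  # exactly one event piled without ADD at the default configuration
  full <- generate_schedule(truth_config(seed = 1))
  expect_equal(sum(!full$add_used), 1L)
  # single event: order index is the first configured index
  one <- generate_schedule(truth_config(n_events = 1, order_indices = 1,
                                        seed = 2))
  expect_equal(nrow(one), 1)
  expect_equal(one$order, 1)
})

test_that("simulated piling durations average to the configured mean", {
  cfg <- truth_config(n_events = 1000, event_interval_h = 24,
                      order_indices = 1:1000, no_add_event = NA,
                      piling_duration_mean_h = 5.0, seed = 10)
  ev <- generate_schedule(cfg)
  dur <- as.numeric(difftime(ev$end, ev$start, units = "hours"))
  expect_lt(abs(mean(dur) - 5.0), 0.25)
})

test_that("truth curve hits 0.5 exactly at both ED50 anchors", {
  cfg <- truth_config(seed = 1)
  expect_equal(truth_response_prob(cfg, cfg$ed50_first_km, 1), 0.5,
               tolerance = 1e-12)
  expect_equal(truth_response_prob(cfg, cfg$ed50_last_km, 86), 0.5,
               tolerance = 1e-12)
  # monotone decreasing in distance, response attenuates with order
  d <- c(0.5, 1, 2, 5, 10, 20)
  expect_true(all(diff(truth_response_prob(cfg, d, 1)) < 0))
  expect_gt(truth_response_prob(cfg, 5, 1), truth_response_prob(cfg, 5, 86))
  # no ADD lowers the response; vessels raise it
  expect_lt(truth_response_prob(cfg, 5, 1, add_used = 0),
            truth_response_prob(cfg, 5, 1, add_used = 1))
  expect_gt(truth_response_prob(cfg, 5, 1, vessels = 200),
            truth_response_prob(cfg, 5, 1, vessels = 0))
})

test_that("homogeneous no-event detections match the configured rate", {
  cfg <- truth_config(n_sites = 10, baseline_dph_rate = 11,
                      diel_amplitude = 0, seasonal_amplitude = 0,
                      site_sd_probit = 0, lo_quality_rate = 0, seed = 3,
                      site_positions = tibble::tibble(
                        site_id = sprintf("S%02d", 1:10),
                        x_km = 1:10, y_km = 0))
  t0 <- as.POSIXct("2017-03-01", tz = "UTC")
  rec <- generate_detections(cfg, events = NULL, t0, t0 + 20 * 86400)
  dph <- compute_dph(rec, t0, t0 + 20 * 86400,
                     devices = attr(rec, "sites") |>
                       dplyr::transmute(site_id,
                                        device_id = paste0("POD-", site_id)))
  daily <- dph |>
    dplyr::mutate(day = as.Date(hour_start)) |>
    dplyr::group_by(site_id, day) |>
    dplyr::summarise(dph = sum(detected), .groups = "drop")
  expect_lt(abs(mean(daily$dph) - 11), 0.7)
})

test_that("suppression halves occurrence at the first-event ED50 distance", {
  # 600 replicate sites at exactly the ED50 range; expected proportional
  # reduction over the 24-h response window is p_true = 0.5
  n <- 600
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  cfg <- truth_config(
    n_sites = n, n_events = 1, order_indices = 1, no_add_event = NA,
    diel_amplitude = 0, seasonal_amplitude = 0, site_sd_probit = 0,
    lo_quality_rate = 0, n_ambient_vessels = 0, seed = 17,
    site_positions = tibble::tibble(site_id = sprintf("S%03d", 1:n),
                                    x_km = 7.4 * cos(th),
                                    y_km = 7.4 * sin(th)))
  ev <- generate_schedule(cfg)
  ev$x_km <- 0; ev$y_km <- 0
  t0 <- ev$start[1] - 96 * 3600
  t1 <- ev$end[1] + 48 * 3600
  rec <- generate_detections(cfg, ev, t0, t1)
  truth <- attr(rec, "truth")
  expect_equal(truth$p_true, rep(0.5, n), tolerance = 1e-12)
  dph <- compute_dph(rec, t0, t1)
  resp <- dph[dph$hour_start >= ev$end[1] &
                dph$hour_start < ev$end[1] + 24 * 3600, ]
  base <- dph[dph$hour_start >= ev$start[1] - 48 * 3600 &
                dph$hour_start < ev$start[1] - 24 * 3600, ]
  reduction <- 1 - mean(resp$detected) / mean(base$detected)
  expect_lt(abs(reduction - 0.5), 0.08)
  # and the realized displacement draws average near p_true
  expect_lt(abs(mean(truth$responded) - 0.5), 0.08)
})

test_that("suppression is negligible far beyond the response range", {
  n <- 400
  cfg <- truth_config(
    n_sites = n, n_events = 1, order_indices = 1, no_add_event = NA,
    diel_amplitude = 0, seasonal_amplitude = 0, site_sd_probit = 0,
    lo_quality_rate = 0, n_ambient_vessels = 0, seed = 23,
    site_positions = tibble::tibble(site_id = sprintf("S%03d", 1:n),
                                    x_km = 740, y_km = seq_len(n) * 1e-3))
  ev <- generate_schedule(cfg); ev$x_km <- 0; ev$y_km <- 0
  t0 <- ev$start[1] - 96 * 3600
  rec <- generate_detections(cfg, ev, t0, ev$end[1] + 48 * 3600)
  truth <- attr(rec, "truth")
  expect_true(all(truth$p_true < 0.01))
  dph <- compute_dph(rec, t0, ev$end[1] + 48 * 3600)
  resp <- dph[dph$hour_start >= ev$end[1] &
                dph$hour_start < ev$end[1] + 24 * 3600, ]
  base <- dph[dph$hour_start < ev$start[1], ]
  # two-proportion test: response-window rate indistinguishable from baseline
  pt <- prop.test(c(sum(resp$detected), sum(base$detected)),
                  c(nrow(resp), nrow(base)))
  expect_gt(pt$p.value, 0.01)
})

test_that("with suppression disabled the change distribution centres at 0", {
  # 200 replicate site-window pairs with no piling: proportional change
  # should have median 0 (two-sided sign test at alpha = 0.01)
  cfg <- truth_config(n_sites = 50, site_sd_probit = 0.3,
                      lo_quality_rate = 0, seed = 31,
                      site_positions = tibble::tibble(
                        site_id = sprintf("S%02d", 1:50),
                        x_km = seq(1, 50), y_km = 0))
  t0 <- as.POSIXct("2017-03-01", tz = "UTC")
  rec <- generate_detections(cfg, events = NULL, t0, t0 + 25 * 86400)
  dph <- compute_dph(rec, t0, t0 + 25 * 86400)
  pcs <- unlist(lapply(0:3, function(k) {
    t <- t0 + (5 + 5 * k) * 86400
    base <- dph[dph$hour_start >= t - 48 * 3600 &
                  dph$hour_start < t - 24 * 3600, ]
    resp <- dph[dph$hour_start >= t & dph$hour_start < t + 24 * 3600, ]
    b <- tapply(base$detected, base$site_id, sum)
    r <- tapply(resp$detected, resp$site_id, sum)
    proportional_change(b, r)
  }))
  pcs <- pcs[!is.na(pcs) & pcs != 0]
  st <- binom.test(sum(pcs > 0), length(pcs), 0.5)
  expect_gt(st$p.value, 0.01)
})

test_that("AIS reports run at a 5-minute cadence and reproduce by seed", {
  cfg <- truth_config(n_events = 2, n_ambient_vessels = 2, seed = 12)
  ev <- generate_schedule(cfg)
  t0 <- ev$start[1] - 86400
  t1 <- ev$end[2] + 86400
  ais <- generate_ais(cfg, ev, t0, t1)
  expect_true(all(as.numeric(ais$timestamp) %% 300 == 0))
  expect_identical(ais, generate_ais(cfg, ev, t0, t1))
  # construction vessels sit on station through each piling event
  for (i in 1:2) {
    con <- ais[ais$vessel_id == sprintf("CON%02d", i) &
                 ais$timestamp >= ev$start[i] & ais$timestamp <= ev$end[i], ]
    d <- sqrt((con$x_km - ev$x_km[i])^2 + (con$y_km - ev$y_km[i])^2)
    expect_true(all(d < 0.5))
    expect_gte(nrow(con), 12)
  }
  # no vessels configured and no events: empty report set
  cfg0 <- truth_config(n_events = 1, n_ambient_vessels = 0, seed = 1)
  ais0 <- generate_ais(cfg0, generate_schedule(cfg0)[0, ], t0, t1)
  expect_equal(nrow(ais0), 0)
})

test_that("identical seeds give bitwise-identical simulations", {
  cfg <- truth_config(n_sites = 6, n_events = 2, seed = 77,
                      site_positions = tibble::tibble(
                        site_id = paste0("S", 1:6), x_km = 1:6 * 3,
                        y_km = 0))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$ais, s2$ais)
  expect_identical(s1$sels, s2$sels)
})

test_that("simulation bundles round-trip through CSV", {
  cfg <- truth_config(n_sites = 4, n_events = 2, seed = 9,
                      site_positions = tibble::tibble(
                        site_id = paste0("S", 1:4), x_km = c(2, 5, 9, 14),
                        y_km = 0))
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("detections.csv", "events.csv", "ais.csv", "sites.csv",
      "truth.yaml")))))
  back <- read_detections_csv(file.path(dir, "detections.csv"))
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(as.numeric(back$timestamp),
               as.numeric(sim$records$timestamp), tolerance = 1)
  y <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(y$ed50_first_km, cfg$ed50_first_km)
  expect_equal(y$seed, cfg$seed)
})
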