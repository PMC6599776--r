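utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("eligibility keeps events with a quiet gap above the minimum", {
  ev <- tibble::tibble(
    event_id = 1:3, order = c(1, 5, 9),
    start = utc(c("2017-04-01 00:00", "2017-04-06 09:00",
                  "2017-04-08 16:00")),
    end = utc(c("2017-04-01 05:00", "2017-04-06 14:00",
                "2017-04-08 21:00")))
  # gap into event 2 is 100 h (keep), into event 3 is 50 h (drop)
  keep <- eligible_events(ev, 96)
  expect_equal(keep$event_id, c(1L, 2L))
  # stricter 192-h rule: always a subset of the 96-h rule
  expect_equal(eligible_events(ev, 192)$event_id, 1L)
  # first event retained only with >= min_gap_h prior coverage
  expect_equal(eligible_events(ev, 96,
                               coverage_start = "2017-03-27 00:00")$event_id,
               c(1L, 2L))
  expect_equal(eligible_events(ev, 96,
                               coverage_start = "2017-03-31 00:00")$event_id,
               2L)
  # single event with ample prior coverage is retained
  expect_equal(nrow(eligible_events(ev[1, ], 96,
                                    coverage_start = "2017-03-01")), 1)
  expect_error(eligible_events(ev[c(2, 1, 3), ], 96), "ordered")
})

test_that("the 192-h subset is nested in the 96-h subset", {
  withr::with_seed(21, {
    for (i in 1:20) {
      cfg <- truth_config(n_events = 8, event_interval_h = 150, seed = i)
      ev <- generate_schedule(cfg)
      e96 <- eligible_events(ev, 96)$event_id
      e192 <- eligible_events(ev, 192)$event_id
      expect_true(all(e192 %in% e96))
    }
  })
})

test_that("baseline-response windows follow the diel-matched layout", {
  ev <- list(start = utc("2017-06-01 06:00"), end = utc("2017-06-01 11:00"))
  w24 <- build_windows(ev, 24)
  expect_equal(w24$baseline_start, utc("2017-05-30 06:00"))
  expect_equal(w24$baseline_end, utc("2017-05-31 06:00"))
  expect_equal(w24$response_start, utc("2017-06-01 11:00"))
  expect_equal(w24$response_end, utc("2017-06-02 11:00"))
  w12 <- build_windows(ev, 12)
  expect_equal(w12$baseline_start, utc("2017-05-30 11:00"))
  expect_equal(w12$baseline_end, utc("2017-05-30 23:00"))
  expect_equal(w12$response_start, utc("2017-06-01 11:00"))
  expect_error(build_windows(ev, 6), "12 or 24")
})

test_that("window layout invariants hold for random event times", {
  withr::with_seed(33, {
    starts <- utc("2017-02-17 00:00") + runif(1000, 0, 250 * 86400)
    durations <- runif(1000, 2.9, 8.8) * 3600
    for (i in seq_len(1000)) {
      ev <- list(start = starts[i], end = starts[i] + durations[i])
      w24 <- build_windows(ev, 24)
      w12 <- build_windows(ev, 12)
      # 24-h baseline starts exactly 48 h before piling start
      expect_identical(as.numeric(ev$start) - as.numeric(w24$baseline_start),
                       48 * 3600)
      # 12-h baseline starts exactly 48 h before piling end
      expect_identical(as.numeric(ev$end) - as.numeric(w12$baseline_start),
                       48 * 3600)
      # 12-h baseline and response share clock start time (48 = 0 mod 24)
      expect_identical(as.numeric(w12$baseline_start) %% 86400,
                       as.numeric(w12$response_start) %% 86400)
      # windows have the requested length and never overlap
      expect_identical(as.numeric(w24$baseline_end) -
                         as.numeric(w24$baseline_start), 24 * 3600)
      expect_lt(as.numeric(w24$baseline_end), as.numeric(w24$response_start))
      expect_lt(as.numeric(w12$baseline_end), as.numeric(w12$response_start))
    }
  })
})

test_that("proportional change and the strict response rule", {
  expect_equal(proportional_change(10, 4), -0.6)
  expect_equal(proportional_change(12, 12), 0)
  expect_true(is.na(proportional_change(0, 3)))
  expect_equal(classify_response(c(-0.6, -0.5, 0.3)), c(1L, 0L, 0L))
  expect_true(all(proportional_change(c(1, 5, 24), c(0, 0, 0)) >= -1))
  # monotone non-increasing in prop_change
  pc <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(classify_response(pc)) <= 0))
})

test_that("vessel covariate counts position reports within the radius", {
  t0 <- utc("2017-05-01 00:00")
  expect_equal(vessel_covariate(NULL, 0, 0, 500, t0, t0 + 3600), 0L)
  # stationary vessel 300 m away reporting at 5-min cadence for 1 h
  ais <- tibble::tibble(timestamp = t0 + seq(0, 3595, by = 300),
                        x_km = 0.3, y_km = 0, vessel_id = "v1")
  expect_equal(vessel_covariate(ais, 0, 0, 500, t0, t0 + 3600), 12L)
  expect_equal(vessel_covariate(ais, 0, 0, 500, t0, t0 + 3600,
                                unique_vessels = TRUE), 1L)
  # 800 m away: counted at 1 km, not at 500 m
  ais$x_km <- 0.8
  expect_equal(vessel_covariate(ais, 0, 0, 500, t0, t0 + 3600), 0L)
  expect_equal(vessel_covariate(ais, 0, 0, 1000, t0, t0 + 3600), 12L)
  # distance exactly at the radius is included
  ais$x_km <- 0.5
  expect_equal(vessel_covariate(ais, 0, 0, 500, t0, t0 + 3600), 12L)
})

test_that("null distribution: degenerate and seeded behaviour", {
  hrs <- rep(1, 14 * 24)
  s <- hourly_series(hrs, start = "2017-03-01")
  periods <- tibble::tibble(start = utc("2017-03-03"),
                            end = utc("2017-03-14"))
  nd <- build_null_distribution(s, periods, n_draws = 300, seed = 4)
  expect_true(all(nd$samples == 0))
  expect_equal(nd$quantile_1pct, 0)
  nd2 <- build_null_distribution(s, periods, n_draws = 300, seed = 4)
  expect_identical(nd$samples, nd2$samples)
  expect_error(build_null_distribution(s[1:24, ], periods, 10),
               "too short")
})

test_that("sampled null quantile converges to the enumeration oracle", {
  withr::with_seed(8, {
    series <- dplyr::bind_rows(lapply(paste0("s", 1:4), function(id)
      hourly_series(rbinom(16 * 24, 1, 0.3), start = "2017-03-01",
                    site = id, device = id)))
  })
  periods <- tibble::tibble(start = utc("2017-03-03"),
                            end = utc("2017-03-15"))
  tab <- piledose:::null_change_table(series, periods)
  exact <- unname(quantile(tab$prop_change[!is.na(tab$prop_change)], 0.01,
                           type = 7))
  for (nd_draws in c(2000, 20000)) {
    nd <- build_null_distribution(series, periods, n_draws = nd_draws,
                                  seed = 99)
    expect_lt(abs(nd$quantile_1pct - exact), 0.05)
  }
})

test_that("response records assemble with exclusions logged", {
  withr::with_seed(2, {
    cfg <- truth_config(n_sites = 8, n_events = 3, seed = 5,
                        site_positions = tibble::tibble(
                          site_id = sprintf("S%d", 1:8),
                          x_km = c(0.4, 2, 4, 7, 10, 15, 22, 30),
                          y_km = 0))
    sim <- simulate_study(cfg)
    # pin the first piling event next to the nearest site so the 1-km
    # exclusion filter has a target
    sim$events$x_km[1] <- 0.4; sim$events$y_km[1] <- 0.2
    sim$sels <- compute_event_sels(sim$sites, sim$events)
    dph <- compute_dph(sim$records, sim$t_start, sim$t_end)
    rec <- assemble_records(dph, sim$events, sim$sels, sites = sim$sites,
                            ais = sim$ais, duration_h = 24,
                            coverage_start = sim$t_start)
    excl <- attr(rec, "exclusions")
    expect_equal(nrow(rec) + sum(excl$reason != "within exclusion distance of piling"),
                 8 * 3)
    expect_true(all(rec$response %in% 0:1))
    expect_true(all(rec$prop_change >= -1))
    expect_true(all(is.finite(rec$log_distance)))
    # 1-km exclusion drops the 0.4-km site entirely
    rec1 <- assemble_records(dph, sim$events, sim$sels, sites = sim$sites,
                             ais = sim$ais, duration_h = 24,
                             coverage_start = sim$t_start,
                             exclude_within_km = 1)
    expect_false("S1" %in% rec1$site_id)
    expect_true("S1" %in% attr(rec1, "exclusions")$site_id)
    # 12-h records carry the same covariate columns
    rec12 <- assemble_records(dph, sim$events, sim$sels, sites = sim$sites,
                              ais = sim$ais, duration_h = 12,
                              coverage_start = sim$t_start)
    expect_setequal(names(rec12), names(rec))
    expect_true(all(rec12$duration_h == 12))
  })
})
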