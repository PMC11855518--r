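test_that("city generation is deterministic and respects its defaults", {
  c1 <- generate_city(city_config(seed = 1))
  c2 <- generate_city(city_config(seed = 1))
  expect_identical(c1, c2)
  expect_equal(nrow(c1$candidates), 624)
  expect_gte(nrow(c1$bases), 1)
  b <- c1$bbox
  expect_true(all(c1$candidates$x >= b[1] & c1$candidates$x <= b[3]))
  expect_true(all(c1$candidates$y >= b[2] & c1$candidates$y <= b[4]))
  expect_false(any(duplicated(c1$candidates$site_id)))
  c3 <- generate_city(city_config(seed = 2))
  expect_false(identical(c1$candidates, c3$candidates))
})

test_that("degenerate single-centre mixture draws all locations from it", {
  city <- tiny_city()
  ev <- simulate_events(city, 300, seed = 5)
  # one bivariate normal with sd 700 centred at (2000, 2000)
  expect_lt(abs(mean(ev$x_m) - 2000), 150)
  expect_lt(abs(mean(ev$y_m) - 2000), 150)
  expect_lt(abs(sd(ev$x_m) - 700), 150)
})

test_that("invalid configurations are rejected", {
  expect_error(city_config(ambulance_speed = 0), "speeds")
  expect_error(city_config(population_centres = data.frame()), "centre")
  expect_error(city_config(population_centres = data.frame(
    x = 1, y = 1, spread = 100, weight = 0.5)), "sum to 1")
  city <- tiny_city()
  expect_error(simulate_events(city, 0), "n_calls")
})

test_that("event simulation is deterministic under a fixed seed", {
  city <- tiny_city()
  e1 <- simulate_events(city, 100, seed = 9)
  e2 <- simulate_events(city, 100, seed = 9)
  expect_identical(e1, e2)
  e3 <- simulate_events(city, 100, seed = 10)
  expect_false(identical(e1$response_time_s, e3$response_time_s))
})

test_that("response time reduces to dispatch delay at zero travel", {
  city <- generate_city(city_config(
    bbox = c(0, 0, 4000, 4000),
    population_centres = data.frame(x = 2000, y = 2000, spread = 1e-9,
                                    weight = 1),
    bases = cbind(2000, 2000),
    travel_log_sd = 0,
    congestion_harmonics = data.frame(amplitude = 0, phase_h = 0),
    n_candidates = 5L, seed = 3
  ))
  ev <- simulate_events(city, 50, seed = 3)
  expect_equal(ev$response_time_s, ev$dispatch_time_s, tolerance = 1e-6)
})

test_that("event records satisfy their structural invariants", {
  city <- tiny_city()
  ev <- simulate_events(city, 200, seed = 4)
  expect_true(all(ev$response_time_s > 0))
  expect_true(all(ev$dispatch_time_s >= 0))
  expect_true(all(ev$dispatch_time_s <= ev$response_time_s))
  expect_true(all(ev$call_hour >= 0 & ev$call_hour < 24))
  # call_hour is the fractional hour of call_datetime (to recording precision)
  dt <- as.POSIXct(ev$call_datetime, format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  h <- as.numeric(format(dt, "%H")) + as.numeric(format(dt, "%M")) / 60 +
    as.numeric(format(dt, "%S")) / 3600
  expect_equal(h, ev$call_hour, tolerance = 2e-4)
})

test_that("diurnal intensity defaults peak in morning/afternoon with a midnight trough", {
  h <- 0:23
  lam <- diurnal_intensity(h, default_intensity_harmonics(), base_rate = 1)
  expect_true(all(lam > 0))
  expect_equal(h[which.min(lam)], 0)
  # afternoon peak near 16:00, and a genuine morning local maximum near 06:00
  expect_lte(abs(h[which.max(lam)] - 16), 1.5)
  morning <- 3:9
  lm <- morning[which.max(lam[morning + 1])]
  expect_lte(abs(lm - 6), 1.5)
  expect_gt(lam[lm + 1], lam[3 + 1])   # rises out of the night
  expect_gt(lam[lm + 1], lam[9 + 1])   # falls toward mid-morning
})

test_that("congestion multiplier peaks near 11:00", {
  h <- seq(0, 23.75, by = 0.25)
  m <- congestion_multiplier(h, default_congestion_harmonics())
  expect_true(all(m > 0))
  expect_lte(abs(h[which.max(m)] - 11), 0.5)
})

test_that("simulated call hours follow the diurnal intensity", {
  city <- tiny_city()
  ev <- simulate_events(city, 3000, seed = 11)
  tab <- tabulate(floor(ev$call_hour) + 1, 24)
  # midnight trough vs afternoon peak
  expect_lt(tab[1], tab[17])
  expect_lt(tab[1], tab[7])
})

test_that("generator calibration: cohort medians track the registry", {
  meds <- numeric(20)
  pg <- numeric(20)
  for (s in 1:20) {
    city <- generate_city(city_config(seed = s))
    coh <- filter_ohca(simulate_events(city, 476, seed = s))
    meds[s] <- median(coh$response_time_s)
    pg[s] <- mean(coh$response_time_s > 600)
  }
  expect_gte(median(meds), 650)
  expect_lte(median(meds), 750)
  expect_lt(abs(mean(pg) - 0.62), 0.05)
})
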