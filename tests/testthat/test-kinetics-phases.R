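test_that("windowed rate fit matches the closed-form OLS solution", {
  s <- make_series(day = c(0, 1, 2), methane = c(0, 1, 2))
  est <- window_rate(s, "methane", -0.5, 2.5)
  expect_equal(est$slope, 1)
  expect_equal(est$r2, 1)
  expect_equal(est$n, 3)

  set.seed(21)
  day <- sort(runif(9, 100, 200))
  y <- 2e-5 * day + rnorm(9, 0, 1e-4)
  s2 <- make_series(day = day, methane = y)
  est2 <- window_rate(s2, "methane", 100, 200)
  oracle <- ols_closed_form(day, y)
  expect_equal(est2$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(est2$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(est2$r2, oracle$r2, tolerance = 1e-12)
})

test_that("constant response has zero slope and r2 defined as 0", {
  s <- make_series(day = c(0, 10, 20), hydrogen = rep(3e-10, 3))
  est <- window_rate(s, "hydrogen", 0, 20)
  expect_equal(est$slope, 0)
  expect_equal(est$r2, 0)
})

test_that("replicates are pooled so triplicate bottles give n = 9", {
  days <- rep(c(553, 570, 586), each = 3)
  s <- geochem_series(
    data.frame(day = days, bottle = rep(c("B1", "B2", "B3"), 3),
               replicate = rep(1:3, 3), sulfate = NA, methane = 4e-5 * days,
               hydrogen = NA, d13c_ch4 = NA, cells = NA),
    test_geometry())
  est <- window_rate(s, "methane", 553, 586)
  expect_equal(est$n, 9)
  expect_equal(est$slope, 4e-5, tolerance = 1e-10)
})

test_that("window must hold at least two points with time spread", {
  s <- make_series(day = c(0, 50), methane = c(1e-3, 2e-3))
  expect_error(window_rate(s, "methane", 0, 10), "fewer than 2")
  s2 <- make_series(day = c(10, 10), methane = c(1e-3, 2e-3),
                    replicate = c(1L, 2L))
  expect_error(window_rate(s2, "methane", 0, 20), "time variance")
})

test_that("noisy windows recover the generating slope within 3 SE", {
  set.seed(99)
  hits <- 0
  for (i in 1:50) {
    day <- seq(362, 396, length.out = 6)
    y <- 0.13e-3 * day + rnorm(6, 0, 0.05e-3)
    s <- make_series(day = day, methane = pmax(y, 0))
    est <- window_rate(s, "methane", 362, 396)
    se <- ols_closed_form(day, s$records$methane)$se_slope
    if (abs(est$slope - 0.13e-3) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 47)
})

test_that("peak detection uses replicate means and earliest-day ties", {
  s1 <- make_series(day = 5, hydrogen = 2e-9)
  expect_equal(detect_peak(s1, "hydrogen"), list(day = 5, value = 2e-9, n = 1))

  s2 <- make_series(day = c(0, 10, 20, 30), hydrogen = c(1, 5, 5, 2) * 1e-9)
  pk <- detect_peak(s2, "hydrogen")
  expect_equal(pk$day, 10)
  expect_equal(pk$value, 5e-9)
})

test_that("an injected bump is located within one sampling interval", {
  set.seed(13)
  days <- seq(0, 580, by = 20)
  base <- 3e-10 + 7e-9 * exp(-((days - 280) / 30)^2)
  for (rep in 1:10) {
    obs <- base * exp(rnorm(length(days), 0, 0.1))
    s <- make_series(day = days, hydrogen = obs)
    pk <- detect_peak(s, "hydrogen")
    expect_lte(abs(pk$day - 280), 20)
  }
})

test_that("plateau detection splits on stability breaks", {
  s <- make_series(day = seq(0, 50, by = 10), hydrogen = rep(3e-10, 6))
  p <- detect_plateaus(s, "hydrogen", cv_max = 0.1, min_n = 3)
  expect_equal(nrow(p), 1)
  expect_equal(p$t0, 0); expect_equal(p$t1, 50)
  expect_equal(p$sd, 0)

  s2 <- make_series(day = seq(0, 50, by = 10),
                    hydrogen = c(1, 1, 1, 9, 9, 9) * 1e-10)
  p2 <- detect_plateaus(s2, "hydrogen", cv_max = 0.1, min_n = 3)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$mean, c(1e-10, 9e-10))
})

test_that("a noisy plateau is recovered near its generating level", {
  set.seed(31)
  days <- seq(461, 524, by = 7)
  for (rep in 1:10) {
    vals <- 0.30e-9 * exp(rnorm(length(days), 0, 0.15))
    s <- make_series(day = days, hydrogen = vals)
    p <- detect_plateaus(s, "hydrogen", cv_max = 0.25, min_n = 3)
    expect_gte(nrow(p), 1)
    big <- p[which.max(p$n), ]
    expect_lt(abs(big$mean - 0.30e-9) / 0.30e-9, 0.10)
  }
})

test_that("phase rules segment a constructed incubation at its crossings", {
  days <- seq(0, 600, by = 25)
  sulf <- pmax(12e-3 - 2.06e-5 * days, 2e-5)   # crosses 5 mM at ~340
  sulf[days >= 550] <- 5e-5
  meth <- ifelse(days < 550, 5e-4, 5e-4 + (days - 550) * 1e-5)
  d13 <- ifelse(days < 550, -35, -35 - (days - 550) * 0.1)
  s <- make_series(day = days, sulfate = sulf, methane = meth, d13c = d13)
  seg <- segment_phases(s)
  expect_identical(seg$phase, c("sulfate_reduction_aom", "methane_cycling",
                                "net_methanogenesis"))
  # contiguity over the full observed span
  expect_equal(seg$t_start[1], 0)
  expect_equal(seg$t_end[nrow(seg)], 600)
  expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])
  # boundaries at the rule crossings
  expect_lte(abs(seg$t_start[2] - 350), 25)
  expect_lte(abs(seg$t_start[3] - 550), 25)
})

test_that("sulfate-replete series stays in a single phase", {
  s <- make_series(day = seq(0, 300, by = 30),
                   sulfate = seq(12e-3, 8e-3, length.out = 11))
  seg <- segment_phases(s)
  expect_equal(nrow(seg), 1)
  expect_identical(seg$phase, "sulfate_reduction_aom")
})

test_that("segmentation recovers the generator's regime switches", {
  sim <- simulate_microcosm(sim_config(seed = 4))
  tr <- sim$truth
  idx <- tr$day %in% sim$config$sampling_days
  truth_series <- geochem_series(
    data.frame(day = tr$day[idx], bottle = tr$bottle[idx],
               replicate = as.integer(factor(tr$bottle[idx])),
               sulfate = tr$sulfate[idx], methane = tr$methane[idx],
               hydrogen = tr$hydrogen[idx], d13c_ch4 = tr$d13c_ch4[idx],
               cells = NA_real_),
    sim$config$geometry)
  seg_truth <- segment_phases(truth_series)
  seg_obs <- segment_phases(sim$observed)
  expect_setequal(seg_truth$phase, c("sulfate_reduction_aom",
                                     "methane_cycling",
                                     "net_methanogenesis"))
  interval <- 30
  for (ph in seg_truth$phase) {
    t_t <- seg_truth$t_start[seg_truth$phase == ph]
    t_o <- seg_obs$t_start[seg_obs$phase == ph]
    expect_length(t_o, 1)
    expect_lte(abs(t_o - t_t), 2 * interval)
  }
})
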