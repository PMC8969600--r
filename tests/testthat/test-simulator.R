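# One full default-scenario run shared by the slower checks below.
sim_default <- simulate_microcosm(sim_config(seed = 1))

make_state <- function(S = 1e-2, H = 5e-10, M = 5e-5, delta = -34.9,
                       Z = 0, Fe = 0, OX = 0, L = 0.05, B_srb = 2e7,
                       B_mca = 2e5, B_other = 2e8) {
  m13 <- M * cryptomethane:::.delta_to_ratio(delta) /
    (1 + cryptomethane:::.delta_to_ratio(delta))
  c(time = 0, S = S, H = H, M12 = M - m13, M13 = m13, Z = Z, Fe = Fe,
    OX = OX, L = L, B_srb = B_srb, B_mca = B_mca, B_other = B_other)
}

zero_cfg <- function(...) {
  sim_config(kinetics = list(k_f = 0, h2_bg = 0, v_sr = 0, v_mg = 0,
                             decay = 0),
             sulfur = list(k_reox = 0, k_pyr = 0, k_pyr_fe = 0),
             ...)
}

test_that("null dynamics leave the state unchanged", {
  for (mode in c("dynamic", "qss")) {
    cfg <- zero_cfg(h2_mode = mode)
    st <- make_state()
    st2 <- sim_step(st, cfg, 0.1)
    expect_equal(st2[["time"]], 0.1)
    expect_equal(st2[names(st)[-1]], st[-1], tolerance = 0)
  }
})

test_that("sulfate reduction conserves sulfur and draws four hydrogens", {
  cfg <- sim_config(kinetics = list(k_f = 0, h2_bg = 0, v_sr = 1e-13,
                                    v_mg = 0, decay = 0, y_srb = 0),
                    sulfur = list(k_reox = 0, k_pyr = 0, k_pyr_fe = 0),
                    h2_mode = "dynamic")
  st <- make_state(H = 1e-6)   # hydrogen-rich so no flux rescue triggers
  st2 <- sim_step(st, cfg, 0.1)
  dS <- st2[["S"]] - st[["S"]]
  dZ <- st2[["Z"]] - st[["Z"]]
  dH <- st2[["H"]] - st[["H"]]
  expect_lt(dS, 0)
  expect_equal(dZ, -dS, tolerance = 1e-9)
  expect_equal(dH, 4 * dS, tolerance = 1e-9)
})

test_that("forward methanogenesis makes one methane per four hydrogens", {
  cfg <- sim_config(kinetics = list(k_f = 0, h2_bg = 0, v_sr = 0,
                                    v_mg = 1e-11, decay = 0, y_mca = 0),
                    sulfur = list(k_reox = 0, k_pyr = 0, k_pyr_fe = 0),
                    h2_mode = "dynamic")
  st <- make_state(H = 1e-6)   # far above the threshold: F > 0
  st2 <- sim_step(st, cfg, 0.1)
  dM <- (st2[["M12"]] + st2[["M13"]]) - (st[["M12"]] + st[["M13"]])
  dH <- st2[["H"]] - st[["H"]]
  expect_gt(dM, 0)
  expect_equal(dM, -dH / 4, tolerance = 1e-12)
})

test_that("AOM consumes methane, preferring the light isotopologue", {
  cfg <- sim_config(kinetics = list(k_f = 0, h2_bg = 0, v_sr = 0,
                                    v_mg = 1e-10, decay = 0, y_mca = 0),
                    sulfur = list(k_reox = 0, k_pyr = 0, k_pyr_fe = 0),
                    h2_mode = "dynamic")
  st <- make_state(H = 1e-11, M = 2e-3)   # far below threshold: F < 0
  d0 <- cryptomethane:::.delta_of_pools(st[["M12"]], st[["M13"]])
  st2 <- sim_step(st, cfg, 0.1)
  rates <- attr(st2, "rates")
  expect_gt(rates[["r_aom"]], 0)
  expect_equal(rates[["r_mg"]], 0)
  dM12 <- st2[["M12"]] - st[["M12"]]
  dM13 <- st2[["M13"]] - st[["M13"]]
  expect_lt(dM12 + dM13, 0)
  # the consumed increment is isotopically lighter than the pool it left
  d_consumed <- cryptomethane:::.delta_of_pools(-dM12, -dM13)
  expect_lt(d_consumed, d0)
  # so the residual pool is enriched after consumption
  d1 <- cryptomethane:::.delta_of_pools(st2[["M12"]], st2[["M13"]])
  expect_gt(d1, d0)
})

test_that("net methane flux sign always matches the thermodynamic drive", {
  cfg <- fast_sim_config(seed = 3)
  st <- cryptomethane:::.sim_init_state(cfg)
  for (i in 1:300) {
    st2 <- sim_step(st, cfg, cfg$dt)
    rates <- attr(st2, "rates")
    drive <- attr(st2, "drive")
    net <- rates[["r_mg"]] - rates[["r_aom"]]
    if (net > 0) expect_gt(drive, 0)
    if (net < 0) expect_lt(drive, 0)
    st <- st2
  }
})

test_that("a fixed seed reproduces the simulation exactly", {
  a <- simulate_microcosm(fast_sim_config(seed = 7))
  b <- simulate_microcosm(fast_sim_config(seed = 7))
  expect_identical(a$truth, b$truth)
  expect_identical(a$observed$records, b$observed$records)
  c <- simulate_microcosm(fast_sim_config(seed = 8))
  expect_false(identical(a$observed$records, c$observed$records))
})

test_that("zero jitter and zero noise give three identical bottles", {
  cfg <- sim_config(horizon = 90, sampling_days = seq(0, 90, 30),
                    obs = list(jitter_cv = 0,
                               noise_cv = c(sulfate = 0, methane = 0,
                                            hydrogen = 0, cells = 0),
                               noise_sd_d13c = 0))
  sim <- simulate_microcosm(cfg)
  r <- sim$observed$records
  b1 <- r[r$bottle == "B1", c("day", "sulfate", "methane", "hydrogen")]
  for (b in c("B2", "B3")) {
    rb <- r[r$bottle == b, c("day", "sulfate", "methane", "hydrogen")]
    rownames(rb) <- rownames(b1) <- NULL
    expect_equal(rb, b1)
  }
})

test_that("a horizon before the last sampling day is rejected", {
  expect_error(sim_config(horizon = 100,
                          sampling_days = seq(0, 200, 50)),
               "horizon")
})

test_that("all pools stay non-negative through the default scenario", {
  tr <- sim_default$truth
  for (col in c("sulfate", "hydrogen", "methane", "sulfide", "fe",
                "oxidant", "labile_c", "b_srb", "b_mca")) {
    expect_true(all(tr[[col]] >= 0, na.rm = TRUE), label = col)
  }
})

test_that("the default scenario reproduces the transition event sequence", {
  ev <- sim_events(sim_default$truth)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$t_sulfate_1mM < ev$t_h2_peak))
  expect_true(all(ev$t_h2_peak < ev$t_ch4_peak))
  expect_true(all(ev$t_ch4_peak < ev$t_d13c_min))
  # magnitudes in the study's qualitative ranges
  tr <- sim_default$truth
  for (b in unique(tr$bottle)) {
    trb <- tr[tr$bottle == b, ]
    expect_gt(max(trb$hydrogen), 2e-9)
    expect_lt(max(trb$hydrogen), 2e-8)
    expect_gt(max(trb$methane), 1.2e-3)
    expect_gt(ev$t_sulfate_1mM[ev$bottle == b], 180)
    expect_lt(ev$t_sulfate_1mM[ev$bottle == b], 360)
  }
})

test_that("late-phase hydrogen settles near the thermodynamic threshold", {
  tr <- sim_default$truth
  late <- tr[tr$day >= 540 & tr$bottle == "B1", ]
  thr <- h2_threshold(late$methane, 1e-2,
                      sim_default$config$geometry$temperature)
  ratio <- late$hydrogen / thr
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("amplicon counts land in guild ASVs in proportion to biomass", {
  biomass <- data.frame(bottle = "B1", day = c(0, 30),
                        b_srb = 0, b_mca = c(1e6, 2e6), b_other = 0)
  tab <- sample_amplicons(biomass,
                          guilds = default_guilds()["methane_cycling_archaea"],
                          depth = 5000, n_background = 0,
                          nontarget_fraction = 0, seed = 1)
  expect_true(all(rowSums(tab$counts) == 5000))
  mg_cols <- grepl("^methane_cycling_archaea", colnames(tab$counts))
  expect_equal(unname(rowSums(tab$counts[, mg_cols, drop = FALSE])),
               c(5000, 5000))
})

test_that("sampled guild fractions track expectations at multinomial precision", {
  set.seed(40)
  sim <- simulate_microcosm(sim_config(seed = 5))
  depth <- 30000
  tab <- sample_amplicons(sim$biomass, depth = depth, seed = 41)
  expected <- attr(tab, "expected_fractions")
  tr <- guild_trajectory(tab, default_guilds()$srb)
  m <- merge(tr, expected[, c("sample_id", "srb")], by = "sample_id")
  p <- m$srb
  within_band <- abs(m$abundance - p) <= 3 * sqrt(p * (1 - p) / depth) +
    0.01 * p   # small allowance for the nontarget share of the library
  expect_gte(mean(within_band), 0.9)
})
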