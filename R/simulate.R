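# Kinetic box model of a sealed anoxic sediment microcosm with a
# thermodynamic gate on hydrogenotrophic methanogenesis.
#
# Mechanism: fermentation of a labile-carbon pool supplies H2; sulfate
# reducers (SRB) consume H2 while sulfate lasts, holding it below the
# free-energy threshold so any methane present is slowly oxidised (AOM
# through reverse methanogenesis, F < 0). A cryptic sulfur loop
# (reoxidation of sulfide back to sulfate, in competition with
# pyritization) sustains a low sulfate plateau after the primary pool is
# gone. When the recycled sulfate flux can no longer absorb the
# fermentative H2 supply, hydrogen overshoots the threshold (F > 0), the
# methanogen guild blooms and a transient methane peak forms; renewed SRB
# drawdown of H2 then reverses the gate (cryptic methane cycling) until
# pyritization exhausts free sulfide, after which the system settles into
# net methanogenesis with hydrogen pinned just above the threshold and
# methane d13C declining toward the biogenic end-member. Methanogen
# biomass grows only from forward methanogenesis; SRB additionally grow
# syntrophically (on methanogenic H2 turnover) once sulfate is depleted.

.delta_to_ratio <- function(delta) .R_VPDB * (1 + delta / 1000)

.pools_from_delta <- function(total, delta) {
  r <- .delta_to_ratio(delta)
  c(m12 = total / (1 + r), m13 = total * r / (1 + r))
}

.delta_of_pools <- function(m12, m13) {
  ifelse(m12 > 0, (m13 / m12 / .R_VPDB - 1) * 1000, NA_real_)
}

#' Simulator configuration
#'
#' Defaults describe triplicate ~11 mM sulfate estuarine-sediment bottles
#' incubated at 21 degrees C for 586 days and sampled monthly; they were
#' chosen to reproduce the qualitative transition sequence (sulfate
#' depletion near day 300, a transient nM-scale hydrogen peak, a transient
#' mM-scale methane peak about a month later, late d13C-CH4 decline toward
#' -80 permil) rather than fitted to any dataset. See the package vignette
#' for the meaning and units of every constant.
#'
#' @param geometry An [incubation_geometry()].
#' @param horizon Simulated days. Default 586.
#' @param dt Euler step, days. Default 0.1.
#' @param sampling_days Observation days (sorted). Default monthly.
#' @param init Named list of initial pools: `sulfate`, `labile_c`, `ch4`,
#'   `h2`, `sulfide`, `fe` (reactive iron), `ox` (sulfide-reoxidation
#'   oxidant; all mol/L), `b_srb`, `b_mca`, `b_other` (cells/ml).
#' @param kinetics Named list of rate constants: `k_f` (1/day fermentation
#'   of labile carbon), `stoich_f` (mol H2 per mol labile C), `h2_bg`
#'   (constant baseline H2 supply from slow necromass turnover,
#'   mol/L/day), `v_sr`,
#'   `v_mg` (mol/L/day per cell/ml), half-saturations `K_S`, `K_Hsr`,
#'   `K_Hmg`, `K_M` (mol/L), yields `y_srb`, `y_mca`, `y_syn`
#'   (cells/ml per mol/L), `decay` (1/day), syntrophy sulfate gate `s_syn`
#'   (mol/L).
#' @param gate Thermodynamic gate: `const` ([thermo_constants()]), `co2`
#'   (fixed aqueous CO2, mol/L), `chi` (drive shape, dimensionless),
#'   `dg_min` (minimum energy quantum, kJ/mol), detection floors
#'   `floor_ch4`, `floor_h2` (mol/L).
#' @param sulfur Cryptic sulfur loop: `k_reox` (sulfide reoxidation to
#'   sulfate, 1/day at saturating oxidant), `K_OX` (oxidant
#'   half-saturation, mol/L; the finite oxidant pool `init$ox` is consumed
#'   1:1 and its exhaustion ends the cryptic loop), `k_pyr` (background
#'   oxidant-independent pyritization, 1/day), `k_pyr_fe` (iron-gated
#'   pyritization, 1/day at saturating iron) and `K_Fe` (iron
#'   half-saturation, mol/L). Iron is consumed 1:1 with pyritized
#'   sulfide; `k_pyr_fe = 0` disables the iron gate.
#' @param isotopes `delta_dic`, `eps_mg`, `eps_aom`, `delta_seed`
#'   (permil).
#' @param ch4_spike Optional `list(day, amount, delta)` methane addition
#'   (mol/L porewater-equivalent). Default: 1.7 mM of -34.9 permil
#'   methane on day 44, emulating the headspace amendment; `NULL`
#'   disables it.
#' @param obs Observation model: `jitter_cv` (bottle-to-bottle kinetic
#'   jitter), `noise_cv` (named multiplicative measurement CV per
#'   analyte), `noise_sd_d13c` (permil), `floors` (named detection
#'   floors, mol/L).
#' @param n_bottles Number of bottles. Default 3.
#' @param seed Integer seed for jitter and measurement noise.
#' @param h2_mode `"qss"` (default; hydrogen solved quasi-statically each
#'   step) or `"dynamic"` (fully explicit hydrogen update). See
#'   [sim_step()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(geometry = incubation_geometry(0.040, 0.020, 0.8),
                       horizon = 586, dt = 0.1,
                       sampling_days = c(seq(0, 570, by = 30), 586),
                       init = list(), kinetics = list(), gate = list(),
                       sulfur = list(), isotopes = list(),
                       ch4_spike = list(day = 44, amount = 1.7e-3,
                                        delta = -34.9),
                       obs = list(), n_bottles = 3, seed = 1,
                       h2_mode = c("qss", "dynamic")) {
  defaults <- list(
    init = list(sulfate = 11e-3, labile_c = 0.0411, ch4 = 5e-5, h2 = 5e-10,
                sulfide = 0, fe = 1.095e-2, ox = 9.1e-3, b_srb = 2e7,
                b_mca = 4e4, b_other = 2e8),
    kinetics = list(k_f = 0.0045, stoich_f = 2, h2_bg = 5e-6, v_sr = 5e-11,
                    K_S = 2.5e-3, K_Hsr = 1e-9, v_mg = 7e-10, K_Hmg = 4e-9,
                    K_M = 3e-2, y_srb = 3e8, y_mca = 8e8, y_syn = 8e10,
                    decay = 0.0015, s_syn = 2e-4),
    gate = list(const = thermo_constants(), co2 = 0.01, chi = 4, dg_min = 0,
                floor_ch4 = 1e-8, floor_h2 = 1e-11),
    sulfur = list(k_reox = 1.2, k_pyr = 0, k_pyr_fe = 2.8, K_Fe = 1e-4,
                  K_OX = 5e-5),
    isotopes = list(delta_dic = -10, eps_mg = 70, eps_aom = 8,
                    delta_seed = -34.9),
    obs = list(jitter_cv = 0.05,
               noise_cv = c(sulfate = 0.06, methane = 0.06, hydrogen = 0.20,
                            cells = 0.35),
               noise_sd_d13c = 1,
               floors = c(sulfate = 1e-5, methane = 1e-6, hydrogen = 5e-11))
  )
  merge_in <- function(base, user) utils::modifyList(base, user)
  cfg <- list(geometry = geometry, horizon = horizon, dt = dt,
              sampling_days = sort(sampling_days),
              init = merge_in(defaults$init, init),
              kinetics = merge_in(defaults$kinetics, kinetics),
              gate = merge_in(defaults$gate, gate),
              sulfur = merge_in(defaults$sulfur, sulfur),
              isotopes = merge_in(defaults$isotopes, isotopes),
              ch4_spike = ch4_spike,
              obs = merge_in(defaults$obs, obs),
              n_bottles = n_bottles, seed = seed,
              h2_mode = match.arg(h2_mode))
  stopifnot(is_incubation_geometry(geometry), dt > 0, horizon > 0,
            cfg$gate$chi > 0, n_bottles >= 1)
  if (any(unlist(cfg$kinetics[c("k_f", "v_sr", "v_mg", "decay")]) < 0) ||
      any(unlist(cfg$sulfur) < 0)) {
    stop("rate constants must be >= 0")
  }
  if (max(cfg$sampling_days) > horizon) {
    stop("horizon is earlier than the last sampling day")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Initial state vector for one bottle.
.sim_init_state <- function(cfg) {
  ini <- cfg$init
  m <- .pools_from_delta(ini$ch4, cfg$isotopes$delta_seed)
  c(time = 0, S = ini$sulfate, H = ini$h2, M12 = unname(m["m12"]),
    M13 = unname(m["m13"]), Z = ini$sulfide, Fe = ini$fe, OX = ini$ox,
    L = ini$labile_c, B_srb = ini$b_srb, B_mca = ini$b_mca,
    B_other = ini$b_other)
}

# Free energy and clipped thermodynamic drive at given CH4/H2 (scalars).
.gate_eval <- function(M, H, g, temp) {
  dg <- g$const$dg0 + g$const$r_kj * temp *
    (log(max(M, g$floor_ch4)) - log(g$co2) - 4 * log(max(H, g$floor_h2)))
  drive <- 1 - exp((dg + g$dg_min) / (g$chi * g$const$r_kj * temp))
  list(dg = dg, drive = max(-1, min(1, drive)))
}

# Quasi-steady hydrogen: root of supply(H) - demand(H), monotone
# decreasing in H. Returns NA when demand cannot absorb the supply even
# at the top of the bracket (caller falls back to the explicit update).
.h2_qss <- function(M, S, B_srb, B_mca, r_f, k, g, temp,
                    lo = 1e-13, hi = 1e-2, h_prev = NA) {
  supply0 <- k$stoich_f * r_f + k$h2_bg
  srb_cap <- 4 * k$v_sr * B_srb * S / (S + k$K_S)
  net <- function(h) {
    gt <- .gate_eval(M, h, g, temp)
    r_sr <- srb_cap * h / (h + k$K_Hsr)
    r_mg <- if (gt$drive > 0) {
      4 * k$v_mg * B_mca * h / (h + k$K_Hmg) * gt$drive
    } else 0
    r_aom <- if (gt$drive < 0 && M > g$floor_ch4) {
      4 * k$v_mg * B_mca * M / (M + k$K_M) * (-gt$drive)
    } else 0
    supply0 + r_aom - r_sr - r_mg
  }
  if (supply0 == 0 && B_mca == 0 && (B_srb == 0 || srb_cap == 0)) {
    return(NA_real_)
  }
  f_hi <- net(hi)
  if (f_hi > 0) return(NA_real_)
  f_lo <- net(lo)
  if (f_lo == 0 && f_hi == 0) return(NA_real_)  # no active H2 fluxes
  if (f_lo <= 0) return(lo)
  # bisection on log10(H); warm-started from the previous step's root
  xlo <- log10(lo); xhi <- log10(hi)
  if (is.finite(h_prev) && h_prev > lo && h_prev < hi) {
    wl <- log10(h_prev) - 1.5; wh <- log10(h_prev) + 1.5
    if (wl > xlo && net(10^wl) > 0) xlo <- wl
    if (wh < xhi && net(10^wh) <= 0) xhi <- wh
  }
  n_it <- ceiling(log2((xhi - xlo) / 1e-9))
  for (i in seq_len(n_it)) {
    xm <- (xlo + xhi) / 2
    if (net(10^xm) > 0) xlo <- xm else xhi <- xm
  }
  10^((xlo + xhi) / 2)
}

#' One step of the microcosm model
#'
#' Advances the state by `dt` days. Rates follow Monod kinetics with a
#' thermodynamic drive `F = 1 - exp((dG + dg_min) / (chi R T))` clipped to
#' `[-1, 1]`: forward methanogenesis runs when `F > 0`, AOM when `F < 0`
#' and methane exceeds its floor. Methane isotopologues are tracked
#' separately; production carries `delta_dic - eps_mg`, AOM consumes the
#' light isotopologue preferentially by `eps_aom`. If the step would
#' drive any pool negative, all fluxes are rescaled by a common factor so
#' the limiting pool lands exactly at zero.
#'
#' Hydrogen is a fast intermediate: its pool (~1e-9 M) turns over in
#' seconds against ~1e-4 M/day fluxes, so with the default
#' `h2_mode = "qss"` the step solves the hydrogen concentration at which
#' fermentative supply (plus AOM release) balances sulfate-reducer and
#' methanogen demand — a unique root, found by bisection in log space —
#' and integrates only the slow pools explicitly. `h2_mode = "dynamic"`
#' applies the fully explicit update (`dH/dt` included), which is exact
#' for stoichiometric bookkeeping at small rates but unstable at
#' realistic ones.
#'
#' @param state Named numeric state vector (`time`, `S`, `H`, `M12`,
#'   `M13`, `Z`, `L`, `B_srb`, `B_mca`, `B_other`), as produced by
#'   [simulate_microcosm()] internals.
#' @param cfg A [sim_config()] (its `kinetics` are used as-is; bottle
#'   jitter is applied by [simulate_microcosm()]).
#' @param dt Step size, days.
#' @return The new state vector, with attributes `rates` (named rate
#'   vector), `dg` and `drive`.
#' @export
sim_step <- function(state, cfg, dt) {
  if (dt <= 0) stop("dt must be > 0")
  k <- cfg$kinetics; g <- cfg$gate; sl <- cfg$sulfur; iso <- cfg$isotopes
  temp <- cfg$geometry$temperature
  S <- state[["S"]]; H <- state[["H"]]
  M12 <- state[["M12"]]; M13 <- state[["M13"]]
  M <- M12 + M13
  Z <- state[["Z"]]; Fe <- state[["Fe"]]; OX <- state[["OX"]]
  L <- state[["L"]]
  B_srb <- state[["B_srb"]]; B_mca <- state[["B_mca"]]

  r_f <- k$k_f * L
  qss <- identical(cfg$h2_mode, "qss")
  if (qss) {
    h_star <- .h2_qss(M, S, B_srb, B_mca, r_f, k, g, temp, h_prev = H)
    if (!is.na(h_star)) H <- h_star else qss <- FALSE
  }
  r_sr <- k$v_sr * B_srb * S / (S + k$K_S) * H / (H + k$K_Hsr)
  r_reox <- sl$k_reox * Z * OX / (OX + sl$K_OX)
  r_pyr_fe <- sl$k_pyr_fe * Fe / (Fe + sl$K_Fe) * Z
  r_pyr <- sl$k_pyr * Z + r_pyr_fe

  gt <- .gate_eval(M, H, g, temp)
  dg <- gt$dg; drive <- gt$drive
  r_mg <- 0; r_aom <- 0
  if (drive > 0) {
    r_mg <- k$v_mg * B_mca * H / (H + k$K_Hmg) * drive
  } else if (drive < 0 && M > g$floor_ch4) {
    r_aom <- k$v_mg * B_mca * M / (M + k$K_M) * (-drive)
  }

  rates <- c(r_f = r_f, r_sr = r_sr, r_reox = r_reox, r_pyr = r_pyr,
             r_mg = r_mg, r_aom = r_aom)
  if (any(!is.finite(rates))) {
    stop("non-finite rate in step: ",
         paste(names(rates)[!is.finite(rates)], collapse = ", "))
  }

  # isotopologue partitioning
  rp <- .delta_to_ratio(iso$delta_dic - iso$eps_mg)
  prod12 <- r_mg / (1 + rp)
  prod13 <- r_mg * rp / (1 + rp)
  alpha <- 1 + iso$eps_aom / 1000   # kinetic preference for 12C
  denom <- M12 + M13 / alpha
  cons12 <- if (denom > 0) r_aom * M12 / denom else 0
  cons13 <- if (denom > 0) r_aom * (M13 / alpha) / denom else 0

  dS <- -r_sr + r_reox
  dH <- k$stoich_f * r_f + k$h2_bg - 4 * r_sr - 4 * r_mg + 4 * r_aom
  dM12 <- prod12 - cons12
  dM13 <- prod13 - cons13
  dZ <- r_sr - r_reox - r_pyr
  dFe <- -r_pyr_fe
  dOX <- -r_reox
  dL <- -r_f
  dB_srb <- k$y_srb * r_sr + (S < k$s_syn) * k$y_syn * (r_mg + r_aom) -
    k$decay * B_srb
  dB_mca <- k$y_mca * r_mg - k$decay * B_mca
  dB_other <- 0

  deriv <- c(S = dS, M12 = dM12, M13 = dM13, Z = dZ, Fe = dFe, OX = dOX,
             L = dL, B_srb = dB_srb, B_mca = dB_mca, B_other = dB_other)
  if (!qss) deriv <- c(deriv, H = dH)
  pools <- state[names(deriv)]
  proj <- pools + deriv * dt
  lambda <- 1
  neg <- which(proj < 0 & deriv < 0)
  if (length(neg)) {
    lambda <- min(pools[neg] / (-deriv[neg] * dt))
    lambda <- max(0, min(1, lambda))
  }
  new_pools <- pmax(pools + deriv * lambda * dt, 0)
  if (any(!is.finite(new_pools)) || (qss && !is.finite(H))) {
    stop("non-finite pool after step: ",
         paste(names(new_pools)[!is.finite(new_pools)], collapse = ", "))
  }
  out <- c(time = state[["time"]] + dt,
           new_pools[c("S")],
           H = if (qss) H else unname(new_pools[["H"]]),
           new_pools[c("M12", "M13", "Z", "Fe", "OX", "L", "B_srb", "B_mca",
                       "B_other")])
  attr(out, "rates") <- rates * lambda
  attr(out, "dg") <- dg
  attr(out, "drive") <- drive
  out
}

# Integrate one bottle; returns a truth matrix recorded every `record_dt`.
.sim_run_bottle <- function(cfg, record_dt = 1) {
  n_steps <- ceiling(cfg$horizon / cfg$dt)
  rec_days <- sort(unique(c(seq(0, cfg$horizon, by = record_dt),
                            cfg$sampling_days, cfg$horizon)))
  out <- matrix(NA_real_, nrow = length(rec_days), ncol = 14,
                dimnames = list(NULL, c("day", "sulfate", "hydrogen",
                                        "methane", "d13c_ch4", "sulfide",
                                        "fe", "oxidant", "labile_c",
                                        "b_srb", "b_mca", "b_other", "dg",
                                        "drive")))
  state <- .sim_init_state(cfg)
  spike_done <- is.null(cfg$ch4_spike)
  rec_i <- 1
  record <- function(state, dg, drive, day = state[["time"]]) {
    out[rec_i, ] <<- c(day, state[["S"]], state[["H"]],
                       state[["M12"]] + state[["M13"]],
                       .delta_of_pools(state[["M12"]], state[["M13"]]),
                       state[["Z"]], state[["Fe"]], state[["OX"]],
                       state[["L"]], state[["B_srb"]], state[["B_mca"]],
                       state[["B_other"]], dg, drive)
    rec_i <<- rec_i + 1
  }
  record(state, NA_real_, NA_real_)
  tol <- 1e-9
  for (i in seq_len(n_steps)) {
    if (!spike_done && state[["time"]] + cfg$dt >= cfg$ch4_spike$day - tol) {
      m <- .pools_from_delta(cfg$ch4_spike$amount, cfg$ch4_spike$delta)
      state[["M12"]] <- state[["M12"]] + m[["m12"]]
      state[["M13"]] <- state[["M13"]] + m[["m13"]]
      spike_done <- TRUE
    }
    state <- sim_step(state, cfg, cfg$dt)
    if (rec_i <= length(rec_days) &&
        state[["time"]] >= rec_days[rec_i] - cfg$dt / 2) {
      record(state, attr(state, "dg"), attr(state, "drive"),
             day = rec_days[rec_i])
    }
  }
  out[seq_len(rec_i - 1), , drop = FALSE]
}

#' Simulate a triplicate microcosm experiment
#'
#' Runs the box model for `n_bottles` bottles whose kinetic constants are
#' jittered multiplicatively (log-normal, CV `obs$jitter_cv`), records
#' noise-free truth trajectories, and samples observations at the
#' configured days with multiplicative log-normal measurement noise and
#' detection floors. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param record_dt Truth recording interval, days. Default 1.
#' @return A list with:
#'   \describe{
#'     \item{truth}{data.frame of noise-free per-bottle trajectories
#'       (`bottle`, `day`, pools, biomasses, `dg`, `drive`);}
#'     \item{observed}{a [geochem_series()] of noisy observations at the
#'       sampling days (one record per bottle per day, `replicate` =
#'       bottle index);}
#'     \item{biomass}{data.frame of true guild biomasses at the sampling
#'       days;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_microcosm <- function(cfg, record_dt = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # population kinetics are jittered between bottles; the slurry chemistry
  # (labile carbon, iron, rate of hydrolysis) is shared by all bottles
  # from the same homogenised sediment
  jitter_names <- c("v_sr", "v_mg", "y_mca")
  cv <- cfg$obs$jitter_cv
  sdlog <- sqrt(log(1 + cv^2))
  truth_list <- vector("list", cfg$n_bottles)
  for (b in seq_len(cfg$n_bottles)) {
    cfg_b <- cfg
    if (cv > 0) {
      jit <- stats::rlnorm(length(jitter_names), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
      for (j in seq_along(jitter_names)) {
        cfg_b$kinetics[[jitter_names[j]]] <-
          cfg$kinetics[[jitter_names[j]]] * jit[j]
      }
    }
    tr <- .sim_run_bottle(cfg_b, record_dt)
    truth_list[[b]] <- data.frame(bottle = sprintf("B%d", b),
                                  as.data.frame(tr),
                                  stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_list)

  # observations at sampling days
  noise_cv <- cfg$obs$noise_cv
  floors <- cfg$obs$floors
  obs_list <- list()
  for (b in seq_len(cfg$n_bottles)) {
    tr <- truth_list[[b]]
    idx <- match(cfg$sampling_days, tr$day)
    stopifnot(!any(is.na(idx)))
    noisy <- function(x, cv) {
      if (cv <= 0) return(x)
      x * stats::rlnorm(length(x), meanlog = -log(1 + cv^2) / 2,
                        sdlog = sqrt(log(1 + cv^2)))
    }
    sulfate <- pmax(noisy(tr$sulfate[idx], noise_cv[["sulfate"]]),
                    floors[["sulfate"]])
    methane <- pmax(noisy(tr$methane[idx], noise_cv[["methane"]]),
                    floors[["methane"]])
    hydrogen <- pmax(noisy(tr$hydrogen[idx], noise_cv[["hydrogen"]]),
                     floors[["hydrogen"]])
    cells <- noisy(tr$b_srb[idx] + tr$b_mca[idx] + tr$b_other[idx],
                   noise_cv[["cells"]])
    d13c <- tr$d13c_ch4[idx] +
      stats::rnorm(length(idx), 0, cfg$obs$noise_sd_d13c)
    obs_list[[b]] <- data.frame(day = cfg$sampling_days,
                                bottle = sprintf("B%d", b), replicate = b,
                                sulfate = sulfate, methane = methane,
                                hydrogen = hydrogen, d13c_ch4 = d13c,
                                cells = cells, stringsAsFactors = FALSE)
  }
  observed <- geochem_series(do.call(rbind, obs_list), cfg$geometry,
                             experiment_id = "simulated_microcosm")
  biomass <- do.call(rbind, lapply(seq_len(cfg$n_bottles), function(b) {
    tr <- truth_list[[b]]
    idx <- match(cfg$sampling_days, tr$day)
    data.frame(bottle = sprintf("B%d", b), day = cfg$sampling_days,
               b_srb = tr$b_srb[idx], b_mca = tr$b_mca[idx],
               b_other = tr$b_other[idx], stringsAsFactors = FALSE)
  }))
  list(truth = truth, observed = observed, biomass = biomass, config = cfg)
}

#' Ground-truth event days of a simulated bottle
#'
#' Extracts, from noise-free truth trajectories, the transition events the
#' analysis pipeline is meant to recover: the day sulfate first falls below
#' 1 mM (and below the phase thresholds), the hydrogen-peak day, the
#' methane-peak day, the day of the d13C-CH4 minimum, and the onset of
#' sustained net methanogenesis (sulfate below `s_mg` with methane
#' non-decreasing thereafter).
#'
#' @param truth The `truth` data.frame from [simulate_microcosm()] (one or
#'   more bottles).
#' @param s_mc,s_mg Sulfate thresholds, mol/L (defaults 5e-3, 1e-4).
#' @return data.frame with one row per bottle: `bottle`,
#'   `t_sulfate_1mM`, `t_cross_s_mc`, `t_cross_s_mg`, `t_h2_peak`,
#'   `t_ch4_peak`, `t_d13c_min`, `t_net_mg`.
#' @export
sim_events <- function(truth, s_mc = 5e-3, s_mg = 1e-4) {
  stopifnot(all(c("bottle", "day", "sulfate", "hydrogen", "methane",
                  "d13c_ch4") %in% names(truth)))
  per_bottle <- function(tr) {
    tr <- tr[order(tr$day), , drop = FALSE]
    first_below <- function(x, thr) {
      i <- which(x < thr)[1]
      if (is.na(i)) NA_real_ else tr$day[i]
    }
    t_h2 <- tr$day[which.max(tr$hydrogen)]
    t_ch4 <- tr$day[which.max(tr$methane)]
    t_d13c <- if (all(is.na(tr$d13c_ch4))) NA_real_ else
      tr$day[which.min(tr$d13c_ch4)]
    # onset of sustained net methanogenesis: the post-peak methane
    # minimum, provided sulfate is depleted there
    t_net <- NA_real_
    i_pk <- which.max(tr$methane)
    if (i_pk < nrow(tr)) {
      post <- seq(i_pk, nrow(tr))
      i_low <- post[which.min(tr$methane[post])]
      if (i_low < nrow(tr) && tr$sulfate[i_low] <= s_mg &&
          tr$methane[nrow(tr)] > tr$methane[i_low]) {
        t_net <- tr$day[i_low]
      }
    }
    data.frame(t_sulfate_1mM = first_below(tr$sulfate, 1e-3),
               t_cross_s_mc = first_below(tr$sulfate, s_mc),
               t_cross_s_mg = first_below(tr$sulfate, s_mg),
               t_h2_peak = t_h2, t_ch4_peak = t_ch4, t_d13c_min = t_d13c,
               t_net_mg = t_net)
  }
  bottles <- unique(truth$bottle)
  out <- do.call(rbind, lapply(bottles, function(b) {
    cbind(data.frame(bottle = b, stringsAsFactors = FALSE),
          per_bottle(truth[truth$bottle == b, , drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}

#' Draw a synthetic amplicon table from simulated guild biomasses
#'
#' Converts true guild biomasses into expected relative abundances
#' (biomass-proportional: methanogens, SRB, and a background compartment),
#' blends the background across `n_background` ASVs with per-sample
#' Dirichlet weights, optionally adds small non-target contaminant ASVs
#' (chloroplast / eukaryote / domain-unassigned) so the full QC path can
#' be exercised, and draws multinomial counts at the given depth.
#'
#' @param biomass The `biomass` data.frame from [simulate_microcosm()].
#' @param guilds Guild definitions used to assign member taxonomy strings.
#'   Default [default_guilds()].
#' @param depth Library size per sample (exact). Default 30000.
#' @param n_background Number of background ASVs. Default 40.
#' @param background_alpha Dirichlet concentration for background weights.
#'   Default 5.
#' @param asvs_per_guild Member ASVs per guild. Default 4.
#' @param nontarget_fraction Expected total fraction of non-target reads
#'   (0 disables). Default 0.005.
#' @param seed Integer seed.
#' @return An [asv_table()] with sample metadata (`day`, `bottle`) and an
#'   attribute `expected_fractions` (data.frame of the true per-sample
#'   guild fractions the counts were drawn from).
#' @export
sample_amplicons <- function(biomass, guilds = default_guilds(),
                             depth = 30000, n_background = 40,
                             background_alpha = 5, asvs_per_guild = 4,
                             nontarget_fraction = 0.005, seed = 1) {
  stopifnot(all(c("bottle", "day", "b_srb", "b_mca", "b_other") %in%
                  names(biomass)), depth > 0)
  set.seed(seed)
  guild_lineages <- list(
    methane_cycling_archaea = c(
      "d__Archaea; p__Halobacterota; c__Methanomicrobia; o__Methanomicrobiales; f__Methanoregulaceae; g__Methanolinea",
      "d__Archaea; p__Halobacterota; c__Methanomicrobia; o__Methanosarcinales; f__Methanosaetaceae; g__Methanosaeta",
      "d__Archaea; p__Halobacterota; c__Methanomicrobia; o__Methanosarcinales; f__Methanosarcinaceae; g__ANME-3",
      "d__Archaea; p__Halobacterota; c__Methanomicrobia; o__Methanomicrobiales; f__Methanomicrobiaceae"),
    srb = c(
      "d__Bacteria; p__Desulfobacterota; c__Desulfarculia; o__Desulfarculales; f__Desulfarculaceae; g__Desulfatiglans",
      "d__Bacteria; p__Desulfobacterota; c__Desulfobacteria; o__Desulfobacterales; f__Desulfobacteraceae; g__Sva0081",
      "d__Bacteria; p__Desulfobacterota; c__Desulfobulbia; o__Desulfobulbales; f__Desulfobulbaceae",
      "d__Bacteria; p__Desulfobacterota; c__Syntrophobacteria; o__Syntrophobacterales; f__Syntrophobacteraceae"))
  stopifnot(all(names(guilds) %in% names(guild_lineages)))
  bg_phyla <- c("Proteobacteria", "Chloroflexi", "Bathyarchaeota",
                "Planctomycetota", "Acidobacteriota", "Lokiarchaeia")
  n_samples <- nrow(biomass)
  asv_ids <- character(0); lineages <- character(0)
  for (g in names(guilds)) {
    k <- min(asvs_per_guild, length(guild_lineages[[g]]))
    ids <- sprintf("%s_ASV%02d", g, seq_len(k))
    asv_ids <- c(asv_ids, ids)
    lineages <- c(lineages, guild_lineages[[g]][seq_len(k)])
  }
  bg_ids <- sprintf("bg_ASV%03d", seq_len(n_background))
  bg_lin <- sprintf("d__%s; p__%s; g__Background%03d",
                    ifelse(seq_len(n_background) %% 4 == 0, "Archaea",
                           "Bacteria"),
                    bg_phyla[(seq_len(n_background) - 1) %% length(bg_phyla) + 1],
                    seq_len(n_background))
  asv_ids <- c(asv_ids, bg_ids)
  lineages <- c(lineages, bg_lin)
  if (nontarget_fraction > 0) {
    asv_ids <- c(asv_ids, "nt_chloroplast", "nt_eukaryote", "nt_nodomain")
    lineages <- c(lineages,
                  "d__Bacteria; p__Cyanobacteria; o__Chloroplast",
                  "d__Eukaryota; p__Diatomea",
                  "Unassigned")
  }
  n_asv <- length(asv_ids)
  counts <- matrix(0L, nrow = n_samples, ncol = n_asv,
                   dimnames = list(sprintf("%s_d%04d", biomass$bottle,
                                           round(biomass$day)), asv_ids))
  guild_w <- 1 / seq_len(asvs_per_guild)   # within-guild ASV split
  expected <- data.frame(sample_id = rownames(counts),
                         day = biomass$day, bottle = biomass$bottle,
                         stringsAsFactors = FALSE)
  for (g in names(guilds)) expected[[g]] <- NA_real_
  for (i in seq_len(n_samples)) {
    tot <- biomass$b_srb[i] + biomass$b_mca[i] + biomass$b_other[i]
    f_guild <- c(methane_cycling_archaea = biomass$b_mca[i] / tot,
                 srb = biomass$b_srb[i] / tot)
    f_guild <- f_guild[names(guilds)]
    f_nt <- nontarget_fraction
    f_bg <- max(0, 1 - sum(f_guild) - f_nt)
    p <- numeric(n_asv)
    pos <- 1
    for (g in names(guilds)) {
      k <- min(asvs_per_guild, length(guild_lineages[[g]]))
      w <- guild_w[seq_len(k)] / sum(guild_w[seq_len(k)])
      p[pos:(pos + k - 1)] <- f_guild[[g]] * w
      pos <- pos + k
    }
    if (n_background > 0) {
      dirich <- stats::rgamma(n_background, shape = background_alpha)
      p[pos:(pos + n_background - 1)] <- f_bg * dirich / sum(dirich)
      pos <- pos + n_background
    }
    if (nontarget_fraction > 0) p[pos:(pos + 2)] <- f_nt / 3
    counts[i, ] <- as.integer(stats::rmultinom(1, size = depth, prob = p))
    for (g in names(guilds)) expected[[g]][i] <- f_guild[[g]]
  }
  tax <- data.frame(asv_id = asv_ids, lineage = lineages,
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = rownames(counts), day = biomass$day,
                     bottle = biomass$bottle,
                     experiment = "simulated_microcosm",
                     stringsAsFactors = FALSE)
  out <- asv_table(counts, tax, meta)
  attr(out, "expected_fractions") <- expected
  out
}
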