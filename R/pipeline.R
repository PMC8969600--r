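# One-call orchestration of the analysis stages into a report bundle.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a geochemistry file
#' (`geochem_path`, optionally with ASV count/taxonomy/metadata files) or
#' a simulation directive (`simulate`, a [sim_config()]).
#'
#' @param geochem_path Optional path to a geochemistry CSV
#'   (see [read_geochem()]).
#' @param geometry [incubation_geometry()] used when reading files.
#' @param asv_counts,asv_taxonomy,asv_metadata Optional ASV TSV paths
#'   (see [read_asv_table()]).
#' @param simulate Optional [sim_config()]; when given, inputs are
#'   simulated instead of read.
#' @param co2_aq Fixed aqueous CO2 for the free-energy stage, mol/L.
#' @param const [thermo_constants()].
#' @param dead_band Near-equilibrium half-width, kJ/mol.
#' @param rules [phase_rules()].
#' @param guilds Guild definitions (see [default_guilds()]).
#' @param plateau List: `analyte`, `cv_max`, `min_n` for
#'   [detect_plateaus()].
#' @param rate_windows Optional data.frame (`analyte`, `t0`, `t1`) of
#'   regression windows; when `NULL`, methane and hydrogen slopes are
#'   fit over each detected phase segment.
#' @param iso List of isotope end-members: `delta_seed`, `delta_bio`.
#' @param min_reads,scale_depth Amplicon QC parameters.
#' @param out_dir Output directory for the CSV bundle (created); `NULL`
#'   suppresses file output.
#' @param seed Root seed (simulation and any resampling derive from it).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geochem_path = NULL,
                            geometry = incubation_geometry(0.040, 0.020, 0.8),
                            asv_counts = NULL, asv_taxonomy = NULL,
                            asv_metadata = NULL, simulate = NULL,
                            co2_aq = 0.01, const = thermo_constants(),
                            dead_band = 0, rules = phase_rules(),
                            guilds = default_guilds(),
                            plateau = list(analyte = "hydrogen",
                                           cv_max = 0.25, min_n = 3),
                            rate_windows = NULL,
                            iso = list(delta_seed = -34.9, delta_bio = -80),
                            min_reads = 20000, scale_depth = 20000,
                            out_dir = NULL, seed = 1) {
  if (is.null(geochem_path) == is.null(simulate)) {
    stop("exactly one of geochem_path or simulate must be given")
  }
  structure(list(geochem_path = geochem_path, geometry = geometry,
                 asv_counts = asv_counts, asv_taxonomy = asv_taxonomy,
                 asv_metadata = asv_metadata, simulate = simulate,
                 co2_aq = co2_aq, const = const, dead_band = dead_band,
                 rules = rules, guilds = guilds, plateau = plateau,
                 rate_windows = rate_windows, iso = iso,
                 min_reads = min_reads, scale_depth = scale_depth,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Composes the stages: read or simulate the geochemistry; evaluate the
#' free-energy series; segment phases; fit rate regressions over the
#' configured (or phase-derived) windows; detect plateaus; summarise the
#' methane isotope mixture; and, when amplicon data are present, run QC,
#' normalisation, guild trajectories and the cross-bottle consistency
#' test. Outputs are returned as a list and, when `out_dir` is set,
#' written as CSV/TSV tables plus a run log carrying the configuration
#' hash and seed. Identical configuration and seed give identical
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_bundle` with elements `series`,
#'   `energy`, `phases`, `rates`, `plateaus`, `isotope_summary`,
#'   `community` (or `NULL`), `truth` (simulation only), `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- c(sprintf("config_hash: %s", .config_hash(cfg)),
                 sprintf("seed: %d", cfg$seed))
  truth <- NULL
  asv <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    sim_cfg$seed <- cfg$seed
    sim <- stage("simulate", simulate_microcosm(sim_cfg))
    series <- sim$observed
    truth <- sim$truth
    asv <- stage("simulate_amplicons",
                 sample_amplicons(sim$biomass, guilds = cfg$guilds,
                                  seed = cfg$seed + 1))
    log_lines <- c(log_lines, "input: simulated")
  } else {
    got <- stage("read_geochem",
                 read_geochem(cfg$geochem_path, cfg$geometry))
    series <- got$series
    log_lines <- c(log_lines,
                   sprintf("input: %s (%d records read, %d kept)",
                           cfg$geochem_path, got$qc$read, got$qc$kept))
    if (!is.null(cfg$asv_counts)) {
      asv <- stage("read_asv_table",
                   read_asv_table(cfg$asv_counts, cfg$asv_taxonomy,
                                  cfg$asv_metadata))
    }
  }

  energy <- stage("energy",
                  energy_series(series, co2_aq = cfg$co2_aq,
                                const = cfg$const,
                                dead_band = cfg$dead_band))
  phases <- stage("phases", segment_phases(series, energy, cfg$rules))

  windows <- cfg$rate_windows
  if (is.null(windows)) {
    windows <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i) {
      data.frame(analyte = c("methane", "hydrogen"),
                 t0 = phases$t_start[i], t1 = phases$t_end[i],
                 phase = phases$phase[i], stringsAsFactors = FALSE)
    }))
  } else if (!"phase" %in% names(windows)) {
    windows$phase <- NA_character_
  }
  rates <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    est <- tryCatch(window_rate(series, windows$analyte[i], windows$t0[i],
                                windows$t1[i]),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(analyte = est$analyte, t0 = windows$t0[i], t1 = windows$t1[i],
               phase = windows$phase[i], slope_per_day = est$slope,
               intercept = est$intercept, r2 = est$r2, n = est$n,
               stringsAsFactors = FALSE)
  }))

  plateaus <- stage("plateaus",
                    detect_plateaus(series, cfg$plateau$analyte,
                                    cv_max = cfg$plateau$cv_max,
                                    min_n = cfg$plateau$min_n))

  iso_summary <- stage("isotopes", {
    dm <- .daily_means(series, "d13c_ch4")
    if (nrow(dm) == 0) NULL else {
      bf <- biogenic_fraction(dm$mean, cfg$iso$delta_seed, cfg$iso$delta_bio)
      data.frame(day = dm$day, mean_d13c = dm$mean,
                 biogenic_fraction = as.numeric(bf),
                 out_of_range = attr(bf, "out_of_range"))
    }
  })

  community <- NULL
  if (!is.null(asv)) {
    community <- stage("community", {
      qc <- qc_filter(asv, min_reads = cfg$min_reads)
      tab <- remove_nontarget(qc$table)
      tab <- scale_even_depth(tab, depth = cfg$scale_depth,
                              mode = "proportional")
      trajectories <- lapply(cfg$guilds, function(g)
        guild_trajectory(tab, g))
      consistency <- NULL
      if (all(c("methane_cycling", "net_methanogenesis") %in% phases$phase)) {
        base_w <- unlist(phases[phases$phase == "methane_cycling",
                                c("t_start", "t_end")])
        test_w <- unlist(phases[phases$phase == "net_methanogenesis",
                                c("t_start", "t_end")])
        consistency <- lapply(trajectories, function(tr) {
          tryCatch(consistent_increase(tr, base_w, test_w),
                   error = function(e) NULL)
        })
      }
      list(qc = qc$qc, table = tab, trajectories = trajectories,
           consistency = consistency)
    })
  } else {
    log_lines <- c(log_lines, "community: skipped (no ASV input)")
  }

  bundle <- structure(
    list(series = series, energy = energy, phases = phases, rates = rates,
         plateaus = plateaus, isotope_summary = iso_summary,
         community = community, truth = truth, log = log_lines),
    class = "pipeline_bundle")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(cfg$out_dir, f), row.names = FALSE)
    write_geochem(series, file.path(cfg$out_dir, "geochem.csv"))
    wcsv(energy, "energy.csv")
    wcsv(as.data.frame(phases), "phases.csv")
    wcsv(rates, "rates.csv")
    wcsv(plateaus, "plateaus.csv")
    wcsv(iso_summary, "isotopes.csv")
    if (!is.null(truth)) wcsv(truth, "truth.csv")
    if (!is.null(community)) {
      traj <- do.call(rbind, lapply(names(community$trajectories), function(g)
        cbind(guild = g, community$trajectories[[g]])))
      wcsv(traj, "guild_trajectories.csv")
      if (!is.null(community$consistency)) {
        cons <- do.call(rbind, lapply(names(community$consistency),
                                      function(g) {
          ci <- community$consistency[[g]]
          if (is.null(ci)) return(NULL)
          data.frame(guild = g, fraction_increased = ci$fraction_increased,
                     p_value = ci$p_value, n_bottles = ci$n_bottles)
        }))
        wcsv(cons, "guild_consistency.csv")
      }
    }
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline bundle\n")
  print(x$series)
  cat(sprintf("  energy: %d records; phases: %d segments; rates: %d fits\n",
              nrow(x$energy), nrow(x$phases),
              if (is.null(x$rates)) 0L else nrow(x$rates)))
  invisible(x)
}
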