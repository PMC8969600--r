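# Shared fixture builders and independent brute-force oracles.

test_geometry <- function(temperature = 294.15) {
  incubation_geometry(0.040, 0.020, porosity = 0.8,
                      temperature = temperature)
}

# Small geochem series built directly from vectors (canonical mol/L units).
make_series <- function(day, sulfate = NA_real_, methane = NA_real_,
                        hydrogen = NA_real_, d13c = NA_real_,
                        bottle = "B1", replicate = 1L,
                        geometry = test_geometry()) {
  n <- length(day)
  geochem_series(data.frame(day = day,
                            bottle = rep_len(bottle, n),
                            replicate = rep_len(replicate, n),
                            sulfate = rep_len(sulfate, n),
                            methane = rep_len(methane, n),
                            hydrogen = rep_len(hydrogen, n),
                            d13c_ch4 = rep_len(d13c, n),
                            cells = rep_len(NA_real_, n)),
                 geometry, "fixture")
}

# Random geochem records for round-trip property tests.
random_records <- function(n) {
  data.frame(day = sort(round(runif(n, 0, 600), 2)),
             bottle = sample(c("A", "B"), n, replace = TRUE),
             replicate = sample(1:3, n, replace = TRUE),
             sulfate = ifelse(runif(n) < 0.1, NA, runif(n, 0, 1.2e-2)),
             methane = ifelse(runif(n) < 0.1, NA, runif(n, 0, 5e-3)),
             hydrogen = ifelse(runif(n) < 0.1, NA, runif(n, 0, 1e-8)),
             d13c_ch4 = ifelse(runif(n) < 0.3, NA, runif(n, -90, -20)),
             cells = ifelse(runif(n) < 0.5, NA, runif(n, 1e7, 1e9)))
}

# Random toy amplicon table with a mix of target and non-target lineages.
random_asv_table <- function(n_samples = 6, n_asvs = 15, max_count = 4000) {
  counts <- matrix(rpois(n_samples * n_asvs, lambda = runif(n_asvs, 1, max_count)),
                   nrow = n_samples,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("ASV%03d", seq_len(n_asvs))))
  lineages <- sample(c(
    "d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; g__Pseudomonas",
    "d__Bacteria; p__Desulfobacterota; f__Desulfobacteraceae; g__Sva0081",
    "d__Archaea; p__Halobacterota; c__Methanomicrobia; g__Methanolinea",
    "d__Bacteria; p__Cyanobacteria; o__Chloroplast",
    "d__Eukaryota; p__Diatomea",
    "Unassigned",
    "d__Bacteria; p__Chloroflexi"), n_asvs, replace = TRUE)
  tax <- data.frame(asv_id = colnames(counts), lineage = lineages,
                    stringsAsFactors = FALSE)
  asv_table(counts, tax,
            data.frame(sample_id = rownames(counts),
                       day = seq_len(n_samples) * 30,
                       bottle = rep_len(c("B1", "B2", "B3"), n_samples)))
}

# Independent brute-force amplicon QC: loops, no vectorised tricks.
bf_qc_filter <- function(counts, min_reads, min_prevalence) {
  keep_s <- character()
  for (s in rownames(counts)) {
    if (sum(counts[s, ]) >= min_reads) keep_s <- c(keep_s, s)
  }
  keep_a <- character()
  for (a in colnames(counts)) {
    pres <- 0
    for (s in keep_s) if (counts[s, a] > 0) pres <- pres + 1
    if (pres >= min_prevalence) keep_a <- c(keep_a, a)
  }
  list(samples = keep_s, asvs = keep_a)
}

bf_nontarget <- function(taxonomy) {
  drop <- character()
  for (i in seq_len(nrow(taxonomy))) {
    lin <- taxonomy$lineage[i]
    no_domain <- !grepl("d__[A-Za-z]", lin)
    if (grepl("chloroplast", lin, ignore.case = TRUE) ||
        grepl("d__Eukary", lin) || no_domain) {
      drop <- c(drop, taxonomy$asv_id[i])
    }
  }
  drop
}

# Closed-form simple linear regression (the OLS oracle).
ols_closed_form <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  se_slope <- sqrt(ss_res / (length(x) - 2) / sum((x - mx)^2))
  list(slope = slope, intercept = intercept,
       r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
       se_slope = se_slope)
}

# A fast small simulator configuration for tests that only need dynamics,
# not the full 586-day default scenario.
fast_sim_config <- function(...) {
  sim_config(horizon = 120, sampling_days = seq(0, 120, by = 20),
             n_bottles = 2, ...)
}

# colnames/rownames of an empty matrix may be NULL; normalise for comparison
nz <- function(x) if (is.null(x)) character(0) else x
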