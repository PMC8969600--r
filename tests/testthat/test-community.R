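test_that("sample-size filter runs before the prevalence filter", {
  counts <- rbind(S1 = c(25000, 0, 5), S2 = c(21000, 10, 0),
                  S3 = c(19000, 10, 10), S4 = c(29990, 0, 10))
  colnames(counts) <- c("A1", "A2", "A3")
  tax <- data.frame(asv_id = colnames(counts),
                    lineage = rep("d__Bacteria; p__Chloroflexi", 3))
  tab <- asv_table(counts, tax)
  got <- qc_filter(tab, min_reads = 20000, min_prevalence = 3)
  expect_equal(got$qc$samples_kept, 3)
  # A2 appears in 2 of the 3 kept samples (S3 dropped) -> out;
  # A3 appears in S2? no; S1 yes, S4 yes -> 2 kept samples -> out; A1 in 3
  expect_identical(colnames(got$table$counts), "A1")
})

test_that("prevalence boundary keeps exactly-three-sample ASVs", {
  counts <- matrix(20000, nrow = 4, ncol = 1,
                   dimnames = list(paste0("S", 1:4), "base"))
  counts <- cbind(counts, in2 = c(5, 5, 0, 0), in3 = c(5, 5, 5, 0))
  tax <- data.frame(asv_id = colnames(counts),
                    lineage = rep("d__Bacteria", 3))
  got <- qc_filter(asv_table(counts, tax))
  expect_true("in3" %in% colnames(got$table$counts))
  expect_false("in2" %in% colnames(got$table$counts))
})

test_that("QC filter equals a brute-force reimplementation on random tables", {
  set.seed(14)
  for (i in 1:30) {
    tab <- random_asv_table(n_samples = sample(4:8, 1),
                            n_asvs = sample(6:20, 1))
    min_reads <- sample(c(2000, 5000, 10000), 1)
    got <- suppressWarnings(qc_filter(tab, min_reads = min_reads, min_prevalence = 3))
    bf <- bf_qc_filter(tab$counts, min_reads, 3)
    expect_identical(nz(rownames(got$table$counts)), bf$samples)
    expect_identical(nz(colnames(got$table$counts)), bf$asvs)
  }
})

test_that("QC filter is idempotent", {
  set.seed(15)
  tab <- random_asv_table()
  once <- qc_filter(tab, min_reads = 3000)$table
  twice <- qc_filter(once, min_reads = 3000)$table
  expect_identical(twice$counts, once$counts)
})

test_that("chloroplast, eukaryote and domain-unassigned ASVs are removed", {
  counts <- matrix(10, nrow = 2, ncol = 4,
                   dimnames = list(c("S1", "S2"), paste0("A", 1:4)))
  tax <- data.frame(asv_id = paste0("A", 1:4), lineage = c(
    "d__Bacteria; p__Cyanobacteria; o__Chloroplast",
    "d__Eukaryota; p__Diatomea",
    "Unassigned",
    "d__Bacteria; p__Proteobacteria"))
  out <- remove_nontarget(asv_table(counts, tax))
  expect_identical(colnames(out$counts), "A4")
  expect_equal(attr(out, "n_removed"), 3)
})

test_that("non-target removal matches hand enumeration on a mixed fixture", {
  set.seed(16)
  for (i in 1:20) {
    tab <- random_asv_table(n_asvs = 10)
    out <- remove_nontarget(tab)
    keep_hand <- setdiff(tab$taxonomy$asv_id, bf_nontarget(tab$taxonomy))
    expect_setequal(colnames(out$counts), keep_hand)
  }
})

test_that("proportional scaling normalises every library to the target depth", {
  counts <- matrix(c(20000, 20000, 30000, 10000), nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("A1", "A2")))
  tab <- asv_table(counts, data.frame(asv_id = c("A1", "A2"),
                                      lineage = rep("d__Bacteria", 2)))
  sc <- scale_even_depth(tab, depth = 20000, mode = "proportional")
  expect_equal(unname(sc$counts["S1", ]), c(10000, 10000))
  expect_equal(unname(rowSums(sc$counts)), c(20000, 20000), tolerance = 1e-6)
})

test_that("rarefaction is exact-depth and reproducible for a fixed seed", {
  set.seed(17)
  tab <- random_asv_table(n_samples = 4, n_asvs = 8, max_count = 3000)
  depth <- min(rowSums(tab$counts))
  r1 <- scale_even_depth(tab, depth = depth, mode = "rarefy", seed = 99)
  r2 <- scale_even_depth(tab, depth = depth, mode = "rarefy", seed = 99)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == depth))
  expect_error(scale_even_depth(tab, depth = 1e7, mode = "rarefy"),
               "library")
})

test_that("agglomeration sums shared lineages and conserves totals", {
  counts <- matrix(c(3, 5, 2, 1), nrow = 1,
                   dimnames = list("S1", paste0("A", 1:4)))
  tax <- data.frame(asv_id = paste0("A", 1:4), lineage = c(
    "d__Bacteria; p__Desulfobacterota; g__Desulfatiglans",
    "d__Bacteria; p__Desulfobacterota; g__Desulfatiglans",
    "d__Bacteria; p__Desulfobacterota",
    "d__Archaea; p__Halobacterota; g__Methanolinea"))
  ag <- agglomerate_rank(asv_table(counts, tax), "genus")
  expect_equal(sum(ag$counts), sum(counts))
  key <- "Bacteria;Desulfobacterota;Desulfatiglans"
  expect_equal(unname(ag$counts[1, key]), 8)
  expect_true("unclassified_Desulfobacterota" %in% colnames(ag$counts))
})

test_that("agglomeration equals a brute-force group-by on random fixtures", {
  set.seed(18)
  for (i in 1:15) {
    tab <- random_asv_table(n_asvs = 20)
    for (rank in c("phylum", "genus")) {
      ag <- agglomerate_rank(tab, rank)
      expect_equal(sum(ag$counts), sum(tab$counts))
      # brute force: group columns by parsed lineage prefix
      upto <- seq_len(match(rank, c("domain", "phylum", "class", "order",
                                    "family", "genus", "species")))
      keys <- vapply(tab$taxonomy$lineage, function(l) {
        v <- cryptomethane:::.parse_lineage(l)[upto]
        if (!is.na(v[length(v)])) paste(v[!is.na(v)], collapse = ";")
        else {
          p <- v[!is.na(v)]
          paste0("unclassified_", if (length(p)) p[length(p)] else "root")
        }
      }, character(1))
      for (k in unique(keys)) {
        expect_equal(unname(ag$counts[, k]),
                     unname(rowSums(tab$counts[, keys == k, drop = FALSE])),
                     label = k)
      }
    }
  }
})

test_that("guild trajectories are library-relative fractions", {
  set.seed(19)
  tab <- random_asv_table(n_samples = 5, n_asvs = 12)
  all_ranks <- guild_definition("everything", data.frame(
    rank = "domain", taxon = c("Bacteria", "Archaea", "Eukaryota")))
  tr <- guild_trajectory(tab, all_ranks)
  unassigned <- grepl("Unassigned", tab$taxonomy$lineage)
  if (!any(unassigned)) expect_true(all(abs(tr$abundance - 1) < 1e-12))
  expect_true(all(tr$abundance >= 0 & tr$abundance <= 1))

  empty <- guild_definition("none", data.frame(rank = "genus",
                                               taxon = "Nosuchtaxon"))
  expect_warning(tr0 <- guild_trajectory(tab, empty), "matches no")
  expect_true(all(tr0$abundance == 0))
})

test_that("a constructed 0.2% methanogen community reads back as 0.002", {
  counts <- matrix(c(40, 19960), nrow = 1,
                   dimnames = list("S1", c("mg1", "bg1")))
  tax <- data.frame(asv_id = c("mg1", "bg1"), lineage = c(
    "d__Archaea; p__Halobacterota; g__Methanolinea",
    "d__Bacteria; p__Chloroflexi"))
  tr <- guild_trajectory(asv_table(counts, tax),
                         default_guilds()$methane_cycling_archaea)
  expect_equal(tr$abundance, 0.002)
})

test_that("guild fractions from the sampler sum to at most one per sample", {
  sim <- simulate_microcosm(fast_sim_config(seed = 2))
  asv <- sample_amplicons(sim$biomass, seed = 3)
  gl <- default_guilds()
  fr <- Reduce(`+`, lapply(gl, function(g) guild_trajectory(asv, g)$abundance))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("cross-bottle consistency uses a two-sided exact sign test", {
  traj <- data.frame(
    day = rep(c(10, 20, 110, 120), 3),
    bottle = rep(c("B1", "B2", "B3"), each = 4),
    abundance = c(0.01, 0.01, 0.02, 0.02,
                  0.01, 0.01, 0.03, 0.03,
                  0.02, 0.02, 0.04, 0.04))
  ci <- consistent_increase(traj, c(0, 30), c(100, 130))
  expect_equal(ci$fraction_increased, 1)
  expect_equal(ci$p_value, 0.25)   # two-sided exact, n = 3
  # all decreasing
  traj$abundance <- rev(traj$abundance)
  ci2 <- consistent_increase(traj, c(0, 30), c(100, 130))
  expect_equal(ci2$fraction_increased, 0)
  # a bottle with no data in the test window is excluded and reported
  traj3 <- traj[!(traj$bottle == "B3" & traj$day > 100), ]
  ci3 <- consistent_increase(traj3, c(0, 30), c(100, 130))
  expect_identical(ci3$excluded, "B3")
  expect_equal(ci3$n_bottles, 2)
})

test_that("pathway sums aggregate gene RPKM and report unmapped genes", {
  rpkm <- matrix(c(1, 2, 4, 8, 16, 32), nrow = 3,
                 dimnames = list(c("mcrA", "mcrB", "dsrA"), c("T1", "T2")))
  map <- data.frame(gene = c("mcrA", "mcrB", "dsrA", "aprA"),
                    pathway = c("methanogenesis", "methanogenesis",
                                "sulfate_reduction", "sulfate_reduction"))
  ps <- pathway_rpkm_sums(rpkm, map)
  expect_equal(ps["methanogenesis", ], c(T1 = 3, T2 = 24))
  expect_equal(ps["sulfate_reduction", ], c(T1 = 4, T2 = 32))
  expect_equal(attr(ps, "n_unmapped"), 0)
  # identity when each gene is its own pathway
  map1 <- data.frame(gene = rownames(rpkm), pathway = rownames(rpkm))
  expect_equal(pathway_rpkm_sums(rpkm, map1), rpkm, ignore_attr = TRUE)
  # brute force on a random fixture
  set.seed(20)
  g <- matrix(runif(40), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  m <- data.frame(gene = paste0("g", 1:6),
                  pathway = sample(c("p1", "p2"), 6, replace = TRUE))
  ps2 <- pathway_rpkm_sums(g, m)
  for (pw in unique(m$pathway)) {
    expect_equal(ps2[pw, ],
                 colSums(g[m$gene[m$pathway == pw], , drop = FALSE]))
  }
  expect_equal(attr(ps2, "n_unmapped"), 2)
  expect_warning(pathway_rpkm_sums(g, m[0, ]), "empty")
})

test_that("ASV tables round-trip through TSV files", {
  set.seed(22)
  tab <- random_asv_table(n_samples = 4, n_asvs = 8)
  fc <- withr::local_tempfile(fileext = ".tsv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(tab, fc, ft, fm)
  back <- read_asv_table(fc, ft, fm)
  expect_equal(back$counts, tab$counts)
  expect_identical(back$taxonomy$lineage, tab$taxonomy$lineage)
  expect_equal(back$metadata$day, tab$metadata$day)
})
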