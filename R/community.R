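# 16S amplicon table container, quality-control and normalisation rules,
# taxonomic agglomeration, guild trajectories, and transcript pathway sums.

.LINEAGE_RANKS <- c(d = "domain", p = "phylum", c = "class", o = "order",
                    f = "family", g = "genus", s = "species")

#' ASV count table with taxonomy and sample metadata
#'
#' @param counts Integer matrix, samples in rows, ASVs in columns, with
#'   dimnames. Counts must be non-negative integers.
#' @param taxonomy data.frame with columns `asv_id` and `lineage`; the
#'   lineage is a `d__...; p__...; ...; g__...` prefixed string. Every ASV
#'   in `counts` must have an entry (possibly with an empty lineage).
#' @param metadata Optional data.frame with a `sample_id` column matching
#'   the count rows plus any sample covariates (`day`, `bottle`, ...).
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy, metadata = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have sample names")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) stop("counts must have ASV names")
    colnames(counts) <- character(0)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(is.data.frame(taxonomy),
            all(c("asv_id", "lineage") %in% names(taxonomy)))
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax)) {
    stop("ASVs without taxonomy entry: ", paste(utils::head(missing_tax, 5),
                                                collapse = ", "))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
    metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d samples x %d ASVs (total %.4g reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# Parse "d__Bacteria; p__Proteobacteria; ..." into a named rank vector.
.parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  out <- stats::setNames(rep(NA_character_, length(.LINEAGE_RANKS)),
                         unname(.LINEAGE_RANKS))
  for (p in parts) {
    m <- regmatches(p, regexec("^([dpcofgs])__(.*)$", p))[[1]]
    if (length(m) == 3 && nzchar(m[3])) out[[.LINEAGE_RANKS[[m[2]]]]] <- m[3]
  }
  out
}

.lineage_matrix <- function(taxonomy) {
  m <- t(vapply(taxonomy$lineage, .parse_lineage,
                character(length(.LINEAGE_RANKS)), USE.NAMES = FALSE))
  colnames(m) <- unname(.LINEAGE_RANKS)
  m
}

#' Sample-size and prevalence quality filter
#'
#' Drops samples whose library size is below `min_reads` first, then drops
#' ASVs present (count > 0) in fewer than `min_prevalence` of the samples
#' that remain. The order matters and is fixed: the prevalence filter sees
#' only the surviving samples.
#'
#' @param table An [asv_table()].
#' @param min_reads Minimum library size. Default 20000.
#' @param min_prevalence Minimum number of samples an ASV must appear in.
#'   Default 3.
#' @return A list with `table` (filtered [asv_table()]) and `qc` (counts
#'   of samples and ASVs read/kept/dropped).
#' @export
qc_filter <- function(table, min_reads = 20000, min_prevalence = 3) {
  stopifnot(inherits(table, "asv_table"))
  libsize <- rowSums(table$counts)
  keep_s <- libsize >= min_reads
  counts <- table$counts[keep_s, , drop = FALSE]
  prevalence <- colSums(counts > 0)
  keep_a <- prevalence >= min_prevalence
  counts <- counts[, keep_a, drop = FALSE]
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    warning("qc_filter removed everything")
  }
  out <- asv_table(counts,
                   table$taxonomy[table$taxonomy$asv_id %in% colnames(counts), ,
                                  drop = FALSE],
                   if (is.null(table$metadata)) NULL else
                     table$metadata[keep_s, , drop = FALSE])
  qc <- list(samples_read = nrow(table$counts), samples_kept = sum(keep_s),
             samples_dropped = sum(!keep_s),
             asvs_read = ncol(table$counts), asvs_kept = sum(keep_a),
             asvs_dropped = sum(!keep_a),
             min_reads = min_reads, min_prevalence = min_prevalence)
  list(table = out, qc = qc)
}

#' Remove non-target lineages
#'
#' Removes ASVs classified as chloroplast or Eukaryota, and ASVs that
#' failed to classify at the domain level.
#'
#' @param table An [asv_table()].
#' @return A filtered [asv_table()] with attribute `n_removed`.
#' @export
remove_nontarget <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  lm <- .lineage_matrix(table$taxonomy)
  is_chloro <- grepl("chloroplast", table$taxonomy$lineage, ignore.case = TRUE)
  is_euk <- !is.na(lm[, "domain"]) &
    grepl("^eukary", lm[, "domain"], ignore.case = TRUE)
  no_domain <- is.na(lm[, "domain"])
  drop <- is_chloro | is_euk | no_domain
  counts <- table$counts[, !drop, drop = FALSE]
  out <- asv_table(counts,
                   table$taxonomy[!drop, , drop = FALSE],
                   table$metadata)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Scale libraries to even depth
#'
#' Either rescales every sample's counts proportionally so that each row
#' sums to `depth` (non-integer values allowed), or rarefies by sampling
#' `depth` reads without replacement (requires every library to hold at
#' least `depth` reads; reproducible for a fixed seed).
#'
#' @param table An [asv_table()].
#' @param depth Target depth. Default 20000.
#' @param mode `"proportional"` (default) or `"rarefy"`.
#' @param seed Integer seed used in rarefy mode.
#' @return An [asv_table()]-shaped list whose `counts` row sums equal
#'   `depth` (to 1e-6 in proportional mode, exactly in rarefy mode).
#' @export
scale_even_depth <- function(table, depth = 20000,
                             mode = c("proportional", "rarefy"), seed = 1) {
  stopifnot(inherits(table, "asv_table"))
  mode <- match.arg(mode)
  libsize <- rowSums(table$counts)
  if (any(libsize == 0)) stop("cannot scale a sample with zero reads")
  if (mode == "proportional") {
    counts <- sweep(table$counts, 1, depth / libsize, "*")
    out <- table
    out$counts <- counts
    return(out)
  }
  if (any(libsize < depth)) {
    stop("rarefy requires every library size >= depth")
  }
  counts <- table$counts
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(nrow(counts))) {
    pool <- rep.int(seq_len(ncol(counts)), counts[i, ])
    draw <- sample(pool, depth, replace = FALSE)
    counts[i, ] <- tabulate(draw, nbins = ncol(counts))
  }
  out <- table
  out$counts <- counts
  out
}

#' Agglomerate ASVs at a taxonomic rank
#'
#' Sums the counts of all ASVs sharing the same lineage down to `rank`.
#' ASVs unassigned at that rank are grouped under
#' `"unclassified_<deepest assigned parent>"`.
#'
#' @param table An [asv_table()].
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return An [asv_table()] keyed by taxon at `rank`; total counts are
#'   conserved.
#' @export
agglomerate_rank <- function(table, rank) {
  stopifnot(inherits(table, "asv_table"))
  rank <- match.arg(rank, unname(.LINEAGE_RANKS))
  lm <- .lineage_matrix(table$taxonomy)
  upto <- seq_len(match(rank, unname(.LINEAGE_RANKS)))
  keys <- apply(lm[, upto, drop = FALSE], 1, function(v) {
    if (!is.na(v[length(v)])) {
      paste(v[!is.na(v)], collapse = ";")
    } else {
      assigned <- v[!is.na(v)]
      parent <- if (length(assigned)) assigned[length(assigned)] else "root"
      paste0("unclassified_", parent)
    }
  })
  groups <- unique(keys)
  counts <- matrix(0, nrow = nrow(table$counts), ncol = length(groups),
                   dimnames = list(rownames(table$counts), groups))
  for (g in groups) {
    counts[, g] <- rowSums(table$counts[, keys == g, drop = FALSE])
  }
  # representative lineage per group, truncated at rank
  prefix_codes <- names(.LINEAGE_RANKS)[upto]
  lineages <- vapply(groups, function(g) {
    i <- which(keys == g)[1]
    v <- lm[i, upto]
    paste(paste0(prefix_codes[!is.na(v)], "__", v[!is.na(v)]), collapse = "; ")
  }, character(1))
  tax <- data.frame(asv_id = groups, lineage = lineages,
                    stringsAsFactors = FALSE)
  asv_table(counts, tax, table$metadata)
}

#' Define a microbial guild by taxonomy patterns
#'
#' A guild is a named set of (rank, taxon) patterns; an ASV belongs to the
#' guild when its lineage carries any listed taxon at the stated rank.
#'
#' @param name Guild label.
#' @param patterns data.frame with columns `rank` (lineage rank name) and
#'   `taxon` (exact taxon string at that rank).
#' @return An object of class `guild_definition`.
#' @examples
#' guild_definition("srb", data.frame(rank = "family",
#'                                    taxon = "Desulfobacteraceae"))
#' @export
guild_definition <- function(name, patterns) {
  stopifnot(is.character(name), is.data.frame(patterns),
            all(c("rank", "taxon") %in% names(patterns)),
            nrow(patterns) > 0)
  if (!all(patterns$rank %in% unname(.LINEAGE_RANKS))) {
    stop("pattern ranks must be lineage ranks")
  }
  structure(list(name = name, patterns = patterns),
            class = "guild_definition")
}

#' Default guild definitions for the sediment microcosm
#'
#' Two guilds: `methane_cycling_archaea` (Methanomicrobia genera observed
#' to rise during the transition to methanogenesis — Methanolinea,
#' Methanosaeta, ANME-3, Methanoregula, plus uncultured
#' Methanomicrobiaceae) and `srb` (families holding cultured sulfate
#' reducers — Desulfarculaceae incl. Desulfatiglans, Desulfobacteraceae
#' incl. Sva0081 and SEEP-SRB1, Desulfobulbaceae, Syntrophobacteraceae).
#'
#' @return Named list of [guild_definition()] objects.
#' @export
default_guilds <- function() {
  list(
    methane_cycling_archaea = guild_definition(
      "methane_cycling_archaea",
      data.frame(
        rank = c("genus", "genus", "genus", "genus", "family"),
        taxon = c("Methanolinea", "Methanosaeta", "ANME-3", "Methanoregula",
                  "Methanomicrobiaceae"),
        stringsAsFactors = FALSE)),
    srb = guild_definition(
      "srb",
      data.frame(
        rank = c("family", "family", "family", "family", "genus"),
        taxon = c("Desulfarculaceae", "Desulfobacteraceae",
                  "Desulfobulbaceae", "Syntrophobacteraceae",
                  "Desulfatiglans"),
        stringsAsFactors = FALSE))
  )
}

#' Read guild definitions from a YAML file
#'
#' The file is a mapping of guild name to a list of `{rank, taxon}`
#' entries.
#'
#' @param path YAML file path.
#' @return Named list of [guild_definition()] objects.
#' @export
read_guild_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    pat <- do.call(rbind, lapply(cfg[[nm]], function(e) {
      data.frame(rank = e$rank, taxon = e$taxon, stringsAsFactors = FALSE)
    }))
    guild_definition(nm, pat)
  })
  stats::setNames(out, names(cfg))
}

.guild_members <- function(table, guild) {
  lm <- .lineage_matrix(table$taxonomy)
  member <- rep(FALSE, nrow(table$taxonomy))
  for (i in seq_len(nrow(guild$patterns))) {
    rk <- guild$patterns$rank[i]
    tx <- guild$patterns$taxon[i]
    member <- member | (!is.na(lm[, rk]) & lm[, rk] == tx)
  }
  table$taxonomy$asv_id[member]
}

#' Guild relative-abundance trajectory
#'
#' Per-sample relative abundance of a guild: the summed counts of its
#' member ASVs divided by the sample's total library size, joined with
#' sample metadata when available.
#'
#' @param table An [asv_table()] (after QC).
#' @param guild A [guild_definition()].
#' @return data.frame with `sample_id`, `abundance` (fraction of total
#'   reads) and any metadata columns (`day`, `bottle`, ...).
#' @export
guild_trajectory <- function(table, guild) {
  stopifnot(inherits(table, "asv_table"), inherits(guild, "guild_definition"))
  members <- .guild_members(table, guild)
  if (length(members) == 0) {
    warning("guild '", guild$name, "' matches no ASVs")
  }
  libsize <- rowSums(table$counts)
  g <- if (length(members)) {
    rowSums(table$counts[, colnames(table$counts) %in% members, drop = FALSE])
  } else rep(0, nrow(table$counts))
  out <- data.frame(sample_id = rownames(table$counts),
                    abundance = as.numeric(g / libsize),
                    stringsAsFactors = FALSE)
  if (!is.null(table$metadata)) {
    out <- merge(out, table$metadata, by = "sample_id", sort = FALSE)
  }
  out
}

#' Cross-bottle consistency of a guild increase
#'
#' For each bottle, compares the mean guild abundance inside a test time
#' window against a baseline window; a bottle counts as increased only on
#' a strict increase (exact ties count as non-increase). Consistency
#' across bottles is summarised by the fraction increased and a two-sided
#' exact sign test.
#'
#' @param trajectory Output of [guild_trajectory()] with `day` and
#'   `bottle` columns.
#' @param baseline_window,test_window Numeric `c(t0, t1)` day windows
#'   (inclusive).
#' @return List with `fraction_increased`, `p_value`, `n_bottles`,
#'   `increased` (named logical per bottle), `excluded` (bottles lacking
#'   data in either window).
#' @export
consistent_increase <- function(trajectory, baseline_window, test_window) {
  stopifnot(all(c("day", "bottle", "abundance") %in% names(trajectory)),
            length(baseline_window) == 2, length(test_window) == 2)
  bottles <- unique(trajectory$bottle)
  if (length(bottles) < 2) stop("need at least 2 bottles")
  win_mean <- function(b, w) {
    v <- trajectory$abundance[trajectory$bottle == b &
                                trajectory$day >= w[1] &
                                trajectory$day <= w[2]]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  base <- vapply(bottles, win_mean, numeric(1), w = baseline_window)
  test <- vapply(bottles, win_mean, numeric(1), w = test_window)
  ok <- !is.na(base) & !is.na(test)
  excluded <- bottles[!ok]
  if (sum(ok) < 2) stop("fewer than 2 bottles with data in both windows")
  inc <- stats::setNames(test[ok] > base[ok], bottles[ok])
  p <- stats::binom.test(sum(inc), length(inc), p = 0.5,
                         alternative = "two.sided")$p.value
  list(fraction_increased = mean(inc), p_value = p, n_bottles = length(inc),
       increased = inc, excluded = excluded)
}

#' Sum transcript abundance over pathways
#'
#' Sums per-gene RPKM values within each pathway, per sample. Genes absent
#' from the map are ignored and counted.
#'
#' @param gene_rpkm Numeric matrix, genes in rows (named), samples in
#'   columns.
#' @param pathway_map data.frame with columns `gene` and `pathway`.
#' @return Matrix pathways x samples with attribute `n_unmapped` (genes in
#'   `gene_rpkm` missing from the map).
#' @export
pathway_rpkm_sums <- function(gene_rpkm, pathway_map) {
  stopifnot(is.matrix(gene_rpkm), !is.null(rownames(gene_rpkm)),
            is.data.frame(pathway_map),
            all(c("gene", "pathway") %in% names(pathway_map)))
  if (nrow(pathway_map) == 0) {
    warning("empty pathway map")
    out <- matrix(numeric(), nrow = 0, ncol = ncol(gene_rpkm),
                  dimnames = list(character(), colnames(gene_rpkm)))
    attr(out, "n_unmapped") <- nrow(gene_rpkm)
    return(out)
  }
  mapped <- pathway_map[pathway_map$gene %in% rownames(gene_rpkm), ,
                        drop = FALSE]
  n_unmapped <- length(setdiff(rownames(gene_rpkm), pathway_map$gene))
  pathways <- unique(mapped$pathway)
  out <- matrix(0, nrow = length(pathways), ncol = ncol(gene_rpkm),
                dimnames = list(pathways, colnames(gene_rpkm)))
  for (pw in pathways) {
    genes <- mapped$gene[mapped$pathway == pw]
    out[pw, ] <- colSums(gene_rpkm[rownames(gene_rpkm) %in% genes, ,
                                   drop = FALSE])
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write / read an ASV table as TSV
#'
#' Counts are written ASVs x samples (`asv_id` first column), taxonomy as
#' a two-column TSV (`asv_id`, `lineage`), metadata as TSV when present.
#'
#' @param table An [asv_table()].
#' @param counts_path,taxonomy_path,metadata_path Output paths
#'   (`metadata_path` optional).
#' @return Invisibly, the counts path.
#' @export
write_asv_table <- function(table, counts_path, taxonomy_path,
                            metadata_path = NULL) {
  stopifnot(inherits(table, "asv_table"))
  cts <- data.frame(asv_id = colnames(table$counts),
                    t(table$counts), check.names = FALSE)
  utils::write.table(cts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path) && !is.null(table$metadata)) {
    utils::write.table(table$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(counts_path, taxonomy_path, metadata_path = NULL) {
  cts <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$asv_id
  counts <- t(counts)
  tax <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- if (!is.null(metadata_path) && file.exists(metadata_path)) {
    utils::read.table(metadata_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  asv_table(counts, tax, meta)
}
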