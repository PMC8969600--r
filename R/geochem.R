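# Geochemical time-series container and delimited-text I/O.
#
# Canonical internal unit for all aqueous species is mol/L; mM/nM appear only
# at the file boundary. Missing measurements are NA, never zero.

.GEOCHEM_UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
.GEOCHEM_ANALYTES <- c("sulfate", "methane", "hydrogen")

#' Geochemical incubation series
#'
#' Per-bottle, per-day analyte measurements from a sealed microcosm
#' incubation. Aqueous species (sulfate, methane, hydrogen) are stored in
#' mol/L; methane stable carbon isotope composition in permil vs VPDB; cell
#' counts in cells/ml. Missing measurements are `NA`.
#'
#' @param records A data.frame with columns `day` (days since slurry
#'   sealing, numeric, non-negative), `bottle` (label), `replicate`
#'   (integer), `sulfate`, `methane`, `hydrogen` (mol/L), and optionally
#'   `d13c_ch4` (permil) and `cells` (cells/ml). Missing columns are added
#'   as `NA`.
#' @param geometry An [incubation_geometry()].
#' @param experiment_id Label for the experiment.
#'
#' @return An object of class `geochem_series`: a list with elements
#'   `records` (sorted by bottle then day), `geometry`, `experiment_id`.
#' @export
geochem_series <- function(records, geometry, experiment_id = "experiment") {
  stopifnot(is.data.frame(records), is_incubation_geometry(geometry))
  needed <- c("day", "bottle", "replicate", .GEOCHEM_ANALYTES, "d13c_ch4", "cells")
  for (col in setdiff(needed, names(records))) {
    if (col %in% c("day", "bottle", "replicate")) {
      stop("records is missing mandatory column: ", col)
    }
    records[[col]] <- NA_real_
  }
  records <- records[needed]
  records$day <- as.numeric(records$day)
  records$bottle <- as.character(records$bottle)
  records$replicate <- as.integer(records$replicate)
  for (col in c(.GEOCHEM_ANALYTES, "d13c_ch4", "cells")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (any(!is.finite(records$day))) stop("day must be finite")
  if (any(records$day < 0)) stop("day must be non-negative")
  for (a in .GEOCHEM_ANALYTES) {
    v <- records[[a]]
    if (any(!is.na(v) & v < 0)) stop("negative concentration in column ", a)
  }
  records <- records[order(records$bottle, records$day, records$replicate), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(records = records, geometry = geometry, experiment_id = experiment_id),
    class = "geochem_series"
  )
}

#' @export
print.geochem_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("Geochem series '%s': %d records, %d bottle(s), days %s-%s\n",
              x$experiment_id, nrow(r), length(unique(r$bottle)),
              if (nrow(r)) format(min(r$day)) else "-",
              if (nrow(r)) format(max(r$day)) else "-"))
  invisible(x)
}

qc_report <- function(read, dropped = integer(), units = character()) {
  dropped <- dropped[dropped > 0]
  kept <- read - sum(dropped)
  stopifnot(kept >= 0)
  structure(list(read = read, kept = kept, dropped = dropped, units = units),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d read, %d kept, %d dropped\n",
              x$read, x$kept, sum(x$dropped)))
  if (length(x$dropped)) {
    for (r in names(x$dropped)) cat(sprintf("  dropped %s: %d\n", r, x$dropped[[r]]))
  }
  invisible(x)
}

# Map a file column name like "hydrogen_nM" to (analyte, factor-to-mol/L).
.parse_analyte_column <- function(nm) {
  m <- regmatches(nm, regexec("^(sulfate|methane|hydrogen)_(M|mM|uM|nM)$", nm))[[1]]
  if (length(m) == 0) return(NULL)
  list(analyte = m[2], unit = m[3], factor = .GEOCHEM_UNIT_FACTORS[[m[3]]])
}

#' Read a geochemical time-series file
#'
#' Reads a delimited-text (CSV) geochemistry file with a header naming the
#' columns. Mandatory columns are `day`, `bottle`, `replicate`. Analyte
#' columns carry unit suffixes (`sulfate_mM`, `methane_mM`, `hydrogen_nM`,
#' ...; any of `_M`, `_mM`, `_uM`, `_nM` is accepted) and are converted to
#' the canonical internal unit mol/L. `d13c_ch4_permil` and `cells_per_ml`
#' are optional. Rows with a negative concentration or an unparseable day
#' are dropped and counted in the QC report; empty cells become `NA`.
#'
#' @param path Path to the file.
#' @param geometry An [incubation_geometry()].
#' @param experiment_id Label; defaults to the file name without extension.
#' @param sep Field separator, default ",".
#'
#' @return A list with elements `series` (a [geochem_series()]) and `qc`
#'   (a QC report with counts `read`, `kept`, `dropped`, and the detected
#'   units).
#' @seealso [write_geochem()]
#' @export
read_geochem <- function(path, geometry, experiment_id = NULL, sep = ",") {
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  for (col in c("day", "bottle", "replicate")) {
    if (!col %in% names(raw)) stop("missing mandatory column: ", col)
  }
  units <- character()
  out <- data.frame(day = suppressWarnings(as.numeric(raw$day)),
                    bottle = as.character(raw$bottle),
                    replicate = suppressWarnings(as.integer(raw$replicate)),
                    stringsAsFactors = FALSE)
  for (nm in names(raw)) {
    pc <- .parse_analyte_column(nm)
    if (!is.null(pc)) {
      out[[pc$analyte]] <- suppressWarnings(as.numeric(raw[[nm]])) * pc$factor
      units[[pc$analyte]] <- pc$unit
    }
  }
  if ("d13c_ch4_permil" %in% names(raw)) {
    out$d13c_ch4 <- suppressWarnings(as.numeric(raw$d13c_ch4_permil))
    units[["d13c_ch4"]] <- "permil"
  }
  if ("cells_per_ml" %in% names(raw)) {
    out$cells <- suppressWarnings(as.numeric(raw$cells_per_ml))
    units[["cells"]] <- "per_ml"
  }
  for (a in .GEOCHEM_ANALYTES) if (!a %in% names(out)) out[[a]] <- NA_real_
  if (!"d13c_ch4" %in% names(out)) out$d13c_ch4 <- NA_real_
  if (!"cells" %in% names(out)) out$cells <- NA_real_

  n_read <- nrow(out)
  dropped <- c(bad_day = 0L, negative_value = 0L)
  bad_day <- !is.finite(out$day) | out$day < 0
  dropped[["bad_day"]] <- sum(bad_day)
  out <- out[!bad_day, , drop = FALSE]
  neg <- rep(FALSE, nrow(out))
  for (a in .GEOCHEM_ANALYTES) {
    v <- out[[a]]
    neg <- neg | (!is.na(v) & v < 0)
  }
  neg <- neg | (!is.na(out$cells) & out$cells < 0)
  dropped[["negative_value"]] <- sum(neg)
  out <- out[!neg, , drop = FALSE]

  series <- geochem_series(out, geometry, experiment_id)
  list(series = series, qc = qc_report(n_read, dropped, units))
}

#' Write a geochemical time-series file
#'
#' Writes a [geochem_series()] to CSV with the header
#' `day,bottle,replicate,sulfate_mM,methane_mM,hydrogen_nM,d13c_ch4_permil,cells_per_ml`.
#' Aqueous species are converted back from mol/L to the header units and
#' formatted to 6 significant digits; missing values are written as empty
#' cells, never zeros. `write_geochem()` followed by [read_geochem()]
#' reproduces the records up to that formatting precision.
#'
#' @param series A [geochem_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geochem <- function(series, path) {
  stopifnot(inherits(series, "geochem_series"))
  r <- series$records
  fmt <- function(x) ifelse(is.na(x), "", formatC(signif(x, 6), format = "g",
                                                  digits = 6))
  out <- data.frame(day = fmt(r$day),
                    bottle = r$bottle,
                    replicate = ifelse(is.na(r$replicate), "", r$replicate),
                    sulfate_mM = fmt(r$sulfate / 1e-3),
                    methane_mM = fmt(r$methane / 1e-3),
                    hydrogen_nM = fmt(r$hydrogen / 1e-9),
                    d13c_ch4_permil = fmt(r$d13c_ch4),
                    cells_per_ml = fmt(r$cells),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
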