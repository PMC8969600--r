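# Windowed rate estimation, peak/plateau detection, and phase segmentation
# of an incubation time series.

.analyte_column <- function(series, analyte) {
  choices <- c("sulfate", "methane", "hydrogen", "d13c_ch4", "cells")
  analyte <- match.arg(analyte, choices)
  analyte
}

# Replicate-mean value per day (pooled across bottles and replicates).
.daily_means <- function(series, analyte) {
  r <- series$records
  v <- r[[analyte]]
  ok <- !is.na(v)
  if (!any(ok)) return(data.frame(day = numeric(), mean = numeric(),
                                  n = integer()))
  agg <- stats::aggregate(list(mean = v[ok]), by = list(day = r$day[ok]),
                          FUN = mean)
  cnt <- stats::aggregate(list(n = v[ok]), by = list(day = r$day[ok]),
                          FUN = length)
  out <- merge(agg, cnt, by = "day")
  out[order(out$day), , drop = FALSE]
}

#' Windowed least-squares rate estimate
#'
#' Ordinary least-squares regression of concentration on day over a time
#' window, pooling all bottles and replicates (so a window with three
#' timepoints and triplicate bottles contributes n = 9 points). Window
#' endpoints are inclusive, with a 1e-6 day comparison tolerance.
#'
#' @param series A [geochem_series()].
#' @param analyte One of `"sulfate"`, `"methane"`, `"hydrogen"`,
#'   `"d13c_ch4"`, `"cells"`.
#' @param t0,t1 Window bounds in days, `t0 < t1`.
#' @return An object of class `rate_estimate`: slope (per day, in the
#'   analyte's canonical unit), intercept, `r2`, `n`, `window`, `analyte`.
#'   `r2` is defined as 0 when the response is constant.
#' @examples
#' \dontrun{window_rate(series, "methane", 362, 396)}
#' @export
window_rate <- function(series, analyte, t0, t1) {
  stopifnot(inherits(series, "geochem_series"))
  analyte <- .analyte_column(series, analyte)
  if (!(t0 < t1)) stop("window must satisfy t0 < t1")
  tol <- 1e-6
  r <- series$records
  keep <- r$day >= t0 - tol & r$day <= t1 + tol & !is.na(r[[analyte]])
  x <- r$day[keep]
  y <- r[[analyte]][keep]
  n <- length(y)
  if (n < 2) stop("fewer than 2 points with ", analyte, " in [", t0, ", ", t1, "]")
  if (stats::var(x) == 0) stop("zero time variance in window")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2, n = n, window = c(t0 = t0, t1 = t1), analyte = analyte),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate (%s, days %g-%g): slope %.4g per day, R2 = %.3f, n = %d\n",
              x$analyte, x$window[["t0"]], x$window[["t1"]], x$slope, x$r2, x$n))
  invisible(x)
}

#' Detect the peak of an analyte trajectory
#'
#' Returns the day at which the replicate-mean value of the analyte is
#' maximal, and that value. Ties are broken by the earliest day.
#'
#' @inheritParams window_rate
#' @return A list with `day`, `value` (replicate mean), and `n` (points
#'   averaged on that day).
#' @export
detect_peak <- function(series, analyte) {
  stopifnot(inherits(series, "geochem_series"))
  analyte <- .analyte_column(series, analyte)
  dm <- .daily_means(series, analyte)
  if (nrow(dm) == 0) stop("no evaluable timepoints for ", analyte)
  i <- which(dm$mean == max(dm$mean))[1]  # earliest day on ties
  list(day = dm$day[i], value = dm$mean[i], n = dm$n[i])
}

#' Detect concentration plateaus
#'
#' Finds maximal runs of consecutive timepoints over which the pooled
#' measurements (all bottles and replicates) are stable, defined as a
#' pooled coefficient of variation `sd/mean <= cv_max`. Runs are grown
#' greedily left to right; a run is reported when it holds at least
#' `min_n` pooled points.
#'
#' @inheritParams window_rate
#' @param cv_max Maximum pooled coefficient of variation (> 0).
#' @param min_n Minimum number of pooled points per plateau (>= 3).
#' @return A data.frame with one row per plateau: `t0`, `t1`, `mean`,
#'   `sd`, `n`. Zero rows when no plateau qualifies.
#' @export
detect_plateaus <- function(series, analyte, cv_max = 0.25, min_n = 3) {
  stopifnot(inherits(series, "geochem_series"))
  if (cv_max <= 0) stop("cv_max must be > 0")
  if (min_n < 3) stop("min_n must be >= 3")
  analyte <- .analyte_column(series, analyte)
  r <- series$records
  ok <- !is.na(r[[analyte]])
  days <- sort(unique(r$day[ok]))
  vals_by_day <- lapply(days, function(d) r[[analyte]][ok & r$day == d])
  pooled_cv <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (length(v) < 2 || s == 0) return(0)
    if (m == 0) return(Inf)
    s / abs(m)
  }
  out <- list()
  i <- 1
  while (i <= length(days)) {
    j <- i
    acc <- vals_by_day[[i]]
    if (pooled_cv(acc) <= cv_max) {
      while (j < length(days)) {
        cand <- c(acc, vals_by_day[[j + 1]])
        if (pooled_cv(cand) <= cv_max) {
          acc <- cand
          j <- j + 1
        } else break
      }
      if (length(acc) >= min_n) {
        out[[length(out) + 1]] <- data.frame(
          t0 = days[i], t1 = days[j], mean = mean(acc),
          sd = if (length(acc) > 1) stats::sd(acc) else 0, n = length(acc))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(t0 = numeric(), t1 = numeric(), mean = numeric(),
                      sd = numeric(), n = integer()))
  }
  do.call(rbind, out)
}

#' Phase segmentation rule thresholds
#'
#' @param s_mc Sulfate (mol/L) below which the incubation leaves the
#'   sulfate-reduction/AOM phase. Default 5e-3 (5 mM).
#' @param s_mg Sulfate (mol/L) below which sulfate is considered depleted.
#'   Default 1e-4 (0.1 mM).
#' @param k_confirm Number of consecutive timepoints of depleted sulfate
#'   with non-decreasing methane (and declining d13C-CH4, when measured)
#'   required to call net methanogenesis. Default 3.
#' @return A list of class `phase_rules`.
#' @export
phase_rules <- function(s_mc = 5e-3, s_mg = 1e-4, k_confirm = 3) {
  stopifnot(s_mc > s_mg, s_mg > 0, k_confirm >= 1)
  structure(list(s_mc = s_mc, s_mg = s_mg, k_confirm = k_confirm),
            class = "phase_rules")
}

#' Segment an incubation into process phases
#'
#' Applies ordered rules to the replicate-mean trajectories to divide the
#' incubation into three contiguous phases:
#' \describe{
#'   \item{sulfate_reduction_aom}{while mean sulfate > `s_mc`;}
#'   \item{methane_cycling}{while sulfate is low but not depleted
#'     (`s_mg` < sulfate <= `s_mc`), or depleted without a confirmed
#'     methane rise;}
#'   \item{net_methanogenesis}{from the first of `k_confirm` consecutive
#'     timepoints with sulfate <= `s_mg`, non-decreasing mean methane and,
#'     when d13C-CH4 is measured, decreasing d13C-CH4.}
#' }
#' Segments partition `[first_day, last_day]` with no gaps. If no
#' timepoint has sulfate above `s_mc` the segmentation starts in the
#' methane-cycling phase.
#'
#' @param series A [geochem_series()] with a sulfate series.
#' @param energy Optional output of [energy_series()]; when given, each
#'   segment's evidence note reports the fraction of records on the
#'   AOM-exergonic side of the free-energy threshold.
#' @param rules A [phase_rules()] object.
#' @return A data.frame of class `phase_segmentation`: `phase`, `t_start`,
#'   `t_end`, `note`.
#' @export
segment_phases <- function(series, energy = NULL, rules = phase_rules()) {
  stopifnot(inherits(series, "geochem_series"), inherits(rules, "phase_rules"))
  sulf <- .daily_means(series, "sulfate")
  if (nrow(sulf) == 0) stop("sulfate series required for phase segmentation")
  meth <- .daily_means(series, "methane")
  d13c <- .daily_means(series, "d13c_ch4")
  days <- sulf$day
  n <- length(days)
  first_day <- min(series$records$day)
  last_day <- max(series$records$day)

  # (a) -> (b): first timepoint with mean sulfate <= s_mc
  idx_b <- which(sulf$mean <= rules$s_mc)[1]

  # (b) -> (c): first of k_confirm consecutive depleted timepoints with
  # non-decreasing methane and (when present) decreasing d13C.
  meth_at <- function(d) {
    i <- match(d, meth$day)
    if (is.na(i)) NA_real_ else meth$mean[i]
  }
  d13c_at <- function(d) {
    i <- match(d, d13c$day)
    if (is.na(i)) NA_real_ else d13c$mean[i]
  }
  have_d13c <- nrow(d13c) > 0
  idx_c <- NA_integer_
  if (!is.na(idx_b)) {
    k <- rules$k_confirm
    for (i in seq(idx_b, n)) {
      if (i + k - 1 > n) break
      run <- seq(i, i + k - 1)
      if (any(sulf$mean[run] > rules$s_mg)) next
      m <- vapply(days[run], meth_at, numeric(1))
      if (any(is.na(m)) || any(diff(m) < 0)) next
      if (have_d13c) {
        dd <- vapply(days[run], d13c_at, numeric(1))
        dd <- dd[!is.na(dd)]
        if (length(dd) >= 2 && !all(diff(dd) <= 0)) next
        if (length(dd) >= 2 && all(diff(dd) == 0)) next
      }
      idx_c <- i
      break
    }
  }

  aom_frac <- function(t0, t1) {
    if (is.null(energy) || nrow(energy) == 0) return(NA_real_)
    e <- energy[energy$day >= t0 & energy$day <= t1, , drop = FALSE]
    if (nrow(e) == 0) return(NA_real_)
    mean(e$direction == "aom_exergonic")
  }
  seg <- function(phase, t0, t1, why) {
    f <- aom_frac(t0, t1)
    note <- if (is.na(f)) why else sprintf("%s; AOM-exergonic fraction %.2f", why, f)
    data.frame(phase = phase, t_start = t0, t_end = t1, note = note,
               stringsAsFactors = FALSE)
  }

  pieces <- list()
  t_b <- if (is.na(idx_b)) NA_real_ else days[idx_b]
  t_c <- if (is.na(idx_c)) NA_real_ else days[idx_c]
  if (is.na(idx_b)) {
    pieces[[1]] <- seg("sulfate_reduction_aom", first_day, last_day,
                       sprintf("mean sulfate never <= %.3g M", rules$s_mc))
  } else {
    if (idx_b > 1 && t_b > first_day) {
      pieces[[length(pieces) + 1]] <-
        seg("sulfate_reduction_aom", first_day, t_b,
            sprintf("mean sulfate > %.3g M", rules$s_mc))
      start_b <- t_b
    } else {
      start_b <- first_day
    }
    if (is.na(idx_c)) {
      pieces[[length(pieces) + 1]] <-
        seg("methane_cycling", start_b, last_day,
            "sulfate low; net methanogenesis never confirmed")
    } else {
      if (t_c > start_b) {
        pieces[[length(pieces) + 1]] <-
          seg("methane_cycling", start_b, t_c,
              sprintf("sulfate <= %.3g M without confirmed methane rise",
                      rules$s_mc))
      }
      why_c <- sprintf(
        "%d consecutive timepoints: sulfate <= %.3g M, methane non-decreasing%s",
        rules$k_confirm, rules$s_mg,
        if (have_d13c) ", d13C-CH4 declining" else "")
      pieces[[length(pieces) + 1]] <- seg("net_methanogenesis", t_c, last_day,
                                          why_c)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("phase_segmentation", "data.frame")
  out
}
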