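# trapezoid integration
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' Centroid of the region between a curve and a baseline
#'
#' Planar centroid of the region enclosed between `y(t)` and the horizontal
#' `baseline`, with negative lobes clipped to the baseline:
#' `xbar = integral(t*h) / integral(h)` and
#' `ybar = baseline + integral(h^2)/2 / integral(h)`, with `h = y - baseline`
#' and trapezoid-rule integrals.
#'
#' @param t Time grid, seconds (strictly increasing).
#' @param y Curve values, volts.
#' @param baseline Baseline level, volts.
#' @return Numeric `c(x, y)` centroid.
#' @export
region_centroid <- function(t, y, baseline = 0) {
  if (length(t) < 2 || length(t) != length(y)) {
    stop("`t` and `y` must be equal-length with at least 2 points",
         call. = FALSE)
  }
  h <- pmax(y - baseline, 0)
  a <- trapz(t, h)
  if (a <= 0) stop("degenerate region: zero area", call. = FALSE)
  c(x = trapz(t, t * h) / a,
    y = baseline + 0.5 * trapz(t, h^2) / a)
}

# sample the signal on [t_from, t_to] (seconds, 0-based (i-1)/fs axis),
# linearly interpolating the fractional end points
slice_signal <- function(x, fs, t_from, t_to) {
  i_from <- t_from * fs + 1
  i_to <- t_to * fs + 1
  ii <- seq(ceiling(i_from + 1e-9), floor(i_to - 1e-9))
  interp <- function(pos) {
    lo <- floor(pos); hi <- min(lo + 1, length(x)); w <- pos - lo
    (1 - w) * x[lo] + w * x[hi]
  }
  t <- c(t_from, (ii - 1) / fs, t_to)
  y <- c(interp(i_from), x[ii], interp(i_to))
  list(t = t, y = y)
}

#' Names and classes of the 17 morphological features
#'
#' The features fall into three classes: temporal (durations and
#' x-centroids: F1, F7, F9, F11, F13, F14, F15), amplitude (voltages, areas
#' and y-centroids: F2, F3, F4, F5, F6, F8, F10, F12) and geometric (slope
#' angles in radians: F16, F17).
#'
#' @return A data.frame with columns `feature` ("f1".."f17"), `class`, and a
#'   short `description`.
#' @export
feature_classes <- function() {
  data.frame(
    feature = paste0("f", 1:17),
    class = c("temporal", "amplitude", "amplitude", "amplitude", "amplitude",
              "amplitude", "temporal", "amplitude", "temporal", "amplitude",
              "temporal", "amplitude", "temporal", "temporal", "temporal",
              "geometric", "geometric"),
    description = c(
      "cycle duration, TI point to next TI point (s)",
      "pulse amplitude, onset to systolic peak (V)",
      "amplitude of the max-slope point above the onset (V)",
      "area of the pulse, TI to TI (V s)",
      "area of the systolic phase, onset to peak (V s)",
      "area of the diastolic phase, peak to next onset (V s)",
      "x-centroid of the pulse (s)",
      "y-centroid of the pulse (V)",
      "x-centroid of the systolic phase (s)",
      "y-centroid of the systolic phase (V)",
      "x-centroid of the diastolic phase (s)",
      "y-centroid of the diastolic phase (V)",
      "pulse width, f11 - f9 (s)",
      "rise time, onset to peak (s)",
      "decay time, peak to next onset (s)",
      "upslope angle, atan(f2 / f14) (rad)",
      "downslope angle, atan(f2 / f15) (rad)"),
    stringsAsFactors = FALSE
  )
}

#' Extract the 17 morphological features of one cardiac cycle
#'
#' Computes the full feature vector for a detected cycle. Areas and
#' centroids are taken above the cycle's onset amplitude (the pulse foot),
#' with negative excursions clipped; y-centroids are reported as absolute
#' voltages. The pulse region (F1, F4, F7, F8) spans TI point to next TI
#' point; the systolic phase spans onset to systolic peak; the diastolic
#' phase spans peak to next onset. Angles are computed on raw (V, s) ratios.
#'
#' @param x Filtered PPG signal the cycles were detected on.
#' @param cycle One row of a [detect_cycles()] result (list or data.frame
#'   row with `onset_index`, `max_slope_index`, `peak_index`,
#'   `next_onset_index`, `ti_time`).
#' @param next_ti TI time (s) of the following cycle, required for the
#'   TI-to-TI features F1/F4/F7/F8.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector `f1`..`f17`.
#' @export
extract_features <- function(x, cycle, next_ti, fs) {
  o <- cycle$onset_index; pk <- cycle$peak_index
  no <- cycle$next_onset_index; ms <- cycle$max_slope_index
  ti <- cycle$ti_time
  if (!is.finite(next_ti)) {
    stop("feature-window error: next TI point unavailable", call. = FALSE)
  }
  base <- x[o]
  t_o <- (o - 1) / fs; t_pk <- (pk - 1) / fs; t_no <- (no - 1) / fs

  f1 <- next_ti - ti
  f2 <- x[pk] - base
  f3 <- x[ms] - base

  pulse <- slice_signal(x, fs, ti, next_ti)
  sys <- list(t = (o:pk - 1) / fs, y = x[o:pk])
  dia <- list(t = (pk:no - 1) / fs, y = x[pk:no])

  f4 <- trapz(pulse$t, pmax(pulse$y - base, 0))
  f5 <- trapz(sys$t, pmax(sys$y - base, 0))
  f6 <- trapz(dia$t, pmax(dia$y - base, 0))

  c78 <- region_centroid(pulse$t, pulse$y, base)
  c910 <- region_centroid(sys$t, sys$y, base)
  c1112 <- region_centroid(dia$t, dia$y, base)
  # x-centroids are reported relative to the cycle onset: on a continuous
  # pressure-ramp protocol an absolute time coordinate would be a proxy for
  # elapsed time (hence contact pressure), not for pulse morphology
  c78[["x"]] <- c78[["x"]] - t_o
  c910[["x"]] <- c910[["x"]] - t_o
  c1112[["x"]] <- c1112[["x"]] - t_o

  f13 <- c1112[["x"]] - c910[["x"]]
  f14 <- t_pk - t_o
  f15 <- t_no - t_pk
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6,
    f7 = c78[["x"]], f8 = c78[["y"]], f9 = c910[["x"]], f10 = c910[["y"]],
    f11 = c1112[["x"]], f12 = c1112[["y"]],
    f13 = f13, f14 = f14, f15 = f15,
    f16 = atan(f2 / f14), f17 = atan(f2 / f15))
}

#' Feature matrix for all detected cycles
#'
#' One row of 17 features per usable cycle (the last cycle is dropped when
#' the following TI point is unavailable), with the cycle's mean contact
#' pressure attached when a force channel is supplied.
#'
#' @param x Filtered PPG signal.
#' @param cycles A [detect_cycles()] result.
#' @param fs Sampling rate, Hz.
#' @param cp Optional contact-pressure series aligned with `x` (mmHg); the
#'   mean over each cycle's onset-to-next-onset span is attached as
#'   `cp_mmHg`.
#' @return A data.frame with columns `cycle_index`, optionally `cp_mmHg`,
#'   and `f1`..`f17`.
#' @export
feature_matrix <- function(x, cycles, fs, cp = NULL) {
  if (nrow(cycles) < 2) {
    stop("need at least 2 cycles for TI-to-TI features", call. = FALSE)
  }
  rows <- vector("list", nrow(cycles) - 1)
  for (i in seq_len(nrow(cycles) - 1)) {
    fv <- extract_features(x, cycles[i, ], next_ti = cycles$ti_time[i + 1],
                           fs = fs)
    row <- as.data.frame(as.list(fv))
    row$cycle_index <- i
    if (!is.null(cp)) {
      span <- cycles$onset_index[i]:cycles$next_onset_index[i]
      row$cp_mmHg <- mean(cp[span])
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  front <- intersect(c("cycle_index", "cp_mmHg"), names(out))
  out[, c(front, paste0("f", 1:17))]
}
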