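# central-difference slope (units of x per sample) over +/- halfwin samples;
# halfwin matched to the analysis band tames derivative noise at high fs.
# Edges shrink the window; halfwin = 1 is the plain central difference.
smooth_slope <- function(x, halfwin = 1) {
  n <- length(x)
  h <- max(1L, min(as.integer(halfwin), n - 1L))
  ip <- pmin(seq_len(n) + h, n)
  im <- pmax(seq_len(n) - h, 1L)
  (x[ip] - x[im]) / (ip - im)
}

# blockwise rolling maximum of a series (window ~ 2*block samples), O(n)
rolling_block_max <- function(x, block) {
  nb <- ceiling(length(x) / block)
  idx <- rep(seq_len(nb), each = block)[seq_along(x)]
  bmax <- tapply(x, idx, max)
  # each sample sees the max of its own and both neighbouring blocks
  look <- pmax(bmax,
               c(bmax[-1], bmax[nb]),
               c(bmax[1], bmax[-nb]))
  as.numeric(look)[idx]
}

#' Detect cardiac cycles in a PPG segment
#'
#' Adaptive-threshold, derivative-based pulse onset detector in the spirit of
#' the adaptive onset/peak detectors standard in the pulse-wave literature:
#' upstrokes are located where the first derivative of the (already
#' filtered) signal exceeds an adaptive threshold equal to a fraction of the
#' local rolling derivative maximum, with a refractory period between
#' upstrokes; each onset is the signal minimum in a short look-back window
#' before its upstroke; the systolic peak is the maximum between consecutive
#' onsets. Incomplete first/last cycles are discarded and every returned
#' cycle satisfies `onset <= ti_time*fs <= max_slope <= peak < next_onset`.
#'
#' Detection is amplitude-scale invariant: scaling the signal by a positive
#' constant leaves all indices unchanged.
#'
#' @param x Filtered, segmented PPG signal.
#' @param fs Sampling rate, Hz.
#' @param thr_frac Threshold as a fraction of the local rolling derivative
#'   maximum (default 0.4).
#' @param refractory_s Minimum spacing between upstrokes, seconds (default
#'   0.3, i.e. a 200 BPM ceiling).
#' @param lookback_s Onset search window before each upstroke, seconds
#'   (default 0.5).
#' @param slope_halfwin_s Central-difference half-window for slope
#'   estimates, seconds (default 0.04, matched to the 12 Hz analysis band:
#'   a one-sample difference at 1 kHz would be dominated by residual noise).
#' @return A data.frame of class `"cardiac_cycles"`, one row per cycle:
#'   `onset_index`, `max_slope_index`, `peak_index`, `next_onset_index`
#'   (samples, 1-based), `ti_time` (s, 0-based like `(index - 1) / fs`).
#' @export
detect_cycles <- function(x, fs, thr_frac = 0.4, refractory_s = 0.3,
                          lookback_s = 0.5, slope_halfwin_s = 0.04) {
  n <- length(x)
  if (n < 2 * fs) stop("no cycles: segment shorter than 2 s", call. = FALSE)
  hw <- max(1L, as.integer(round(slope_halfwin_s * fs)))
  d <- smooth_slope(x, hw) * fs
  dmax <- rolling_block_max(pmax(d, 0), block = round(2 * fs))
  if (max(dmax) <= 0) stop("no cycles: signal has no upstrokes", call. = FALSE)
  thr <- thr_frac * pmax(dmax, 0.05 * max(dmax))
  above <- d > thr
  starts <- which(above & !c(FALSE, above[-n]))
  if (length(starts) < 2) stop("no cycles: fewer than 2 onsets", call. = FALSE)
  # refractory: keep the first crossing of each burst
  keep <- c(TRUE, diff(starts) > refractory_s * fs)
  starts <- starts[keep]
  if (length(starts) < 2) stop("no cycles: fewer than 2 onsets", call. = FALSE)

  lb <- as.integer(round(lookback_s * fs))
  onsets <- vapply(starts, function(s) {
    lo <- max(1L, as.integer(s) - lb)
    lo + which.min(x[lo:s]) - 1L
  }, integer(1))
  onsets <- unique(onsets)
  if (length(onsets) < 2) stop("no cycles: fewer than 2 onsets", call. = FALSE)

  rows <- list()
  for (i in seq_len(length(onsets) - 1)) {
    o <- onsets[i]; no <- onsets[i + 1]
    if (no - o < refractory_s * fs) next
    pk <- o + which.max(x[o:no]) - 1L
    if (pk <= o || pk >= no) next
    ms <- tryCatch(max_slope_point(x, o, pk, halfwin = hw),
                   error = function(e) NA_integer_)
    if (is.na(ms)) next
    ti <- tryCatch(ti_point(x, o, ms, fs, halfwin = hw),
                   error = function(e) NA_real_)
    if (is.na(ti)) next
    if (!(o <= ti * fs + 1 && ti * fs + 1 <= ms + 1e-9 && ms <= pk)) next
    rows[[length(rows) + 1]] <- data.frame(
      onset_index = o, max_slope_index = ms, peak_index = pk,
      next_onset_index = no, ti_time = ti)
  }
  if (length(rows) == 0) stop("no cycles: no valid cycle found", call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("cardiac_cycles", "data.frame")
  out
}

#' Maximum-slope point of a pulse upstroke
#'
#' Index of the maximum first difference of `x` on `[onset, peak]`; ties are
#' broken to the earliest sample.
#'
#' @param x Signal.
#' @param onset,peak Sample indices bounding the upstroke.
#' @param halfwin Central-difference half-window in samples for the slope
#'   estimate (default 1: plain first difference; the cycle detector passes
#'   a window matched to the analysis band).
#' @return Sample index of the maximum-slope point.
#' @export
max_slope_point <- function(x, onset, peak, halfwin = 1) {
  if (peak <= onset) stop("degenerate cycle: peak <= onset", call. = FALSE)
  if (peak == onset + 1) return(onset)
  if (halfwin <= 1) {
    dd <- diff(x[onset:peak])
  } else {
    dd <- smooth_slope(x[onset:peak], halfwin)[seq_len(peak - onset)]
  }
  if (max(dd) <= 0) stop("degenerate cycle: flat upstroke", call. = FALSE)
  onset + which.max(dd) - 1L
}

#' Tangent-intersection (TI) point of a pulse
#'
#' Intersection of the tangent at the maximum-slope point of the upstroke
#' with the horizontal tangent at the pulse valley (onset): with the
#' max-slope point at `(t_m, y_m)`, slope `s_m` (central difference), and
#' valley amplitude `y_v`, the TI time is `t_m - (y_m - y_v) / s_m`. The
#' result is clipped to the onset time (with a warning) if the geometry
#' degenerates.
#'
#' @param x Signal.
#' @param onset Onset (valley) sample index.
#' @param max_slope_index Max-slope sample index.
#' @param fs Sampling rate, Hz.
#' @param halfwin Central-difference half-window (samples) for the tangent
#'   slope; exact for locally quadratic upstrokes at any window size.
#' @return TI time in seconds on the `(index - 1) / fs` time axis (may fall
#'   between samples).
#' @export
ti_point <- function(x, onset, max_slope_index, fs, halfwin = 1) {
  i <- max_slope_index
  if (i <= 1 || i >= length(x)) {
    stop("degenerate cycle: max-slope point at signal edge", call. = FALSE)
  }
  h <- max(1L, min(as.integer(halfwin), i - 1L, length(x) - i))
  s_m <- (x[i + h] - x[i - h]) / (2 * h) * fs
  if (s_m <= 0) stop("degenerate cycle: non-positive slope", call. = FALSE)
  t_m <- (i - 1) / fs
  ti <- t_m - (x[i] - x[onset]) / s_m
  t_on <- (onset - 1) / fs
  if (ti < t_on) {
    warning("TI point clipped to onset time (degenerate geometry)")
    ti <- t_on
  }
  ti
}
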