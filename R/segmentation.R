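#' Contact window of a recording
#'
#' The coarse analysis window: from the first sample at which the load-cell
#' force is positive to the sample of maximum force (first of ties).
#'
#' @param record A `ppg_record`.
#' @return Integer vector `c(start, end)` of sample indices.
#' @export
contact_window <- function(record) {
  f <- record$force
  if (is.null(f)) stop("invalid record: missing force channel", call. = FALSE)
  pos <- which(f > 0)
  if (length(pos) == 0) stop("no contact: force never positive", call. = FALSE)
  c(pos[1], which.max(f))
}

#' Rectified-signal envelope
#'
#' Envelope of the rectified PPG signal: the signal is baseline-removed by
#' subtracting its median, rectified (absolute value) and smoothed with a
#' linear-phase FIR low-pass filter with 0.5 Hz cut-off and order 5 x fs.
#' Negative filter ringing is clipped to zero so the envelope is
#' non-negative.
#'
#' @param x Numeric PPG segment (inside the contact window).
#' @param fs Sampling rate, Hz.
#' @param cutoff_hz Envelope smoother cut-off (default 0.5 Hz).
#' @param order FIR order (default `5 * fs`).
#' @return Non-negative envelope, same length as `x`.
#' @export
rectified_envelope <- function(x, fs, cutoff_hz = 0.5, order = 5 * fs) {
  r <- abs(x - stats::median(x))
  pmax(fir_lowpass(r, cutoff_hz, order, fs), 0)
}

# first local minimum at or after index `from`: the first sample that is the
# minimum of its +/- `halfwin` neighbourhood (first sample of a flat run).
# The neighbourhood requirement keeps sub-cycle noise ripple on the heavily
# smoothed envelope from being mistaken for an envelope onset.
first_local_min_after <- function(y, from, halfwin = 1) {
  n <- length(y)
  i <- max(from, halfwin + 1)
  while (i <= n - halfwin) {
    nb <- y[(i - halfwin):(i + halfwin)]
    if (y[i] <= min(nb) && y[i] < y[i - halfwin]) return(i)
    i <- i + 1
  }
  NA_integer_
}

#' Isolate the pulsatile segment of a recording
#'
#' Automatically finds the portion of the record in which the sensor is in
#' contact with the tissue and pulsatile flow persists:
#' \enumerate{
#'   \item restrict to the [contact_window()];
#'   \item compute the [rectified_envelope()] of the 12 Hz-filtered channel;
#'   \item differentiate the envelope and smooth the derivative with a
#'     0.1 Hz FIR low-pass of order 10 x fs;
#'   \item min-max normalise both curves to `[0, 1]` over the contact
#'     window; the segment start is the first index at which the normalised
#'     derivative and the normalised envelope intersect (sign change of
#'     their difference, either direction);
#'   \item the segment end is the first local minimum ("onset") of the
#'     envelope after the global minimum of the smoothed derivative, clipped
#'     to the end of the contact window.
#' }
#'
#' @param record A `ppg_record`.
#' @param channel `"ir"` or `"red"`.
#' @param min_pulse_band_fraction Minimum fraction of the (DC-removed)
#'   spectral power that must lie in the pulse band 0.5-3 Hz for the record
#'   to count as pulsatile (default 0.5); pure noise spreads its power over
#'   the whole bandwidth and fails this test.
#' @return A list of class `"segment_window"`: `start_index`, `end_index`
#'   (absolute sample indices), `start_reason`, `end_reason`, plus a
#'   `diagnostics` list (envelope, smoothed derivative, contact window).
#' @export
segment_pulsatile <- function(record, channel = c("ir", "red"),
                              min_pulse_band_fraction = 0.5) {
  channel <- match.arg(channel)
  fs <- record$fs
  cw <- contact_window(record)
  x <- record[[paste0("ppg_", channel)]][cw[1]:cw[2]]

  # pulsatility gate: fraction of non-DC power in the 0.5-3 Hz pulse band
  x0 <- x - stats::median(x)
  p <- Mod(stats::fft(x0))^2
  nb <- floor(length(x0) / 2) + 1
  p <- p[seq_len(nb)]
  fr <- (seq_len(nb) - 1) * fs / length(x0)
  band <- sum(p[fr >= 0.5 & fr <= 3])
  tot <- sum(p[fr >= 0.05])
  if (tot <= 0 || band / tot < min_pulse_band_fraction) {
    stop("segmentation failure: no pulsatile envelope detected ",
         sprintf("(pulse-band power fraction %.2f < %.2f)",
                 if (tot > 0) band / tot else 0, min_pulse_band_fraction),
         call. = FALSE)
  }

  xf <- lowpass_zero_phase(x, fs = fs)
  env <- rectified_envelope(xf, fs)
  denv <- c(diff(env), 0) * fs
  denv_s <- fir_lowpass(denv, 0.1, 10 * fs, fs)

  rng <- range(env)
  if (diff(rng) <= 0) {
    stop("segmentation failure: flat envelope", call. = FALSE)
  }
  ne <- (env - rng[1]) / diff(rng)
  rngd <- range(denv_s)
  nd <- (denv_s - rngd[1]) / diff(rngd)

  d <- nd - ne
  s <- sign(d)
  cross <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (length(cross) == 0) {
    stop("segmentation failure: envelope and derivative never intersect",
         call. = FALSE)
  }
  start_rel <- cross[1] + 1L

  imin_d <- which.min(denv_s)
  end_rel <- first_local_min_after(env, imin_d + 1L,
                                   halfwin = round(0.5 * fs))
  end_reason <- "post_minimum_onset"
  if (is.na(end_rel) || end_rel > length(x)) {
    end_rel <- length(x)
    end_reason <- "clipped_to_max_force"
  }
  if (end_rel <= start_rel) {
    stop("segmentation failure: degenerate window (end <= start)",
         call. = FALSE)
  }
  structure(list(
    start_index = cw[1] + start_rel - 1L,
    end_index = cw[1] + end_rel - 1L,
    start_reason = "derivative_crossing",
    end_reason = end_reason,
    diagnostics = list(contact_window = cw, envelope = env,
                       derivative = denv_s, channel = channel)
  ), class = "segment_window")
}

#' @export
print.segment_window <- function(x, ...) {
  cat(sprintf("<segment_window> samples %d..%d (%s -> %s)\n",
              x$start_index, x$end_index, x$start_reason, x$end_reason))
  invisible(x)
}

#' Jaccard overlap of two index/time windows
#'
#' Utility for comparing a recovered segment window with a reference window:
#' intersection length over union length.
#'
#' @param a,b Length-2 numeric vectors `c(start, end)`.
#' @return Jaccard index in `[0, 1]`.
#' @export
window_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) return(0)
  inter / uni
}
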