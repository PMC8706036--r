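# Kaiser window; beta = 38 puts sidelobes below double-precision noise so
# spectral leakage outside a component's main lobe never contaminates the
# noise estimate.
kaiser_window <- function(n, beta = 38) {
  k <- seq(0, n - 1)
  r <- 2 * k / (n - 1) - 1
  besselI(beta * sqrt(pmax(1 - r^2, 0)), 0) / besselI(beta, 0)
}

# expand from a peak bin to the local minima bracketing its lobe
expand_peak <- function(p, i) {
  lo <- i
  while (lo > 1 && p[lo - 1] < p[lo]) lo <- lo - 1
  hi <- i
  while (hi < length(p) && p[hi + 1] < p[hi]) hi <- hi + 1
  lo:hi
}

#' Signal-to-noise ratio of a quasi-periodic signal (periodogram method)
#'
#' Estimates SNR the way the widely used MATLAB `snr(x)` convention does: a
#' Kaiser-windowed (beta = 38) periodogram is computed; the DC lobe is
#' excluded (bins descending from DC); the fundamental is the largest
#' remaining spectral peak, and its power is summed over its main lobe
#' (extended to the bracketing local minima); the lobes of the first
#' `n_harmonics` harmonics are likewise excluded; the noise power is the mean
#' of the remaining bins scaled back to the full (non-DC) bandwidth. Returns
#' `10*log10(Psignal/Pnoise)` in dB.
#'
#' @param x Numeric signal, at least one second long.
#' @param fs Sampling rate, Hz.
#' @param n_harmonics Number of harmonics above the fundamental to exclude
#'   from the noise (default 6).
#' @return SNR in dB.
#' @export
snr_db <- function(x, fs, n_harmonics = 6) {
  n <- length(x)
  if (n < fs) stop("need at least 1 s of signal", call. = FALSE)
  if (all(x == x[1])) {
    stop("degenerate signal: constant input has no fundamental",
         call. = FALSE)
  }
  # remove the DC component up front: with a high-beta Kaiser window a large
  # baseline otherwise smears a wide DC lobe into the fundamental's
  x <- x - mean(x)
  w <- kaiser_window(n)
  X <- stats::fft(x * w)
  nb <- floor(n / 2) + 1
  p <- Mod(X[seq_len(nb)])^2
  # one-sided scaling (irrelevant for the ratio, kept for interpretability)
  if (nb > 2) p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]

  used <- rep(FALSE, nb)
  dc <- 1
  while (dc < nb && p[dc + 1] < p[dc]) dc <- dc + 1
  used[seq_len(dc)] <- TRUE

  cand <- which(!used)
  if (length(cand) == 0) stop("degenerate signal", call. = FALSE)
  ifund <- cand[which.max(p[cand])]
  lobe <- expand_peak(p, ifund)
  lobe <- lobe[!used[lobe]]
  psig <- sum(p[lobe])
  used[lobe] <- TRUE
  # refined fundamental frequency: power-weighted centroid of the lobe
  f0 <- sum((lobe - 1) * p[lobe]) / sum(p[lobe]) * fs / n

  for (h in seq_len(n_harmonics) + 1) {
    ih <- round(h * f0 * n / fs) + 1
    if (ih < 2 || ih > nb) next
    # climb to the nearest local max
    while (ih > 1 && p[ih - 1] > p[ih]) ih <- ih - 1
    while (ih < nb && p[ih + 1] > p[ih]) ih <- ih + 1
    hl <- expand_peak(p, ih)
    used[hl] <- TRUE
  }
  rest <- which(!used)
  if (length(rest) == 0) return(Inf)
  pnoise <- mean(p[rest]) * (nb - dc)
  if (pnoise <= 0) return(Inf)
  10 * log10(psig / pnoise)
}

#' Per-second SNR trace against contact pressure
#'
#' Computes [snr_db()] for every whole second of the selected PPG channel and
#' pairs each window with the mean contact pressure (from the force channel
#' via [force_to_mmHg()]) over the same window. Windows in which the channel
#' is constant (e.g. noiseless post-occlusion baseline) receive `-Inf`,
#' representing total signal loss.
#'
#' By default the SNR is computed on the unfiltered channel: out-of-band
#' noise removed by the 12 Hz conditioning filter still counts as noise. Set
#' `filtered = TRUE` to compute it on the 12 Hz zero-phase filtered signal
#' instead.
#'
#' @param record A `ppg_record` (see [simulate_recording()] /
#'   [read_record()]).
#' @param channel `"ir"` or `"red"`.
#' @param filtered Logical; low-pass the channel at 12 Hz first.
#' @param n_harmonics Passed to [snr_db()].
#' @return A data.frame of class `"snr_trace"` with columns `window_start`
#'   (s), `snr_db`, `mean_cp` (mmHg).
#' @export
snr_trace <- function(record, channel = c("ir", "red"), filtered = FALSE,
                      n_harmonics = 6) {
  channel <- match.arg(channel)
  if (is.null(record$force)) {
    stop("invalid record: missing force channel", call. = FALSE)
  }
  fs <- record$fs
  x <- record[[paste0("ppg_", channel)]]
  n <- length(x)
  if (n < 2 * fs) stop("record must be at least 2 s long", call. = FALSE)
  if (filtered) x <- lowpass_zero_phase(x, fs = fs)
  cp <- force_to_mmHg(record$force, record$config$sensor_area_m2)
  nw <- floor(n / fs)
  out <- data.frame(window_start = numeric(nw), snr_db = numeric(nw),
                    mean_cp = numeric(nw))
  for (i in seq_len(nw)) {
    idx <- ((i - 1) * fs + 1):(i * fs)
    out$window_start[i] <- (i - 1)
    out$mean_cp[i] <- mean(cp[idx])
    xi <- x[idx]
    out$snr_db[i] <- if (all(xi == xi[1])) -Inf else
      snr_db(xi, fs, n_harmonics)
  }
  class(out) <- c("snr_trace", "data.frame")
  out
}

#' Locate the optimum contact pressure from an SNR trace
#'
#' Returns the global SNR maximum of the trace; ties are broken to the
#' earliest window.
#'
#' @param trace An [snr_trace()] result (or any data.frame with columns
#'   `snr_db`, `mean_cp`).
#' @return A list of class `"optimum_pressure"` with `max_snr_db`,
#'   `cp_at_max` and `window_index`.
#' @export
find_optimum <- function(trace) {
  if (is.null(trace) || nrow(trace) == 0) {
    stop("empty SNR trace", call. = FALSE)
  }
  i <- which.max(trace$snr_db)  # which.max returns the first of ties
  structure(list(max_snr_db = trace$snr_db[i], cp_at_max = trace$mean_cp[i],
                 window_index = i),
            class = "optimum_pressure")
}

#' @export
print.optimum_pressure <- function(x, ...) {
  cat(sprintf("<optimum_pressure> %.1f dB at %.1f mmHg (window %d)\n",
              x$max_snr_db, x$cp_at_max, x$window_index))
  invisible(x)
}
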