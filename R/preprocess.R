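#' Filter specification
#'
#' Lightweight validated container for the filters used by the pipeline.
#' Defaults mirror the analysis protocol: a 4th-order IIR (Butterworth)
#' low-pass zero-phase filter with 12 Hz cut-off for signal conditioning, and
#' heavy linear-phase FIR smoothers (0.5 Hz, order 5 x fs; 0.1 Hz, order
#' 10 x fs) for envelope work.
#'
#' @param kind `"iir_lowpass_zerophase"` or `"fir_lowpass"`.
#' @param cutoff_hz Cut-off frequency, Hz; `0 < cutoff_hz < fs/2`.
#' @param order Filter order, >= 1.
#' @param fs Sampling rate, Hz.
#' @return A list of class `"ppg_filter_spec"`.
#' @export
filter_spec <- function(kind = c("iir_lowpass_zerophase", "fir_lowpass"),
                        cutoff_hz = 12, order = 4, fs = 1000) {
  kind <- match.arg(kind)
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2)) {
    stop("require 0 < cutoff_hz < fs/2", call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = order, fs = fs),
            class = "ppg_filter_spec")
}

# Butterworth low-pass digital design (bilinear transform with prewarping).
# Returns list(b, a) with a[1] = 1.
butter_lowpass <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  p <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  pd <- (fs2 + p) / (fs2 - p)
  kd <- warped^order / prod(fs2 - p)
  poly_from_roots <- function(r) {
    cf <- 1
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  a <- Re(poly_from_roots(pd))
  b <- Re(kd * poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a / a[1])
}

# single-pass IIR filtering (direct form), zero initial conditions
iir_apply <- function(x, b, a) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# complex frequency response of (b, a) at frequencies f (Hz)
filter_freq_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  num / den
}

#' Zero-phase IIR low-pass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth low-pass
#' filter. Edge transients are suppressed by odd (point-reflected) extension
#' of the signal before filtering, as is standard for `filtfilt`-style
#' filtering. The effective amplitude response is the square of the
#' single-pass magnitude; the phase response is exactly zero, so peak
#' locations of in-band components are preserved.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()] of kind `"iir_lowpass_zerophase"`; or leave
#'   `NULL` and give `cutoff_hz`, `order`, `fs` directly.
#' @param cutoff_hz,order,fs Used when `spec` is `NULL` (defaults 12 Hz,
#'   order 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, spec = NULL, cutoff_hz = 12, order = 4,
                               fs = 1000) {
  if (!is.null(spec)) {
    if (spec$kind != "iir_lowpass_zerophase") {
      stop("`spec` must have kind 'iir_lowpass_zerophase'", call. = FALSE)
    }
    cutoff_hz <- spec$cutoff_hz; order <- spec$order; fs <- spec$fs
  }
  n <- length(x)
  if (n <= 3 * order) {
    stop(sprintf("insufficient data: need more than %d samples", 3 * order),
         call. = FALSE)
  }
  coef <- butter_lowpass(order, cutoff_hz, fs)
  padlen <- min(n - 1, max(3 * order, ceiling(6 * fs / cutoff_hz)))
  # odd extension about the end points
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xe <- c(pre, x, post)
  y <- iir_apply(xe, coef$b, coef$a)
  y <- rev(iir_apply(rev(y), coef$b, coef$a))
  y[(padlen + 1):(padlen + n)]
}

# windowed-sinc (Hamming) linear-phase FIR low-pass; order is forced even so
# the group delay is an integer number of samples
fir_design_lowpass <- function(order, cutoff_hz, fs) {
  if (order %% 2 == 1) order <- order + 1
  m <- order / 2
  k <- 0:order
  fc <- cutoff_hz / fs
  arg <- 2 * pi * fc * (k - m)
  h <- ifelse(k == m, 2 * fc, sin(arg) / (pi * (k - m)))
  w <- 0.54 - 0.46 * cos(2 * pi * k / order)
  h <- h * w
  h / sum(h)
}

# linear convolution via FFT
fft_conv <- function(x, h) {
  L <- length(x) + length(h) - 1
  n2 <- 2^ceiling(log2(L))
  X <- stats::fft(c(x, rep(0, n2 - length(x))))
  H <- stats::fft(c(h, rep(0, n2 - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(L)] / n2
}

#' Linear-phase FIR low-pass filter with delay compensation
#'
#' Applies a windowed-sinc (Hamming) FIR low-pass filter and compensates the
#' group delay so the output is time-aligned with the input. Edges are
#' handled by symmetric (reflected) padding. Odd orders are promoted to the
#' next even order so the delay is an integer.
#'
#' @param x Numeric signal.
#' @param cutoff_hz Cut-off frequency, Hz.
#' @param order Filter order (number of taps minus one); must be smaller than
#'   `length(x)`.
#' @param fs Sampling rate, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
fir_lowpass <- function(x, cutoff_hz, order, fs) {
  n <- length(x)
  if (order >= n) {
    stop(sprintf(
      "insufficient data: filter order %d >= signal length %d", order, n),
      call. = FALSE)
  }
  h <- fir_design_lowpass(order, cutoff_hz, fs)
  half <- (length(h) - 1) / 2
  if (half > 0) {
    pre <- x[min(half + 1, n):2]
    post <- x[(n - 1):max(n - half, 1)]
    # for very short signals reflect repeatedly
    while (length(pre) < half) pre <- c(pre, rev(pre))
    while (length(post) < half) post <- c(post, rev(post))
    xp <- c(pre[seq_len(half)], x, post[seq_len(half)])
  } else xp <- x
  y <- fft_conv(xp, h)
  y[(2 * half + 1):(2 * half + n)]
}
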