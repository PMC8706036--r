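# Shared, lazily built simulation fixtures. Everything is generated in code;
# the cache just avoids re-simulating the same default record in every file.
.fixture_cache <- new.env(parent = emptyenv())

fixture_record <- function(seed = 3L, state = "normotensive") {
  key <- sprintf("rec_%s_%d", state, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_recording(
      generator_config(state = state, seed = seed))
  }
  .fixture_cache[[key]]
}

# segment + filter + cycles + features for the default record's IR channel
fixture_analysis <- function(seed = 3L) {
  key <- sprintf("an_%d", seed)
  if (is.null(.fixture_cache[[key]])) {
    rec <- fixture_record(seed)
    seg <- segment_pulsatile(rec, "ir")
    idx <- seg$start_index:seg$end_index
    xf <- lowpass_zero_phase(rec$ppg_ir[idx], fs = rec$fs)
    cyc <- detect_cycles(xf, rec$fs)
    cp <- force_to_mmHg(rec$force, rec$config$sensor_area_m2)[idx]
    fm <- feature_matrix(xf, cyc, rec$fs, cp = cp)
    .fixture_cache[[key]] <- list(rec = rec, seg = seg, idx = idx, xf = xf,
                                  cycles = cyc, features = fm, cp = cp)
  }
  .fixture_cache[[key]]
}

# clean periodic pulse train (no descent, fixed gain) for fiducial tests
clean_pulse_train <- function(duration_s = 30, fs = 1000, rate = 1,
                              amplitude = 1, baseline = 2, noise_sd = 0,
                              seed = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  x <- baseline + amplitude * bell_pulse(t * rate)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(t), 0, noise_sd)
  }
  list(t = t, x = x, fs = fs)
}

# discrete triangular pulse cycle: rise_s up to `amp`, decay_s back to 0,
# embedded between flat feet; returns signal plus the cycle index bookkeeping
triangle_cycle <- function(rise_s = 0.3, decay_s = 0.7, amp = 1, fs = 1000,
                           foot_s = 0.2) {
  nf <- round(foot_s * fs); nr <- round(rise_s * fs); nd <- round(decay_s * fs)
  x <- c(rep(0, nf),
         seq(0, amp, length.out = nr + 1),
         seq(amp, 0, length.out = nd + 1)[-1],
         rep(0, nf))
  onset <- nf + 1L
  peak <- nf + nr + 1L
  next_onset <- nf + nr + nd + 1L
  list(x = x, fs = fs, onset = onset, peak = peak, next_onset = next_onset)
}
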