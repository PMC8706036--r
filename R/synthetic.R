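#' Smooth bell-shaped pump pulse
#'
#' One period of a smooth unimodal "bell" stroke profile, realised as a
#' periodised Gaussian, min-max normalised so that the value is exactly 0 at
#' phase 0 (and 1^-) and exactly 1 at the mode (phase 0.5). The periodic
#' continuation is continuous and smooth.
#'
#' @param phase Phase within the cycle; values are wrapped into `[0, 1)`.
#' @param width Standard deviation of the underlying Gaussian as a fraction of
#'   the period (default 0.25).
#' @return Pulse amplitude in `[0, 1]`, same length as `phase`.
#' @export
bell_pulse <- function(phase, width = 0.25) {
  if (any(!is.finite(phase)) || !is.finite(width)) {
    stop("`phase` and `width` must be finite", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  p <- phase - floor(phase)
  # periodised Gaussian centred at 0.5; 5 wraps are ample for width <= 0.5
  g <- 0
  for (k in -2:2) g <- g + exp(-0.5 * ((p - 0.5 + k) / width)^2)
  g0 <- sum(exp(-0.5 * ((0 - 0.5 + (-2:2)) / width)^2))
  g1 <- sum(exp(-0.5 * ((0.5 - 0.5 + (-2:2)) / width)^2))
  (g - g0) / (g1 - g0)
}

#' Contact-pressure to pulse-amplitude transfer function
#'
#' Dimensionless gain applied to the pulsatile PPG component as a function of
#' sensor contact pressure. The gain is continuous, strictly increasing on
#' `[0, optimum_cp]` with maximum 1 at `optimum_cp`, strictly decreasing on
#' `[optimum_cp, occlusion_cp]`, and exactly 0 for `cp >= occlusion_cp`
#' (complete vessel occlusion).
#'
#' The shape is the product of a mechanical coupling term,
#' `1 - exp(-cp / coupling_scale)` (optical coupling between sensor and tissue
#' saturates shortly after contact), and a compliance resonance term that
#' plateaus at `plateau` and peaks exponentially (scale `rise_scale` /
#' `fall_scale` mmHg) around the transmural-equilibrium point, where the
#' vessel wall is least stressed and pulsatile volume change is maximal. The
#' falling branch is renormalised to reach exactly 0 at `occlusion_cp`.
#'
#' @param cp Contact pressure, mmHg (vectorised, >= 0).
#' @param optimum_cp Pressure of maximal pulse amplitude, mmHg.
#' @param occlusion_cp Pressure of complete occlusion, mmHg
#'   (`> optimum_cp`).
#' @param plateau Resonance floor reached away from the optimum, as a
#'   fraction of the peak gain (default 0.75: the coupled-but-lightly-loaded
#'   amplitude is already a large fraction of the optimum amplitude).
#' @param rise_scale,fall_scale Exponential scales (mmHg) of the resonance
#'   peak below and above the optimum (defaults 1.5 and 8: the compliance
#'   resonance is sharp, the decay towards occlusion more gradual).
#' @param coupling_scale Contact-coupling saturation scale, mmHg (default 2:
#'   optical contact is established within a few mmHg of touch-down).
#' @return Gain in `[0, 1]`, same length as `cp`.
#' @export
contact_transfer <- function(cp, optimum_cp, occlusion_cp,
                             plateau = 0.75, rise_scale = 1.5, fall_scale = 8,
                             coupling_scale = 2) {
  if (!is.finite(optimum_cp) || !is.finite(occlusion_cp) ||
      optimum_cp <= 0 || optimum_cp >= occlusion_cp) {
    stop("require 0 < optimum_cp < occlusion_cp", call. = FALSE)
  }
  if (any(!is.finite(cp)) || any(cp < 0)) {
    stop("`cp` must be finite and non-negative", call. = FALSE)
  }
  couple <- 1 - exp(-cp / coupling_scale)
  res <- numeric(length(cp))
  lo <- cp <= optimum_cp
  # the "plateau" drifts gently upward with load (progressive mechanical
  # coupling), from 60% of its end value at first contact
  base <- plateau * (0.6 + 0.4 * cp[lo] / optimum_cp)
  res[lo] <- base + (1 - base) * exp(-(optimum_cp - cp[lo]) / rise_scale)
  e1 <- exp(-(occlusion_cp - optimum_cp) / fall_scale)
  hi <- cp > optimum_cp & cp < occlusion_cp
  res[hi] <- (exp(-(cp[hi] - optimum_cp) / fall_scale) - e1) / (1 - e1)
  res[cp >= occlusion_cp] <- 0
  g <- couple * res
  # pin the maximum exactly at the optimum (coupling term is < 1)
  gmax <- (1 - exp(-optimum_cp / coupling_scale))
  out <- g / gmax
  out[cp >= occlusion_cp] <- 0
  pmin(out, 1)
}

#' Generator configuration for a simulated phantom recording
#'
#' Collects all parameters of the synthetic recording: the blood-pressure
#' state, pump rate, sampling rate, actuator descent, contact mechanics,
#' transfer-function landmarks, optics and noise.
#'
#' Defaults mirror the physical protocol being emulated: a 60 BPM (1 Hz)
#' bell-pulse pump stroke, 1 kHz sampling, a sensor descending at
#' 0.03 mm/s into tissue with the vessel at 3 mm depth, and a 1 cm^2 sensor
#' contact area. The default optimum contact pressure maps the state's MAP
#' linearly into the 35-48 mmHg band where optimal sensor pressures are
#' observed empirically; occlusion occurs 20 mmHg above the optimum, and the
#' Hookean contact stiffness is set so that the occlusion pressure is reached
#' at exactly 3 mm indentation.
#'
#' @param state A state label accepted by [bp_state()] or a list with fields
#'   `label`, `sbp`, `dbp`, `map`.
#' @param pulse_rate_hz Pump pulse rate, Hz (default 1).
#' @param fs Sampling rate, Hz (default 1000, minimum 100).
#' @param descent_rate_mm_s Actuator descent rate, mm/s (default 0.03).
#' @param vessel_depth_mm Vessel depth below the surface, mm (default 3).
#' @param sensor_area_m2 Sensor contact area, m^2 (default 1e-4).
#' @param optimum_cp_mmHg Contact pressure of maximal pulse amplitude; default
#'   derived from the state's MAP (see Details).
#' @param occlusion_cp_mmHg Contact pressure of complete occlusion; default
#'   `optimum_cp_mmHg + 20`.
#' @param contact_stiffness Force/indentation slope, N/mm; default chosen so
#'   `occlusion_cp_mmHg` is reached at `vessel_depth_mm` indentation.
#' @param noise_sd White Gaussian noise SD, volts (default 0.02, which yields
#'   a peak per-second SNR near 26 dB for the default optics).
#' @param channel_gains Named vector of per-wavelength pulsatile gains
#'   (default `c(red = 0.8, ir = 1)`: red slightly lower SNR).
#' @param baseline Named vector of per-wavelength DC baselines, volts.
#' @param pulse_width Bell-pulse width as fraction of the period (default
#'   0.25).
#' @param pulse_amplitude_v Peak pulsatile amplitude at the optimum, volts.
#' @param pre_contact_s Seconds of recording before the sensor touches the
#'   surface (default 5).
#' @param seed Integer RNG seed.
#' @return A list of class `"ppg_generator_config"`.
#' @export
generator_config <- function(state = "normotensive",
                             pulse_rate_hz = 1, fs = 1000,
                             descent_rate_mm_s = 0.03, vessel_depth_mm = 3,
                             sensor_area_m2 = 1e-4,
                             optimum_cp_mmHg = NULL, occlusion_cp_mmHg = NULL,
                             contact_stiffness = NULL,
                             noise_sd = 0.02,
                             channel_gains = c(red = 0.8, ir = 1),
                             baseline = c(red = 1.5, ir = 2),
                             pulse_width = 0.25, pulse_amplitude_v = 1,
                             pre_contact_s = 5, seed = 1L) {
  if (is.character(state)) state <- bp_state(state)
  stopifnot(is.list(state), all(c("label", "sbp", "dbp", "map") %in%
                                  names(state)))
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(optimum_cp_mmHg)) {
    # map MAP in [64, 145] linearly into the empirical 35-48 mmHg optimum band
    optimum_cp_mmHg <- 35 + 13 * (state$map - 64) / (145 - 64)
  }
  if (is.null(occlusion_cp_mmHg)) occlusion_cp_mmHg <- optimum_cp_mmHg + 20
  if (!(optimum_cp_mmHg > 0 && optimum_cp_mmHg < occlusion_cp_mmHg)) {
    stop("require 0 < optimum_cp_mmHg < occlusion_cp_mmHg", call. = FALSE)
  }
  if (is.null(contact_stiffness)) {
    contact_stiffness <- occlusion_cp_mmHg * sensor_area_m2 * 133 /
      vessel_depth_mm
  }
  structure(list(
    state = state, pulse_rate_hz = pulse_rate_hz, fs = fs,
    descent_rate_mm_s = descent_rate_mm_s, vessel_depth_mm = vessel_depth_mm,
    sensor_area_m2 = sensor_area_m2,
    optimum_cp_mmHg = optimum_cp_mmHg, occlusion_cp_mmHg = occlusion_cp_mmHg,
    contact_stiffness = contact_stiffness, noise_sd = noise_sd,
    channel_gains = channel_gains, baseline = baseline,
    pulse_width = pulse_width, pulse_amplitude_v = pulse_amplitude_v,
    pre_contact_s = pre_contact_s, seed = as.integer(seed)
  ), class = "ppg_generator_config")
}

#' Simulate a phantom contact-pressure recording
#'
#' Generates a synchronized multi-channel recording: red and infrared PPG,
#' load-cell force and inline blood pressure, sampled on a uniform grid. The
#' sensor descends at the configured rate starting after `pre_contact_s`;
#' force ramps linearly with indentation (Hookean contact), contact pressure
#' follows from [force_to_mmHg()], and the pulsatile PPG amplitude is scaled
#' by [contact_transfer()] so that it peaks at the configured optimum and
#' vanishes at occlusion. White Gaussian noise is added to both optical
#' channels. A `truth` block records the exact cycle onset times, contact and
#' occlusion times, optimum crossing time and the ground-truth pulsatile
#' window (contact to occlusion); the analysis pipeline never reads it.
#'
#' Identical seeds give bit-identical records; the caller's RNG state is left
#' untouched.
#'
#' @param config A [generator_config()].
#' @param duration_s Total record duration, seconds. Default covers the full
#'   descent to vessel depth. Must be long enough for the descent to reach
#'   occlusion, otherwise an error names the required minimum.
#' @return A list of class `"ppg_record"` with fields `t`, `ppg_red`,
#'   `ppg_ir`, `force`, `inline_pressure`, `fs`, `state`, `truth`, `config`.
#' @export
simulate_recording <- function(config = generator_config(),
                               duration_s = NULL) {
  stopifnot(inherits(config, "ppg_generator_config"))
  cfg <- config
  descent_s <- cfg$vessel_depth_mm / cfg$descent_rate_mm_s
  if (is.null(duration_s)) duration_s <- cfg$pre_contact_s + descent_s
  # time at which cp reaches occlusion_cp
  occl_force <- cfg$occlusion_cp_mmHg * cfg$sensor_area_m2 * 133
  occl_depth <- occl_force / cfg$contact_stiffness
  t_occl <- cfg$pre_contact_s + occl_depth / cfg$descent_rate_mm_s
  if (duration_s < t_occl) {
    stop(sprintf(
      "`duration_s` = %.1f s is too short: descent reaches occlusion at %.1f s",
      duration_s, t_occl), call. = FALSE)
  }
  n <- floor(duration_s * cfg$fs) + 1L
  t <- (seq_len(n) - 1L) / cfg$fs

  indent <- pmin(pmax(t - cfg$pre_contact_s, 0) * cfg$descent_rate_mm_s,
                 cfg$vessel_depth_mm)
  force <- cfg$contact_stiffness * indent
  cp <- force_to_mmHg(force, cfg$sensor_area_m2)
  gain <- contact_transfer(cp, cfg$optimum_cp_mmHg, cfg$occlusion_cp_mmHg)

  phase <- t * cfg$pulse_rate_hz
  pulse <- bell_pulse(phase, cfg$pulse_width)
  drive <- cfg$pulse_amplitude_v * gain * pulse

  # restore caller RNG state afterwards
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  noise_red <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else
    numeric(n)
  noise_ir <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else
    numeric(n)

  ppg_red <- cfg$baseline[["red"]] + cfg$channel_gains[["red"]] * drive +
    noise_red
  ppg_ir <- cfg$baseline[["ir"]] + cfg$channel_gains[["ir"]] * drive +
    noise_ir

  inline <- cfg$state$dbp + (cfg$state$sbp - cfg$state$dbp) * pulse

  t_contact <- t[which(force > 0)[1]]
  opt_force <- cfg$optimum_cp_mmHg * cfg$sensor_area_m2 * 133
  t_opt <- cfg$pre_contact_s +
    opt_force / cfg$contact_stiffness / cfg$descent_rate_mm_s
  onsets <- seq(0, duration_s, by = 1 / cfg$pulse_rate_hz)
  onsets_pulsatile <- onsets[onsets >= t_contact & onsets <= t_occl]
  # ground-truth pulsatile window: pulsatile gain at a non-negligible level
  # (>= 5% of its maximum); the pulsatile component is effectively
  # extinguished before the occlusion pressure itself is reached
  pulsatile <- which(gain >= 0.05 * max(gain))
  seg_truth <- c(t[pulsatile[1]], t[pulsatile[length(pulsatile)]])

  structure(list(
    t = t, ppg_red = ppg_red, ppg_ir = ppg_ir, force = force,
    inline_pressure = inline, fs = cfg$fs, state = cfg$state,
    truth = list(
      onset_times = onsets_pulsatile,
      all_onset_times = onsets,
      contact_time = t_contact,
      optimum_time = t_opt,
      occlusion_time = t_occl,
      optimum_cp_mmHg = cfg$optimum_cp_mmHg,
      occlusion_cp_mmHg = cfg$occlusion_cp_mmHg,
      segment_window_s = seg_truth
    ),
    config = cfg
  ), class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf(
    "<ppg_record> %s, fs = %g Hz, %.1f s, %d samples\n",
    x$state$label, x$fs, x$t[length(x$t)], length(x$t)))
  cat(sprintf("  optimum cp %.1f mmHg, occlusion cp %.1f mmHg (truth)\n",
              x$truth$optimum_cp_mmHg, x$truth$occlusion_cp_mmHg))
  invisible(x)
}

# contact pressure series (mmHg) for a record
record_cp <- function(record) {
  force_to_mmHg(record$force, record$config$sensor_area_m2)
}
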