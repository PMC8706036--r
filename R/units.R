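#' Convert sensor force to contact pressure in mmHg
#'
#' Converts a load-cell force reading into the equivalent pressure exerted by
#' the sensor on the tissue, `P = F / (A * k)`, where `A` is the sensor active
#' contact area and `k` converts pascals to mmHg. By default the rounded
#' constant 133 Pa/mmHg is used for parity with published conversion tables; a
#' high-precision mode uses 133.322.
#'
#' @param force_n Force in newtons (vectorised, must be >= 0).
#' @param area_m2 Sensor active contact area in square metres (default
#'   `1e-4`, i.e. 1 cm^2).
#' @param precise Logical; if `TRUE` use 133.322 Pa/mmHg instead of 133.
#' @return Pressure in mmHg.
#' @examples
#' force_to_mmHg(0.5)            # 37.59 mmHg over 1 cm^2
#' force_to_mmHg(1.33)           # 100 mmHg
#' @export
force_to_mmHg <- function(force_n, area_m2 = 1e-4, precise = FALSE) {
  if (!is.numeric(area_m2) || length(area_m2) != 1 || !is.finite(area_m2) ||
      area_m2 <= 0) {
    stop("`area_m2` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(force_n)) || any(force_n < 0)) {
    stop("`force_n` must be finite and non-negative", call. = FALSE)
  }
  k <- if (precise) 133.322 else 133
  force_n / (area_m2 * k)
}

#' Convert kilopascals to mmHg
#'
#' Straight conversion kPa to mmHg (kPa times 7.501). With `truncate = TRUE`
#' the result is integer-truncated, matching how converted pressures are
#' customarily printed in comparison tables (e.g. 10.9 kPa -> 81 mmHg).
#'
#' @param p Pressure in kPa (vectorised, >= 0).
#' @param truncate Logical; truncate towards zero to an integer.
#' @return Pressure in mmHg.
#' @export
kpa_to_mmHg <- function(p, truncate = FALSE) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("`p` must be finite and non-negative", call. = FALSE)
  }
  out <- p * 7.501
  if (truncate) trunc(out) else out
}

#' Convert hectopascals to mmHg
#'
#' Straight conversion hPa to mmHg (hPa divided by 1.333), with optional
#' integer truncation for report parity (e.g. 50 hPa -> 37 mmHg).
#'
#' @inheritParams kpa_to_mmHg
#' @return Pressure in mmHg.
#' @export
hpa_to_mmHg <- function(p, truncate = FALSE) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("`p` must be finite and non-negative", call. = FALSE)
  }
  out <- p / 1.333
  if (truncate) trunc(out) else out
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' One-third-pulse-pressure rule: `MAP = DBP + (SBP - DBP) / 3`, optionally
#' rounded to the nearest integer as customarily reported.
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param dbp Diastolic blood pressure, mmHg; must satisfy `sbp > dbp > 0`.
#' @param round Logical; round to nearest integer (default `TRUE`).
#' @return MAP in mmHg.
#' @examples
#' mean_arterial_pressure(112, 72)   # 85
#' mean_arterial_pressure(171, 132)  # 145
#' @export
mean_arterial_pressure <- function(sbp, dbp, round = TRUE) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop("pressures must be finite", call. = FALSE)
  }
  if (any(dbp <= 0) || any(sbp <= dbp)) {
    stop("require sbp > dbp > 0", call. = FALSE)
  }
  map <- dbp + (sbp - dbp) / 3
  if (round) round(map) else map
}

#' Reference blood-pressure states
#'
#' The four in vitro blood-pressure states used throughout the package:
#' hypotensive, normotensive, stage 1 hypertensive and stage 2 hypertensive,
#' with their systolic/diastolic pressures and the MAP implied by the
#' one-third-pulse-pressure rule.
#'
#' @return A data.frame with columns `label`, `sbp`, `dbp`, `map` (mmHg).
#' @export
pressure_states <- function() {
  st <- data.frame(
    label = c("hypotensive", "normotensive",
              "stage1_hypertensive", "stage2_hypertensive"),
    sbp = c(93, 112, 143, 171),
    dbp = c(50, 72, 104, 132),
    stringsAsFactors = FALSE
  )
  st$map <- mean_arterial_pressure(st$sbp, st$dbp)
  st
}

#' Look up one blood-pressure state
#'
#' @param label One of `"hypotensive"`, `"normotensive"`,
#'   `"stage1_hypertensive"`, `"stage2_hypertensive"`.
#' @return A list with fields `label`, `sbp`, `dbp`, `map`.
#' @export
bp_state <- function(label = c("normotensive", "hypotensive",
                               "stage1_hypertensive", "stage2_hypertensive")) {
  label <- match.arg(label)
  st <- pressure_states()
  as.list(st[st$label == label, , drop = FALSE])
}
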