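#' Write a recording to CSV
#'
#' Canonical wide layout: comment header lines (`# key=value`: fs, state,
#' sbp, dbp, map, seed, sensor_area_m2) followed by columns `t`, `ppg_red`,
#' `ppg_ir`, `force_n`, `inline_pressure_mmhg`. The ground-truth block of
#' simulated records is deliberately not written: the analysis pipeline must
#' never see it.
#'
#' @param record A `ppg_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- if (!is.null(record$config$seed)) record$config$seed else NA
  writeLines(c(
    sprintf("# fs=%.10g", record$fs),
    sprintf("# state=%s", record$state$label),
    sprintf("# sbp=%g", record$state$sbp),
    sprintf("# dbp=%g", record$state$dbp),
    sprintf("# map=%g", record$state$map),
    sprintf("# sensor_area_m2=%.10g", record$config$sensor_area_m2),
    sprintf("# seed=%s", seed)
  ), con)
  df <- data.frame(t = record$t, ppg_red = record$ppg_red,
                   ppg_ir = record$ppg_ir, force_n = record$force,
                   inline_pressure_mmhg = record$inline_pressure)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a recording in long form
#'
#' Long-form export (`t`, `channel`, `value`) for plotting tools; the wide
#' layout of [write_record()] remains the canonical round-trip format.
#'
#' @inheritParams write_record
#' @export
write_record_long <- function(record, path) {
  df <- data.frame(
    t = rep(record$t, 4),
    channel = rep(c("ppg_red", "ppg_ir", "force_n", "inline_pressure_mmhg"),
                  each = length(record$t)),
    value = c(record$ppg_red, record$ppg_ir, record$force,
              record$inline_pressure))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Reads the wide layout written by [write_record()], validates the required
#' columns and checks the header sampling rate against the time-grid spacing
#' to 1 ppm.
#'
#' @param path CSV file path.
#' @return A `ppg_record`.
#' @export
read_record <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "ppg_red", "ppg_ir", "force_n", "inline_pressure_mmhg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  fs <- as.numeric(kv$fs)
  if (!length(fs) || is.na(fs)) {
    stop("format error: missing header field 'fs'", call. = FALSE)
  }
  dt <- diff(df$t)
  if (any(abs(dt * fs - 1) > 1e-6)) {
    stop("format error: time grid inconsistent with header fs (1 ppm)",
         call. = FALSE)
  }
  state <- list(label = kv$state %||% "unknown",
                sbp = as.numeric(kv$sbp %||% NA),
                dbp = as.numeric(kv$dbp %||% NA),
                map = as.numeric(kv$map %||% NA))
  structure(list(
    t = df$t, ppg_red = df$ppg_red, ppg_ir = df$ppg_ir, force = df$force_n,
    inline_pressure = df$inline_pressure_mmhg, fs = fs, state = state,
    truth = NULL,
    config = list(sensor_area_m2 = as.numeric(kv$sensor_area_m2 %||% 1e-4),
                  seed = suppressWarnings(as.integer(kv$seed %||% NA)))
  ), class = "ppg_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on one recording
#'
#' Orchestrates the stages in order: 12 Hz zero-phase conditioning, SNR
#' trace and optimum-pressure detection, pulsatile-segment isolation,
#' cardiac-cycle and fiducial detection, 17-feature extraction, and Spearman
#' feature ranking — for each requested channel. Optionally writes CSV
#' artifacts and a JSON summary.
#'
#' @param record A `ppg_record`.
#' @param channels Channels to analyse (default both).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param state,replica Optional labels propagated into results/outputs.
#' @param verbose Log stage progress with counts.
#' @return A list of class `"ppg_analysis"`, one entry per channel, each
#'   with `snr_trace`, `optimum`, `segment`, `cycles`, `features`,
#'   `ranking`; plus `state`, `replica`, `seed`.
#' @export
run_pipeline <- function(record, channels = c("red", "ir"), out_dir = NULL,
                         state = record$state$label, replica = NA_integer_,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  cp_all <- force_to_mmHg(record$force, record$config$sensor_area_m2)
  for (ch in channels) {
    say("[%s/%s] SNR trace", state, ch)
    tr <- snr_trace(record, channel = ch)
    opt <- find_optimum(tr)
    say("[%s/%s] optimum %.1f dB at %.1f mmHg", state, ch,
        opt$max_snr_db, opt$cp_at_max)
    seg <- segment_pulsatile(record, channel = ch)
    say("[%s/%s] segment %d..%d", state, ch, seg$start_index, seg$end_index)
    idx <- seg$start_index:seg$end_index
    xf <- lowpass_zero_phase(record[[paste0("ppg_", ch)]][idx],
                             fs = record$fs)
    cyc <- detect_cycles(xf, record$fs)
    say("[%s/%s] %d cycles", state, ch, nrow(cyc))
    fm <- feature_matrix(xf, cyc, record$fs, cp = cp_all[idx])
    rk <- rank_features(fm, channel = ch, state = state, replica = replica)
    res[[ch]] <- list(snr_trace = tr, optimum = opt, segment = seg,
                      cycles = cyc, features = fm, ranking = rk)
  }
  out <- structure(c(res, list(state = state, replica = replica,
                               seed = record$config$seed)),
                   class = "ppg_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

# CSV/JSON artifact writer for one analysed record
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("%s_r%s", analysis$state, analysis$replica)
  summary <- list(state = analysis$state, replica = analysis$replica,
                  seed = analysis$seed, channels = list())
  for (ch in intersect(c("red", "ir"), names(analysis))) {
    a <- analysis[[ch]]
    utils::write.csv(a$snr_trace,
                     file.path(out_dir, sprintf("%s_%s_snr.csv", tag, ch)),
                     row.names = FALSE)
    utils::write.csv(a$features,
                     file.path(out_dir, sprintf("%s_%s_features.csv", tag, ch)),
                     row.names = FALSE)
    summary$channels[[ch]] <- list(
      max_snr_db = a$optimum$max_snr_db,
      cp_at_max_mmHg = a$optimum$cp_at_max,
      segment = c(a$segment$start_index, a$segment$end_index),
      n_cycles = nrow(a$cycles),
      rho = as.list(a$ranking$rho),
      ordering = a$ranking$ordering)
  }
  jsonlite::write_json(summary,
                       file.path(out_dir, sprintf("%s_summary.json", tag)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run a replicated multi-state batch
#'
#' Simulates and analyses `replicas` recordings for each blood-pressure
#' state (default: all four), analysing both optical channels — the default
#' 3 replicas x 4 states x 2 channels yields 24 analysed PPG signals.
#'
#' @param states Character vector of state labels.
#' @param replicas Number of replicas per state (default 3).
#' @param base_seed Integer; replica seeds are derived deterministically
#'   from it.
#' @param config_fn Function `(state, seed) -> generator_config`, by default
#'   [generator_config()] with those arguments.
#' @param out_dir Optional artifact directory.
#' @param verbose Log progress.
#' @return A list of class `"ppg_batch"`: `analyses` (list of
#'   `ppg_analysis`), `rankings` (flat list of all per-channel ranking
#'   results), `class_summary`.
#' @export
run_batch <- function(states = pressure_states()$label, replicas = 3,
                      base_seed = 1L,
                      config_fn = function(state, seed)
                        generator_config(state = state, seed = seed),
                      out_dir = NULL, verbose = FALSE) {
  analyses <- list()
  rankings <- list()
  for (si in seq_along(states)) {
    for (r in seq_len(replicas)) {
      seed <- (base_seed + 7919L * (si - 1L) + 104729L * (r - 1L)) %% 2147483647L
      rec <- simulate_recording(config_fn(states[si], seed))
      an <- run_pipeline(rec, out_dir = out_dir, state = states[si],
                         replica = r, verbose = verbose)
      analyses[[sprintf("%s_r%d", states[si], r)]] <- an
      for (ch in c("red", "ir")) {
        rankings[[sprintf("%s_r%d_%s", states[si], r, ch)]] <-
          an[[ch]]$ranking
      }
    }
  }
  structure(list(analyses = analyses, rankings = rankings,
                 class_summary = class_summary(rankings)),
            class = "ppg_batch")
}

#' Command-line interface
#'
#' Minimal CLI with subcommands `simulate` (write a simulated recording to
#' CSV), `analyze` (run the pipeline on a recording CSV) and `convert`
#' (pressure-unit conversions). Used by the `inst/cli/ppgpress` script.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code: 0 success, 2 configuration error, 3 data error.
#' @export
ppg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppgpress <simulate|analyze|convert> ...",
    "  simulate --state <label> --seed <int> --out <csv>",
    "  analyze  --in <csv> --out-dir <dir>",
    "  convert  --from <kpa|hpa|force_n> --value <num> [--truncate]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(2L) }
  cmd <- args[1]; args <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) return(default)
    if (i == length(args)) return(TRUE)
    args[i + 1]
  }
  if (cmd == "simulate") {
    out <- opt("out"); if (is.null(out)) { message(usage); return(2L) }
    rec <- simulate_recording(generator_config(
      state = opt("state", "normotensive"),
      seed = as.integer(opt("seed", "1"))))
    write_record(rec, out)
    message("wrote ", out)
    return(0L)
  }
  if (cmd == "analyze") {
    inp <- opt("in"); if (is.null(inp)) { message(usage); return(2L) }
    rec <- tryCatch(read_record(inp), error = function(e) {
      message("data error: ", conditionMessage(e)); NULL })
    if (is.null(rec)) return(3L)
    run_pipeline(rec, out_dir = opt("out-dir", "."), verbose = TRUE)
    return(0L)
  }
  if (cmd == "convert") {
    v <- as.numeric(opt("value")); from <- opt("from", "kpa")
    tr <- isTRUE(opt("truncate", FALSE)) || identical(opt("truncate"), TRUE)
    res <- switch(from,
                  kpa = kpa_to_mmHg(v, truncate = tr),
                  hpa = hpa_to_mmHg(v, truncate = tr),
                  force_n = force_to_mmHg(v),
                  { message("unknown unit: ", from); return(2L) })
    cat(res, "\n")
    return(0L)
  }
  message(usage)
  2L
}
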