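# End-to-end pipeline on the simulated bench: build the bench, calibrate,
# characterise, flatten, optionally run sensorless correction, and write all
# artifacts (matrices, assay, history, phase TIFFs, resolved config, log).

default_config <- function() {
  list(
    seed = 1L,
    grid_size = 128L,
    out_dir = "aokit-run",
    mirror = list(n_actuators = 69L, layout = "alpao69_like",
                  mode = "gaussian_bumps", influence_sigma = NULL,
                  stroke_limit = 1, stroke_scale = 10),
    sensor = list(mode = "direct_phase", carrier_frequency = 16,
                  lenslet_count = 16L, focal_scale = 20, noise_sigma = 0),
    phase_method = "direct",
    phase_params = list(),
    calibration = list(p = 5L, n_modes = NULL, entry_threshold = 0.005,
                       sv_cutoff = 0.01),
    aberration = list(modes = 5:29, rms = 3.818),
    flatten = list(modes = 5:29, max_iter = 20L, rms_threshold = 0.1,
                   stop_mode = "either", gain = 1,
                   central_fraction = 1),
    sensorless = list(enabled = FALSE, metric = "fourier_power",
                      modes = 4:11,
                      amplitudes = seq(-1.5, 1.5, length.out = 7),
                      workflow = "sequential_immediate",
                      object_grid = 64L),
    isosense = NULL
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (top level or within a section) are rejected; missing keys
#' take the documented defaults.
#'
#' @param config named list of overrides (possibly nested).
#' @return The completed config list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merge1 <- function(def, usr, section) {
    if (is.null(usr)) return(def)
    if (!is.list(def)) return(usr)
    bad <- setdiff(names(usr), names(def))
    if (length(bad))
      stop(sprintf("unknown config key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")))
    for (k in names(usr)) def[[k]] <- usr[[k]]
    def
  }
  out <- defaults
  for (k in names(config)) out[[k]] <- merge1(defaults[[k]], config[[k]], k)
  if (is.null(out$calibration$n_modes))
    out$calibration$n_modes <- out$mirror$n_actuators
  out$seed <- as.integer(out$seed)
  out$grid_size <- as.integer(out$grid_size)
  out$mirror$n_actuators <- as.integer(out$mirror$n_actuators)
  out$calibration$n_modes <- as.integer(out$calibration$n_modes)
  out$calibration$p <- as.integer(out$calibration$p)
  out$flatten$max_iter <- as.integer(out$flatten$max_iter)
  # clip mode lists to the calibrated range so small benches run unchanged
  M <- out$calibration$n_modes
  out$flatten$modes <- intersect(out$flatten$modes, 2:M)
  out$aberration$modes <- intersect(out$aberration$modes, 2:M)
  if (length(out$flatten$modes) == 0 || length(out$aberration$modes) == 0)
    stop("no flatten/aberration modes fall inside the calibrated range 2..",
         M)
  out
}

#' Run the full simulated AO pipeline
#'
#' Bench construction, calibration, control-matrix computation,
#' characterisation, closed-loop flattening of a seeded random aberration,
#' and (optionally) sensorless correction. All artifacts are written under
#' `config$out_dir`: `B.csv`, `C.csv`, `assay.csv`, `flatten_history.csv`,
#' `scan.csv` (if enabled), before/after phase TIFFs, the resolved
#' `config.yaml` and a timing log.
#'
#' @param config list accepted by [validate_config()].
#' @return Invisibly, a list with the in-memory results (`B`, `C`, `assay`,
#'   `history`, `scan`) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  logf <- file.path(out, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat(sprintf("aokit pipeline, seed %d\n", cfg$seed), file = logf)
  tstage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    logline("%s: %.2f s", name, proc.time()[3] - t0)
    val
  }

  g <- cfg$grid_size
  mirror <- tstage("bench", make_sim_mirror(
    cfg$mirror$n_actuators, cfg$mirror$layout, cfg$mirror$mode,
    seed = cfg$seed, grid_size = g,
    influence_sigma = cfg$mirror$influence_sigma,
    stroke_limit = cfg$mirror$stroke_limit,
    stroke_scale = cfg$mirror$stroke_scale))
  sensor <- sim_sensor(cfg$sensor$mode,
                       carrier_frequency = cfg$sensor$carrier_frequency,
                       lenslet_count = cfg$sensor$lenslet_count,
                       focal_scale = cfg$sensor$focal_scale,
                       noise_sigma = cfg$sensor$noise_sigma)
  pp <- cfg$phase_params
  if (cfg$phase_method == "fourier_fringe" && is.null(pp$carrier))
    pp$carrier <- cfg$sensor$carrier_frequency

  B <- tstage("calibrate", calibrate(
    mirror, sensor, cfg$phase_method, p = cfg$calibration$p,
    M = cfg$calibration$n_modes, phase_params = pp,
    seed = cfg$seed))
  save_matrix(B, file.path(out, "B.csv"), meta = list(seed = cfg$seed,
                                                      p = cfg$calibration$p))
  C <- control_matrix(B, cfg$calibration$entry_threshold,
                      cfg$calibration$sv_cutoff)
  save_matrix(C, file.path(out, "C.csv"))
  set_control_matrix(mirror, C)
  mirror$control_matrix$source <- "calibration"

  assay <- tstage("characterise",
                  characterise(mirror, sensor, cfg$phase_method, C,
                               phase_params = pp, seed = cfg$seed))
  utils::write.csv(
    cbind(applied_noll = assay$mode_indices,
          as.data.frame(signif(assay$matrix, 12))),
    file.path(out, "assay.csv"), row.names = FALSE, quote = FALSE)

  ab <- random_aberration(cfg$aberration$modes, cfg$aberration$rms,
                          seed = cfg$seed, grid_size = g)
  ab_map <- synthesize(ab, g)
  write_phase_tiff(ab_map, file.path(out, "phase_before.tiff"))
  hist <- tstage("flatten", flatten(
    mirror, sensor, cfg$phase_method, C, modes = cfg$flatten$modes,
    max_iter = cfg$flatten$max_iter, rms_threshold = cfg$flatten$rms_threshold,
    stop_mode = cfg$flatten$stop_mode, gain = cfg$flatten$gain,
    aberration = ab_map, central_fraction = cfg$flatten$central_fraction,
    phase_params = pp, seed = cfg$seed))
  utils::write.csv(data.frame(iteration = hist$history$iteration,
                              rms_rad = signif(hist$history$rms, 12)),
                   file.path(out, "flatten_history.csv"), row.names = FALSE,
                   quote = FALSE)
  write_phase_tiff(phase_add(ab_map, mirror_surface(mirror)),
                   file.path(out, "phase_after.tiff"))
  logline("flatten final RMS: %.6g rad (%s)", hist$final_rms, hist$stop_reason)

  scan <- NULL
  if (isTRUE(cfg$sensorless$enabled)) {
    og <- cfg$sensorless$object_grid
    scope <- sim_scope(bead_object(og, seed = cfg$seed))
    sab <- random_aberration(cfg$sensorless$modes, 0.8, seed = cfg$seed + 1L,
                             grid_size = og)
    scan <- tstage("sensorless", run_sensorless(
      bench_image_fn(scope, sab, og),
      scan_plan(cfg$sensorless$modes, cfg$sensorless$amplitudes),
      metric = cfg$sensorless$metric, workflow = cfg$sensorless$workflow))
    utils::write.csv(summary(scan), file.path(out, "scan.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cfg$isosense)) {
    iso <- cfg$isosense
    pat <- isosense_pattern(iso$shape, iso$pixel_size, iso$w, iso$gamma,
                            iso$diagonal_convention %||% "radius")
    tiff::writeTIFF(pat, file.path(out, "isosense.tiff"), bits.per.sample = 16)
  }
  invisible(list(B = B, C = C, assay = assay, history = hist, scan = scan,
                 out_dir = out))
}
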