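#' Default ROI definitions for the phantom's function measurements
#'
#' Ellipsoidal-coordinate regions of interest anchored on the phantom's
#' left ventricle, given in mm in the volume-centred frame.  `core_frac`
#' bounds a region that is blood at every cardiac phase; `region_frac`
#' bounds the integration region for fractional-volume measurement (blood
#' plus inner myocardium at every phase); `myo_band` is a shell that stays
#' within the myocardial wall at every phase.  Fractions are relative to
#' the diastolic blood-pool semi-axes.
#'
#' @param center LV blood-pool centre (mm).
#' @param semi_diastole diastolic LV blood-pool semi-axes (mm).
#' @param core_frac,region_frac,myo_band normalized elliptical radii.
#' @return list passed to [run_pipeline()] / [measure_function()].
#' @export
lv_roi_spec <- function(center = c(-18, 0, -12),
                        semi_diastole = c(24, 24, 33),
                        core_frac = 0.5, region_frac = 1.3,
                        myo_band = c(1.32, 1.42)) {
  list(center = center, semi_diastole = semi_diastole,
       core_frac = core_frac, region_frac = region_frac,
       myo_band = myo_band)
}

# normalized elliptical radius of every voxel w.r.t. an ROI spec
roi_radius <- function(grid, roi) {
  ax <- grid_axis_mm(grid)
  qx <- ((ax - roi$center[1]) / roi$semi_diastole[1])^2
  qy <- ((ax - roi$center[2]) / roi$semi_diastole[2])^2
  qz <- ((ax - roi$center[3]) / roi$semi_diastole[3])^2
  sqrt(outer(outer(qx, qy, "+"), qz, "+"))
}

#' Partial-volume-aware blood-pool volume from a 3D image
#'
#' Estimates the blood volume inside the ROI's integration region by the
#' fractional-intensity sum
#' \eqn{\sum_R (I - I_{myo}) / (I_{blood} - I_{myo}) \cdot v_{vox}},
#' where the blood and myocardium reference intensities are measured from
#' the image itself (core region and myocardial band of the ROI).  The
#' unclamped sum is conserved under the point-spread blurring of an
#' undersampled reconstruction, which makes the estimate robust to the
#' partial-volume effect at coarse desk-scale grids.
#'
#' @param volume real 3D array.
#' @param grid the [voxel_grid()] of `volume`.
#' @param roi an [lv_roi_spec()].
#' @return list with `volume_ml`, `i_blood`, `i_myo`.
#' @export
blood_volume_fractional <- function(volume, grid, roi = lv_roi_spec()) {
  q <- roi_radius(grid, roi)
  core <- volume[q <= roi$core_frac]
  myo <- volume[q >= roi$myo_band[1] & q <= roi$myo_band[2]]
  if (length(core) < 4 || length(myo) < 4)
    stop("ROI too small for this grid")
  i_blood <- mean(core)
  i_myo <- mean(myo)
  if (i_blood <= i_myo) stop("no blood-myocardium contrast in ROI")
  region <- volume[q <= roi$region_frac]
  vol <- sum(region - i_myo) / (i_blood - i_myo) * grid$spacing_mm^3 / 1000
  list(volume_ml = max(vol, 0), i_blood = i_blood, i_myo = i_myo)
}

#' Pipeline configuration
#'
#' Desk-scale defaults: a 48-voxel isotropic grid over a 160 mm FOV,
#' 45 s of free-running acquisition at TR 5.94 ms with 18 readouts per
#' interleave, heart rate 66 bpm (RR 909 ms) with 3% RR jitter,
#' respiration 4 s / 8 mm, 2 coils, 72 ms cardiac bins (12 bins at RR
#' 909 ms) and 2 respiratory bins, TV weights 0.005.
#'
#' @param grid_n,fov_mm reconstruction grid.
#' @param scan_time_s free-running acquisition duration.
#' @param TR_ms,readouts_per_shot sequence timing.
#' @param n_coils receive coils.
#' @param cardiac_period_ms,rr_jitter_frac,resp_period_ms,resp_amplitude_mm,contraction_frac phantom motion parameters (see [dynamic_phantom()]).
#' @param noise_sigma_ref complex-noise sigma at 401 Hz/px.
#' @param bandwidth_hz_per_px receiver bandwidth.
#' @param bin_width_ms,n_resp binning parameters.
#' @param recon a [recon_config()].
#' @param roi an [lv_roi_spec()].
#' @param seed global seed; fans out to per-stage seeds by fixed offsets.
#' @param output_dir optional directory for persisted intermediates.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_n = 48, fov_mm = 160, scan_time_s = 45,
                            TR_ms = 5.94, readouts_per_shot = 18,
                            n_coils = 2, cardiac_period_ms = 909,
                            rr_jitter_frac = 0.03, resp_period_ms = 4000,
                            resp_amplitude_mm = 8, contraction_frac = 0.25,
                            noise_sigma_ref = 17, bandwidth_hz_per_px = 401,
                            bin_width_ms = 72, n_resp = 2,
                            recon = recon_config(outer_iterations = 5,
                                                 inner_cg_iterations = 2),
                            roi = lv_roi_spec(), seed = 1,
                            output_dir = NULL) {
  n_shots <- max(3L, floor(scan_time_s * 1000 / (TR_ms * readouts_per_shot)))
  structure(list(grid_n = grid_n, fov_mm = fov_mm, scan_time_s = scan_time_s,
                 TR_ms = TR_ms, readouts_per_shot = readouts_per_shot,
                 n_shots = n_shots, n_coils = n_coils,
                 cardiac_period_ms = cardiac_period_ms,
                 rr_jitter_frac = rr_jitter_frac,
                 resp_period_ms = resp_period_ms,
                 resp_amplitude_mm = resp_amplitude_mm,
                 contraction_frac = contraction_frac,
                 noise_sigma_ref = noise_sigma_ref,
                 bandwidth_hz_per_px = bandwidth_hz_per_px,
                 bin_width_ms = bin_width_ms, n_resp = n_resp,
                 recon = recon, roi = roi, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Simulate the raw data stage of a pipeline configuration
#'
#' Builds the phantom (seeded beat table), trajectory, coils and raw
#' k-space for a [pipeline_config()].  Exposed separately so gating and
#' reconstruction stages can be exercised against the same inputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `phantom`, `traj`, `grid`, `coils`, `raw`.
#' @export
simulate_stage <- function(config) {
  grid <- voxel_grid(config$grid_n, config$fov_mm)
  design <- acquisition_design(
    Np = config$grid_n, Nim = 1, Ufactor = 1,
    readouts_per_shot = config$readouts_per_shot, TR_ms = config$TR_ms,
    Nshots = config$n_shots, samples_per_readout = config$grid_n)
  traj <- generate_phyllotaxis(design)
  phantom <- dynamic_phantom(
    cardiac_period_ms = config$cardiac_period_ms,
    rr_jitter_frac = config$rr_jitter_frac,
    resp_period_ms = config$resp_period_ms,
    resp_amplitude_mm = config$resp_amplitude_mm,
    contraction_frac = config$contraction_frac,
    duration_ms = config$scan_time_s * 1000 + 10000,
    seed = config$seed + 101L)
  coils <- coil_profiles(grid, config$n_coils)
  raw <- simulate_kspace(phantom, traj, grid, coils,
                         noise_sigma_ref = config$noise_sigma_ref,
                         bandwidth_hz_per_px = config$bandwidth_hz_per_px,
                         seed = config$seed + 202L,
                         os = config$recon$os, width = config$recon$width)
  list(phantom = phantom, traj = traj, grid = grid, coils = coils, raw = raw)
}

#' Function and image-quality measurements on a motion-resolved image
#'
#' Quantitative analysis in the end-expiration respiratory state (bin 1):
#' per-cardiac-bin LV blood volume by partial-volume-aware counting, ED
#' and ES identification as the volume extremes, ejection fraction,
#' blood-myocardium contrast ratio and Laplacian-variance sharpness on a
#' mid-ventricular short-axis reformat, and image SNR against an air ROI.
#'
#' @param rec a `freerun_image5d`.
#' @param roi an [lv_roi_spec()].
#' @param resp_state respiratory bin analysed (default 1, end expiration).
#' @return list with `volumes_ml` (per cardiac bin), `edv_ml`, `esv_ml`,
#'   `ef_percent`, `ed_bin`, `es_bin`, `cr`, `lapv`, `snr`.
#' @export
measure_function <- function(rec, roi = lv_roi_spec(), resp_state = 1) {
  stopifnot(inherits(rec, "freerun_image5d"))
  grid <- rec$grid
  n_card <- dim(rec$values)[4]
  vols <- numeric(n_card)
  for (b in seq_len(n_card)) {
    vol3 <- abs(rec$values[, , , b, resp_state])
    dim(vol3) <- rep(grid$n, 3L)
    vols[b] <- blood_volume_fractional(vol3, grid, roi)$volume_ml
  }
  ed_bin <- which.max(vols); es_bin <- which.min(vols)
  edv <- vols[ed_bin]; esv <- vols[es_bin]
  ef <- ejection_fraction(edv, min(esv, edv))

  # mid-ventricular short-axis reformat at end diastole for image quality
  vol_ed <- abs(rec$values[, , , ed_bin, resp_state])
  dim(vol_ed) <- rep(grid$n, 3L)
  sax <- slice_plane(origin = roi$center, normal = c(0, 0, 1),
                     extent_mm = c(grid$fov_mm * 0.75, grid$fov_mm * 0.75),
                     spacing_mm = 2, thickness_mm = 8)
  sl <- reformat_slab(vol_ed, grid$spacing_mm, sax)
  uu <- seq(-sax$extent_mm[1] / 2, sax$extent_mm[1] / 2, by = sax$spacing_mm)
  ru <- sqrt(outer(uu^2, uu^2, "+"))   # in-plane radius from LV centre
  blood_px <- sl[ru <= roi$core_frac * min(roi$semi_diastole[1:2])]
  myo_px <- sl[ru >= roi$myo_band[1] * roi$semi_diastole[1] &
                 ru <= roi$myo_band[2] * roi$semi_diastole[1]]
  cr <- tryCatch(contrast_ratio(blood_px, myo_px), error = function(e) NA_real_)
  # sharpness over a patch centred on the heart
  ctr <- which.min(abs(uu))
  hw <- min(ctr - 1, floor(40 / sax$spacing_mm))
  patch <- sl[(ctr - hw):(ctr + hw), (ctr - hw):(ctr + hw)]
  lapv <- laplacian_variance(patch)
  # air ROI: slice corners, outside the torso
  corner_px <- sl[sqrt(outer((uu - roi$center[1])^2,
                             (uu - roi$center[2])^2, "+")) > 0.9 * grid$fov_mm / 2]
  snr <- tryCatch(snr_measure(blood_px, corner_px), error = function(e) NA_real_)
  list(volumes_ml = vols, edv_ml = edv, esv_ml = esv, ef_percent = ef,
       ed_bin = ed_bin, es_bin = es_bin, cr = cr, lapv = lapv, snr = snr)
}

#' Run the full free-running 5D pipeline on the numerical phantom
#'
#' simulate -> self-gate -> bin -> estimate sensitivities -> reconstruct
#' -> measure.  Deterministic: identical configurations (including seed)
#' produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param keep_intermediates return the raw data, gating products and
#'   reconstruction alongside the report.
#' @return an object of class `freerun_report`: measured function,
#'   ground-truth comparison, agreement statistics between measured and
#'   analytic per-bin volumes, gating summary, undersampling summary, and
#'   the configuration; with `keep_intermediates`, also the stage outputs.
#' @export
run_pipeline <- function(config, keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_label <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  sim <- stage_label("simulate", simulate_stage(config))
  gate <- stage_label("selfgating",
                      self_gate(sim$raw, bin_width_ms = config$bin_width_ms,
                                n_resp = config$n_resp))
  maps <- stage_label("sensitivities", {
    if (config$n_coils == 1)
      suppressWarnings(estimate_sensitivities(sim$raw))
    else estimate_sensitivities(sim$raw, os = config$recon$os,
                                width = config$recon$width)
  })
  rec <- stage_label("recon",
                     reconstruct_5d(sim$raw, gate$bins, maps, config$recon))
  meas <- stage_label("metrics", measure_function(rec, config$roi))

  # analytic ground truth at the accepted bin centres
  ef_truth <- ground_truth_ef(sim$phantom)
  n_card <- gate$bins$n_cardiac_bins
  phase_centres <- ((seq_len(n_card) - 0.5) * gate$bins$bin_width_ms) /
    gate$bins$median_rr_ms
  truth_vols <- vapply(pmin(phase_centres, 0.999), function(p)
    ground_truth_volumes(sim$phantom, p)[["lv_blood"]], numeric(1))
  agree <- agreement_stats(meas$volumes_ml, truth_vols)

  rc <- config$recon
  run_log <- c(
    sprintf("grid %d^3, FOV %g mm, scan %g s, TR %g ms, %d readouts/shot",
            config$grid_n, config$fov_mm, config$scan_time_s, config$TR_ms,
            config$readouts_per_shot),
    sprintf("phantom: RR %g ms (jitter %g), resp %g ms / %g mm, contraction %g",
            config$cardiac_period_ms, config$rr_jitter_frac,
            config$resp_period_ms, config$resp_amplitude_mm,
            config$contraction_frac),
    sprintf("noise sigma_ref %g at %g Hz/px", config$noise_sigma_ref,
            config$bandwidth_hz_per_px),
    sprintf("gating: cardiac band 0.7-3 Hz, resp band 0.08-0.7 Hz, bin %g ms, %d resp bins, RR reject 20%%",
            config$bin_width_ms, config$n_resp),
    sprintf("recon: lambda_c %g, lambda_r %g, rho %g, %d outer x %d CG, tol %g, os %g, kernel width %g",
            rc$lambda_c, rc$lambda_r, rc$admm_rho, rc$outer_iterations,
            rc$inner_cg_iterations, rc$tolerance, rc$os, rc$width),
    sprintf("analysis: end-expiration bin, ROI region %g, myo band [%g, %g], seed %d",
            config$roi$region_frac, config$roi$myo_band[1],
            config$roi$myo_band[2], config$seed))
  report <- structure(list(
    ef_percent = meas$ef_percent, ef_truth_percent = ef_truth,
    ef_error = meas$ef_percent - ef_truth,
    edv_ml = meas$edv_ml, esv_ml = meas$esv_ml,
    volumes_ml = meas$volumes_ml, truth_volumes_ml = truth_vols,
    volume_agreement = agree,
    cr = meas$cr, lapv = meas$lapv, snr = meas$snr,
    n_cardiac_bins = n_card, n_resp = gate$bins$n_resp,
    median_rr_ms = gate$bins$median_rr_ms,
    accepted_frac = mean(!is.na(gate$bins$cardiac_bin)),
    undersampling = undersampling_report(gate$bins, config$grid_n),
    objective = rec$objective,
    log = run_log,
    config = config), class = "freerun_report")
  if (!is.null(config$output_dir))
    write_report(report, rec, config$output_dir)
  if (keep_intermediates) {
    report$sim <- sim; report$gate <- gate; report$rec <- rec
    report$maps <- maps
  }
  report
}

#' @export
print.freerun_report <- function(x, ...) {
  cat(sprintf(paste0("5D free-running pipeline report\n",
                     "  EF measured %.1f%% (truth %.1f%%, error %+.1f points)\n",
                     "  EDV %.1f mL, ESV %.1f mL; %d cardiac x %d respiratory bins\n",
                     "  median RR %.0f ms, %.1f%% readouts accepted\n",
                     "  CR %.2f, LAPV %.3g, SNR %.1f\n"),
              x$ef_percent, x$ef_truth_percent, x$ef_error,
              x$edv_ml, x$esv_ml, x$n_cardiac_bins, x$n_resp,
              x$median_rr_ms, 100 * x$accepted_frac,
              x$cr, x$lapv, x$snr))
  invisible(x)
}

# persist report + end-expiration cine as NIfTI/CSV/JSON
write_report <- function(report, rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cine <- abs(rec$values[, , , , 1])
  RNifti::writeNifti(RNifti::asNifti(cine, pixdim = rep(rec$voxel_spacing_mm, 3)),
                     file.path(dir, "cine_end_expiration.nii.gz"))
  utils::write.csv(data.frame(bin = seq_along(report$volumes_ml),
                              measured_ml = report$volumes_ml,
                              truth_ml = report$truth_volumes_ml),
                   file.path(dir, "volumes.csv"), row.names = FALSE)
  utils::write.csv(report$undersampling,
                   file.path(dir, "undersampling.csv"), row.names = FALSE)
  scalars <- report[c("ef_percent", "ef_truth_percent", "ef_error", "edv_ml",
                      "esv_ml", "cr", "lapv", "snr", "n_cardiac_bins",
                      "n_resp", "median_rr_ms", "accepted_frac")]
  jsonlite::write_json(c(scalars, list(volume_agreement = report$volume_agreement)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Named desk-scale study configurations
#'
#' Three registered fixtures: `"tiny"` (24-voxel grid, 1 coil, ~12 s of
#' data - a smoke-test scene), `"standard"` (48-voxel grid, 2 coils, 45 s
#' - the default study conditions), and `"stress"` (standard with 5% RR
#' jitter).
#'
#' @param name fixture name.
#' @param seed global seed.
#' @return a [pipeline_config()].
#' @export
fixture_config <- function(name = c("tiny", "standard", "stress"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    tiny = pipeline_config(grid_n = 24, scan_time_s = 12, n_coils = 1,
                           bin_width_ms = 100,
                           recon = recon_config(outer_iterations = 5,
                                                inner_cg_iterations = 4),
                           seed = seed),
    standard = pipeline_config(seed = seed),
    stress = pipeline_config(rr_jitter_frac = 0.05, seed = seed))
}

#' Generate an on-disk fixture bundle
#'
#' Simulates the named scene and writes the trajectory (CSV), raw k-space
#' (RDS), and ground-truth tables (CSV) to `dir`.
#'
#' @param name one of `"tiny"`, `"standard"`, `"stress"`.
#' @param seed global seed.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
generate_fixture <- function(name, seed = 1, dir = tempfile(name)) {
  config <- fixture_config(name, seed)
  sim <- simulate_stage(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(sim$traj, file.path(dir, "trajectory.csv"))
  saveRDS(sim$raw, file.path(dir, "raw_kspace.rds"))
  utils::write.csv(sim$phantom$beats, file.path(dir, "beats.csv"),
                   row.names = FALSE)
  t_ro <- sim$traj$timestamps_ms
  truth <- data.frame(t_ms = t_ro,
                      beat = cardiac_phase(sim$phantom, t_ro)$beat,
                      phase = cardiac_phase(sim$phantom, t_ro)$phase,
                      resp_mm = resp_displacement(sim$phantom, t_ro))
  utils::write.csv(truth, file.path(dir, "motion_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(name = name, seed = seed,
                            ef_truth = ground_truth_ef(sim$phantom)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Cardiac bin accuracy against the phantom's ground truth
#'
#' Fraction of accepted readouts whose assigned cardiac bin matches the
#' bin implied by the simulator's true beat table.  Detected triggers sit
#' at the self-gating signal's systolic maximum, a fixed latency after the
#' beat onset; that constant latency is estimated (median offset between
#' detected triggers and the preceding true beat onset) and removed before
#' comparison.  An off-by-one bin at a bin edge counts as correct.
#'
#' @param bins a `freerun_bins`.
#' @param phantom the generating [dynamic_phantom()].
#' @param traj the trajectory that was binned.
#' @return fraction in [0, 1].
#' @export
gating_accuracy <- function(bins, phantom, traj) {
  stopifnot(inherits(bins, "freerun_bins"), inherits(phantom, "freerun_phantom"))
  onsets <- phantom$beats$onset_ms
  tb <- pmax(findInterval(bins$trigger_times_ms, onsets), 1)
  latency <- stats::median(bins$trigger_times_ms - onsets[tb])
  t_ro <- traj$timestamps_ms
  shifted_onsets <- onsets + latency
  b <- findInterval(t_ro, shifted_onsets)
  valid <- b >= 1 & b < length(shifted_onsets)
  true_phase <- t_ro - shifted_onsets[pmax(b, 1)]
  true_bin <- floor(true_phase / bins$bin_width_ms) + 1
  ok <- valid & !is.na(bins$cardiac_bin) &
    true_bin >= 1 & true_bin <= bins$n_cardiac_bins
  if (!any(ok)) return(0)
  mean(abs(bins$cardiac_bin[ok] - true_bin[ok]) <= 1)
}
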