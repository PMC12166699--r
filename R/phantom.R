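#' Isotropic voxel grid specification
#'
#' @param n matrix size per dimension (even positive integer, or length-3
#'   vector with equal entries).
#' @param fov_mm field of view in mm (scalar, or length-3 equal entries).
#' @return list with `n`, `fov_mm`, `spacing_mm`.
#' @export
voxel_grid <- function(n, fov_mm = 160) {
  if (length(n) == 3) {
    if (length(unique(n)) != 1) stop("grid must be isotropic (equal matrix size)")
    n <- n[1]
  }
  if (length(fov_mm) == 3) {
    if (length(unique(fov_mm)) != 1) stop("grid must be isotropic (equal FOV)")
    fov_mm <- fov_mm[1]
  }
  n <- as.integer(n)
  if (n < 2 || n %% 2L != 0L) stop("n must be an even integer >= 2")
  if (!is.finite(fov_mm) || fov_mm <= 0) stop("fov_mm must be positive")
  list(n = n, fov_mm = fov_mm, spacing_mm = fov_mm / n)
}

# centred voxel-centre coordinates in mm
grid_axis_mm <- function(grid) {
  (seq_len(grid$n) - 1 - grid$n %/% 2) * grid$spacing_mm
}

# Painting order matters: chambers later in the list overwrite earlier
# ones.  The RV and LA blood pools are painted before the LV epicardial
# shell, so the shell provides the interventricular septum and the
# atrioventricular wall; the LV blood pool is painted last and is
# therefore never clipped, keeping its rasterized volume equal to the
# analytic ellipsoid volume.  The shell is static (the epicardial surface
# moves far less than the endocardium), so ventricular contraction
# automatically thickens the wall at systole.
# `respiratory` marks chambers that translate head-foot with breathing;
# the torso background stays still, as the chest wall does.
default_chambers <- function() {
  list(
    list(name = "background",    center = c(0, 0, 0),      semi = c(70, 70, 74),       intensity = 0.15, dynamic = "static",    respiratory = FALSE),
    list(name = "rv_blood",      center = c(22, 6, -12),   semi = c(20, 17, 28),       intensity = 3.8,  dynamic = "ventricle", respiratory = TRUE),
    list(name = "la_blood",      center = c(-16, 10, 40),  semi = c(15, 13, 11),       intensity = 3.8,  dynamic = "atrium",    respiratory = TRUE),
    list(name = "lv_myocardium", center = c(-18, 0, -12),  semi = c(37.2, 37.2, 51.2), intensity = 1.0,  dynamic = "static",    respiratory = TRUE),
    list(name = "lv_blood",      center = c(-18, 0, -12),  semi = c(24, 24, 33),       intensity = 4.0,  dynamic = "ventricle", respiratory = TRUE)
  )
}

chamber_respiratory <- function(ch) {
  if (!is.null(ch$respiratory)) isTRUE(ch$respiratory)
  else !identical(ch$name, "background")
}

#' Dynamic multi-chamber heart phantom
#'
#' A numerical stand-in for a beating, breathing heart: ellipsoidal
#' chambers (LV blood pool inside an LV myocardial shell, RV blood pool,
#' LA blood pool, and a static torso background) with bSSFP-like
#' blood/myocardium contrast.  Ventricular semi-axes contract by a
#' raised-cosine waveform occupying `systole_frac` of each RR interval; the
#' atrium expands in anti-phase.  Respiration is a bulk head-foot (z)
#' translation with an end-expiratory plateau.  Beat-to-beat RR variability
#' is multiplicative Gaussian jitter (truncated at 3 sigma), drawn once at
#' construction from `seed`, so every downstream quantity has an exact
#' per-beat ground truth.
#'
#' With contraction fraction \eqn{f} applied to all three semi-axes the
#' ejection fraction is analytically \eqn{1 - (1-f)^3}; the default
#' \eqn{f = 0.25} gives EF = 57.8%, a healthy adult value.
#'
#' @param cardiac_period_ms mean RR interval (default 1000 ms, 60 bpm).
#' @param rr_jitter_frac per-beat RR standard deviation as a fraction of
#'   the mean (default 0.03).
#' @param resp_period_ms respiratory period (default 4000 ms).
#' @param resp_amplitude_mm peak head-foot translation (default 8 mm).
#' @param contraction_frac peak fractional reduction of ventricular
#'   semi-axes at systole, in [0, 0.5] (default 0.25).
#' @param systole_frac fraction of the RR interval occupied by the
#'   systolic contraction (default 0.4: raised-cosine shoulders around an
#'   end-systolic plateau of ~35% of the window, i.e. ~130 ms at 66 bpm).
#' @param resp_shape_power exponent sharpening the end-expiratory plateau
#'   of the respiratory waveform (default 2; 1 gives a pure sinusoid).
#' @param atrial_expansion_frac peak fractional increase of atrial
#'   semi-axes at ventricular systole (default 0.15).
#' @param duration_ms length of the precomputed beat table (default 120 s).
#' @param seed RNG seed for the beat table.
#' @param chambers optional replacement chamber list (see
#'   `freerun5d:::default_chambers` for the layout).
#' @return an object of class `freerun_phantom`.
#' @export
dynamic_phantom <- function(cardiac_period_ms = 1000, rr_jitter_frac = 0.03,
                            resp_period_ms = 4000, resp_amplitude_mm = 8,
                            contraction_frac = 0.25, systole_frac = 0.4,
                            resp_shape_power = 2,
                            atrial_expansion_frac = 0.15,
                            duration_ms = 120000, seed = 1,
                            chambers = default_chambers()) {
  if (contraction_frac < 0 || contraction_frac > 0.5)
    stop("contraction_frac must lie in [0, 0.5]")
  if (any(vapply(chambers, function(ch) any(ch$semi <= 0), logical(1))))
    stop("all semi-axes must be positive")
  if (any(vapply(chambers, function(ch) ch$intensity < 0, logical(1))))
    stop("intensities must be non-negative")
  # beat table: onsets + per-beat RR with truncated multiplicative jitter
  rng <- local({ set.seed(seed); function(n) stats::rnorm(n) })
  n_beats <- ceiling(duration_ms / (cardiac_period_ms * (1 - 3 * rr_jitter_frac))) + 2
  z <- pmin(pmax(rng(n_beats), -3), 3)
  rr <- cardiac_period_ms * (1 + rr_jitter_frac * z)
  onset <- c(0, cumsum(rr))[seq_len(n_beats)]
  beats <- data.frame(onset_ms = onset, rr_ms = rr)
  structure(list(chambers = chambers,
                 cardiac_period_ms = cardiac_period_ms,
                 rr_jitter_frac = rr_jitter_frac,
                 resp_period_ms = resp_period_ms,
                 resp_amplitude_mm = resp_amplitude_mm,
                 contraction_frac = contraction_frac,
                 systole_frac = systole_frac,
                 resp_shape_power = resp_shape_power,
                 atrial_expansion_frac = atrial_expansion_frac,
                 duration_ms = duration_ms, seed = seed,
                 beats = beats),
            class = "freerun_phantom")
}

#' @export
print.freerun_phantom <- function(x, ...) {
  cat(sprintf(paste0("Dynamic heart phantom: RR %g ms (jitter %.1f%%), ",
                     "respiration %g ms / %g mm,\n  contraction %.2f ",
                     "(analytic EF %.1f%%), %d chambers, %d beats tabled\n"),
              x$cardiac_period_ms, 100 * x$rr_jitter_frac, x$resp_period_ms,
              x$resp_amplitude_mm, x$contraction_frac,
              ground_truth_ef(x), length(x$chambers), nrow(x$beats)))
  invisible(x)
}

#' Cardiac phase, beat index, and respiratory displacement at given times
#'
#' Ground-truth accessors into the phantom's precomputed beat table and
#' respiratory waveform, used by the self-gating validation.
#'
#' @param phantom a [dynamic_phantom()].
#' @param t_ms vector of times (ms from scan start).
#' @return `cardiac_phase`: data.frame with `beat` (1-based index),
#'   `phase` in [0,1), and `phase_ms` since beat onset.
#'   `resp_displacement`: numeric vector of z-displacements in mm
#'   (0 = end expiration).
#' @export
cardiac_phase <- function(phantom, t_ms) {
  b <- findInterval(t_ms, phantom$beats$onset_ms)
  b[b < 1] <- 1L
  if (max(b) > nrow(phantom$beats))
    stop("time beyond the phantom's tabled duration")
  dt <- t_ms - phantom$beats$onset_ms[b]
  data.frame(beat = b, phase = dt / phantom$beats$rr_ms[b], phase_ms = dt)
}

#' @rdname cardiac_phase
#' @export
resp_displacement <- function(phantom, t_ms) {
  if (phantom$resp_amplitude_mm == 0) return(rep(0, length(t_ms)))
  base <- 0.5 - 0.5 * cos(2 * pi * t_ms / phantom$resp_period_ms)
  phantom$resp_amplitude_mm * base^phantom$resp_shape_power
}

# Systolic contraction waveform, 0 (diastole) .. 1 (end systole): a
# raised-cosine rise and fall around an end-systolic plateau occupying
# 35% of the systolic window.  The plateau models the isovolumic phases,
# during which ventricular volume holds near its minimum; it also makes
# the end-systolic volume recoverable from finite-width cardiac bins
# (~50-100 ms), as it is in vivo.
contraction_wave <- function(phase, systole_frac, plateau_frac = 0.35) {
  w <- numeric(length(phase))
  u <- phase / systole_frac
  edge <- (1 - plateau_frac) / 2
  rise <- phase >= 0 & u < edge
  flat <- u >= edge & u <= 1 - edge
  fall <- u > 1 - edge & u < 1
  w[rise] <- 0.5 * (1 - cos(pi * u[rise] / edge))
  w[flat] <- 1
  w[fall] <- 0.5 * (1 - cos(pi * (1 - u[fall]) / edge))
  w
}

# per-chamber semi-axis scale factor at contraction-wave value w
chamber_scale <- function(chamber, w, phantom) {
  switch(chamber$dynamic,
         static = 1,
         ventricle = 1 - phantom$contraction_frac * w,
         # the shell contracts half as much: wall thickens at systole
         myocardium = 1 - 0.5 * phantom$contraction_frac * w,
         # atrium fills while the ventricle ejects; no contraction, no
         # volume exchange, so a non-contracting heart is fully static
         atrium = if (phantom$contraction_frac > 0)
           1 + phantom$atrial_expansion_frac * w else 1,
         stop("unknown chamber dynamic: ", chamber$dynamic))
}

#' Rasterize the phantom at a given time
#'
#' Paints the chambers (in list order, later chambers overwriting earlier
#' ones) onto an isotropic voxel grid at the cardiac phase and respiratory
#' displacement of time `t_ms`.  Respiration is a rigid z-translation of
#' the heart chambers (those flagged `respiratory`); the torso background
#' stays still.  Deterministic: depends only on the phantom (including its
#' seeded beat table) and `t_ms`.
#'
#' @param phantom a [dynamic_phantom()].
#' @param t_ms time in ms.
#' @param grid a [voxel_grid()].
#' @param cardiac_phase_override,resp_override optionally pin the cardiac
#'   phase (in [0,1)) and/or respiratory displacement (mm) instead of
#'   deriving them from `t_ms`.
#' @return real 3D array (n x n x n).
#' @export
render_frame <- function(phantom, t_ms, grid,
                         cardiac_phase_override = NULL,
                         resp_override = NULL) {
  p <- if (is.null(cardiac_phase_override))
    cardiac_phase(phantom, t_ms)$phase else cardiac_phase_override
  dz <- if (is.null(resp_override))
    resp_displacement(phantom, t_ms) else resp_override
  w <- contraction_wave(p, phantom$systole_frac)
  ax <- grid_axis_mm(grid)
  img <- array(0, rep(grid$n, 3L))
  for (ch in phantom$chambers) {
    s <- ch$semi * chamber_scale(ch, w, phantom)
    dz_ch <- if (chamber_respiratory(ch)) dz else 0
    qx <- ((ax - ch$center[1]) / s[1])^2
    qy <- ((ax - ch$center[2]) / s[2])^2
    qz <- ((ax - (ch$center[3] + dz_ch)) / s[3])^2
    inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    img[inside] <- ch$intensity
  }
  img
}

#' Analytic chamber volumes and ejection fraction
#'
#' Ellipsoid volumes \eqn{(4/3)\pi abc} (mL) at a given cardiac phase,
#' without rasterization error.
#'
#' @param phantom a [dynamic_phantom()].
#' @param phase cardiac phase in [0, 1).
#' @return named numeric vector of volumes in mL (background excluded).
#' @export
ground_truth_volumes <- function(phantom, phase) {
  w <- contraction_wave(phase, phantom$systole_frac)
  vols <- vapply(phantom$chambers, function(ch) {
    s <- ch$semi * chamber_scale(ch, w, phantom)
    (4 / 3) * pi * prod(s) / 1000
  }, numeric(1))
  names(vols) <- vapply(phantom$chambers, `[[`, character(1), "name")
  vols[names(vols) != "background"]
}

#' @rdname ground_truth_volumes
#' @return `ground_truth_ef`: the ventricular ejection fraction in percent,
#'   analytically \eqn{100 (1 - (1-f)^3)} for contraction fraction `f`.
#' @export
ground_truth_ef <- function(phantom) {
  100 * (1 - (1 - phantom$contraction_frac)^3)
}

#' Smooth complex coil-sensitivity profiles
#'
#' Gaussian-magnitude receive profiles centred at distinct positions on a
#' ring around the z axis, each with a mild linear phase ramp, normalized
#' so the voxelwise root-sum-of-squares is exactly 1.
#'
#' @param grid a [voxel_grid()].
#' @param n_coils number of coils, 1 to 8 (default 2).  With a single coil
#'   a uniform unit map is returned.
#' @return complex array (n, n, n, n_coils).
#' @export
coil_profiles <- function(grid, n_coils = 2) {
  if (n_coils < 1 || n_coils > 8) stop("n_coils must be between 1 and 8")
  n <- grid$n
  ax <- grid_axis_mm(grid)
  maps <- array(0i, c(n, n, n, n_coils))
  if (n_coils == 1) {
    maps[, , , 1] <- 1 + 0i
    return(maps)
  }
  X <- array(rep(ax, times = n * n), rep(n, 3))
  Y <- array(rep(rep(ax, each = n), times = n), rep(n, 3))
  Z <- array(rep(ax, each = n * n), rep(n, 3))
  ring_r <- 0.55 * grid$fov_mm / 2
  width <- 0.8 * grid$fov_mm
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    cx <- ring_r * cos(th); cy <- ring_r * sin(th)
    cz <- ifelse(c %% 2 == 0, 0.2, -0.2) * grid$fov_mm / 2
    mag <- exp(-(((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) / (2 * width^2)))
    ph <- 2 * pi * 0.15 * (cos(th) * X + sin(th) * Y) / grid$fov_mm
    maps[, , , c] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(abs(maps)^2, 1:3, sum))
  for (c in seq_len(n_coils)) maps[, , , c] <- maps[, , , c] / rss
  maps
}

#' Simulate multi-coil radial k-space of the dynamic phantom
#'
#' Forward-models every readout of the trajectory through the non-uniform
#' Fourier transform of (coil profile x phantom frame at the readout time)
#' and adds i.i.d. complex Gaussian noise whose standard deviation follows
#' the receiver-bandwidth law \eqn{\sigma =
#' \sigma_{ref}\sqrt{BW / BW_{ref}}} with reference bandwidth 401 Hz/px.
#'
#' For speed the cardiac phase is quantized to `n_phase` rendered frames
#' per beat (default 32, i.e. ~31 ms at RR 1000 ms, finer than the 50 ms
#' bin width), while the respiratory z-translation of the heart is applied
#' exactly per readout: the frame is split into the static background and
#' a heart term (their painted difference), and the heart term's spectrum
#' is multiplied by the shift phase ramp.  This decomposition is exact for
#' the rendered frames because chambers that breathe are painted after the
#' static ones.
#'
#' @param phantom a [dynamic_phantom()].
#' @param traj a [generate_phyllotaxis()] trajectory.
#' @param grid a [voxel_grid()].
#' @param coils complex coil maps from [coil_profiles()] (or compatible).
#' @param noise_sigma_ref complex-noise standard deviation at the reference
#'   bandwidth (default 0 = noiseless).
#' @param bandwidth_hz_per_px receiver bandwidth (default 401).
#' @param seed RNG seed for the noise.
#' @param n_phase cardiac-phase quantization (frames per beat).
#' @param os,width NUFFT oversampling and kernel width.
#' @return an object of class `freerun_raw`: list with `samples` (complex
#'   array sample x readout x coil), `traj`, `grid`, `coils`,
#'   `noise_sigma`, `bandwidth_hz_per_px`, `n_coils`.
#' @export
simulate_kspace <- function(phantom, traj, grid, coils = coil_profiles(grid, 2),
                            noise_sigma_ref = 0, bandwidth_hz_per_px = 401,
                            seed = 1, n_phase = 32, os = 1.5, width = 4) {
  stopifnot(inherits(phantom, "freerun_phantom"),
            inherits(traj, "freerun_trajectory"))
  if (!identical(dim(coils)[1:3], as.integer(rep(grid$n, 3))))
    stop("coil maps do not match the grid")
  n_coils <- dim(coils)[4]
  n_ro <- nrow(traj$directions)
  ns <- traj$design$samples_per_readout
  t_ro <- traj$timestamps_ms
  static <- phantom$contraction_frac == 0 && phantom$resp_amplitude_mm == 0

  cp <- cardiac_phase(phantom, t_ro)
  pq <- if (static) rep(0, n_ro) else (floor(cp$phase * n_phase) + 0.5) / n_phase
  dz <- resp_displacement(phantom, t_ro)

  # the static/respiratory split requires static chambers painted first
  resp_flags <- vapply(phantom$chambers, chamber_respiratory, logical(1))
  if (is.unsorted(resp_flags))   # a static chamber after a breathing one
    stop("static chambers must precede breathing chambers in the paint order")
  bg_phantom <- phantom
  bg_phantom$chambers <- phantom$chambers[!resp_flags]
  bg <- if (any(!resp_flags))
    render_frame(bg_phantom, 0, grid, cardiac_phase_override = 0,
                 resp_override = 0)
  else array(0, rep(grid$n, 3L))

  kall <- trajectory_kspace(traj)
  dz_vox <- dz / grid$spacing_mm
  kz <- matrix(kall$coords[, 3], nrow = ns)       # sample x readout
  ramp <- exp(-2i * pi * kz * rep(dz_vox, each = ns))
  samples <- array(0i, c(ns, n_ro, n_coils))
  # static background: one forward evaluation on all readouts per coil
  plan_all <- nufft_plan(kall$coords, grid$n, os = os, width = width)
  for (c in seq_len(n_coils)) {
    sbg <- nufft_forward(plan_all, coils[, , , c] * bg)
    samples[, , c] <- matrix(sbg, nrow = ns)
  }
  # heart term per quantized cardiac phase, shifted by the resp phase ramp
  for (p in unique(pq)) {
    ro_idx <- which(pq == p)
    frame <- render_frame(phantom, 0, grid,
                          cardiac_phase_override = p, resp_override = 0)
    delta <- frame - bg
    flat_idx <- as.vector(outer(seq_len(ns), (ro_idx - 1) * ns, "+"))
    plan <- nufft_plan(kall$coords[flat_idx, , drop = FALSE], grid$n,
                       os = os, width = width)
    for (c in seq_len(n_coils)) {
      s <- nufft_forward(plan, coils[, , , c] * delta)
      samples[, ro_idx, c] <- samples[, ro_idx, c] +
        matrix(s, nrow = ns) * ramp[, ro_idx, drop = FALSE]
    }
  }
  sigma <- noise_sigma_ref * sqrt(bandwidth_hz_per_px / 401)
  if (sigma > 0) {
    set.seed(seed)
    ntot <- length(samples)
    samples <- samples + sigma * (stats::rnorm(ntot) + 1i * stats::rnorm(ntot))
  }
  structure(list(samples = samples, traj = traj, grid = grid, coils = coils,
                 noise_sigma = sigma,
                 bandwidth_hz_per_px = bandwidth_hz_per_px,
                 n_coils = n_coils, seed = seed),
            class = "freerun_raw")
}

#' @export
print.freerun_raw <- function(x, ...) {
  cat(sprintf("Raw radial k-space: %d samples x %d readouts x %d coils, sigma %.3g (BW %g Hz/px)\n",
              dim(x$samples)[1], dim(x$samples)[2], x$n_coils,
              x$noise_sigma, x$bandwidth_hz_per_px))
  invisible(x)
}

#' Density-compensated gridding (adjoint) reconstruction
#'
#' Motion-averaged root-sum-of-squares gridded image from all readouts:
#' the adjoint NUFFT of density-compensated samples, per coil, combined by
#' root-sum-of-squares.  Used for initialisation, coil-map estimation, and
#' as the plain (non-iterative) reference image.
#'
#' @param raw a [simulate_kspace()] result.
#' @param readout_idx optional readout subset.
#' @param os,width NUFFT parameters.
#' @return real 3D array.
#' @export
gridded_recon <- function(raw, readout_idx = NULL, os = 1.5, width = 4) {
  stopifnot(inherits(raw, "freerun_raw"))
  if (is.null(readout_idx)) readout_idx <- seq_len(dim(raw$samples)[2])
  ns <- dim(raw$samples)[1]
  kk <- trajectory_kspace(raw$traj, readout_idx)
  w <- density_weights(kk$coords, length(readout_idx), ns)
  plan <- nufft_plan(kk$coords, raw$grid$n, os = os, width = width)
  acc <- array(0, rep(raw$grid$n, 3L))
  for (c in seq_len(raw$n_coils)) {
    s <- as.vector(raw$samples[, readout_idx, c])
    img <- nufft_adjoint(plan, w * s)
    acc <- acc + abs(img)^2
  }
  sqrt(acc)
}
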