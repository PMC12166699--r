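#' Acquisition design for a free-running 3D radial phyllotaxis scan
#'
#' Bundles the geometric and timing parameters of the continuously running
#' 3D radial balanced-SSFP acquisition: matrix size, the number of
#' motion-resolved 3D images the data will be split into, the per-image
#' Nyquist fraction, the interleave (shot) structure with one
#' superior-inferior (SI) self-navigation readout leading every interleave,
#' and the repetition time.
#'
#' If `Nshots` is not given it is derived from the line budget: the Nyquist
#' line count for (`Np`, `Nim`, `Ufactor`) is divided into interleaves of
#' `readouts_per_shot` readouts (ceiling division), then rounded up to the
#' next admissible interleave count (see [select_admissible_interleaves()]).
#'
#' @param Np acquisition matrix size per dimension (voxels).
#' @param Nim number of motion-resolved 3D images (cardiac x respiratory).
#' @param Ufactor fraction of the Nyquist limit per image, in (0, 1].
#' @param readouts_per_shot readouts per interleave, including the leading
#'   SI readout (default 18, giving one SI readout per ~107 ms at
#'   TR = 5.94 ms).
#' @param TR_ms repetition time in milliseconds.
#' @param Nshots number of interleaves; derived from the line budget when
#'   `NULL`.
#' @param samples_per_readout k-space points along each spoke (a full
#'   diameter); defaults to `Np`.
#' @param admissible predicate used when deriving `Nshots`; see
#'   [select_admissible_interleaves()].
#' @return an object of class `acquisition_design`.
#' @export
acquisition_design <- function(Np = 160, Nim = 80, Ufactor = 0.05,
                               readouts_per_shot = 18, TR_ms = 5.94,
                               Nshots = NULL, samples_per_readout = Np,
                               admissible = NULL) {
  check_pos_int <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x))
      stop(sprintf("%s must be a positive integer", nm))
  }
  check_pos_int(Np, "Np"); check_pos_int(Nim, "Nim")
  check_pos_int(readouts_per_shot, "readouts_per_shot")
  check_pos_int(samples_per_readout, "samples_per_readout")
  if (!is.finite(Ufactor) || Ufactor <= 0 || Ufactor > 1)
    stop("Ufactor must lie in (0, 1]")
  if (!is.finite(TR_ms) || TR_ms <= 0) stop("TR_ms must be positive")
  if (is.null(Nshots)) {
    Nlim <- nyquist_line_count(Np, Nim, Ufactor)
    minimum <- required_interleaves(Nlim, readouts_per_shot)
    Nshots <- select_admissible_interleaves(minimum, admissible)
  } else {
    check_pos_int(Nshots, "Nshots")
  }
  structure(list(Np = as.integer(Np), Nim = as.integer(Nim),
                 Ufactor = Ufactor,
                 readouts_per_shot = as.integer(readouts_per_shot),
                 TR_ms = TR_ms, Nshots = as.integer(Nshots),
                 samples_per_readout = as.integer(samples_per_readout)),
            class = "acquisition_design")
}

#' @export
print.acquisition_design <- function(x, ...) {
  ts <- timing_summary(x)
  cat(sprintf(paste0("Free-running acquisition design\n",
                     "  matrix %d^3, %d motion-resolved images, %.3g%% Nyquist per image\n",
                     "  %d interleaves x %d readouts = %d readouts, TR %.3g ms\n",
                     "  SI interval %.4g ms, scan time %.1f s\n"),
              x$Np, x$Nim, 100 * x$Ufactor, x$Nshots, x$readouts_per_shot,
              x$Nshots * x$readouts_per_shot, x$TR_ms,
              ts$si_interval_ms, ts$scan_time_s))
  invisible(x)
}

#' Nyquist line budget for undersampled 3D radial imaging
#'
#' Smallest integer number of radial lines strictly exceeding
#' \eqn{(\pi/4) N_p^2 N_{im} U}: the total line count needed so that each
#' of the `Nim` motion-resolved images holds a fraction `Ufactor` of the
#' radial Nyquist criterion for matrix size `Np`.
#'
#' @param Np acquisition matrix size per dimension.
#' @param Nim number of motion-resolved images.
#' @param Ufactor per-image fraction of Nyquist, in (0, 1].
#' @return positive integer line count.
#' @examples
#' nyquist_line_count(160, 80, 0.05)  # 80425
#' @export
nyquist_line_count <- function(Np, Nim, Ufactor) {
  for (v in list(Np = Np, Nim = Nim, Ufactor = Ufactor)) {
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      stop("all arguments must be positive finite scalars")
  }
  if (Ufactor > 1) stop("Ufactor must lie in (0, 1]")
  v <- (pi / 4) * Np^2 * Nim * Ufactor
  as.integer(floor(v) + 1)   # smallest integer strictly greater than v
}

#' Minimal interleave count covering a line budget
#'
#' @param Nlim total number of radial lines required.
#' @param readouts_per_shot readouts per interleave (including the SI
#'   readout).
#' @return `ceiling(Nlim / readouts_per_shot)`.
#' @export
required_interleaves <- function(Nlim, readouts_per_shot) {
  if (length(Nlim) != 1 || !is.finite(Nlim) || Nlim <= 0)
    stop("Nlim must be a positive scalar")
  if (length(readouts_per_shot) != 1 || !is.finite(readouts_per_shot) ||
      readouts_per_shot <= 0)
    stop("readouts_per_shot must be a positive scalar")
  as.integer(ceiling(Nlim / readouts_per_shot))
}

#' Smallest admissible interleave count at or above a minimum
#'
#' Not every phyllotaxis interleave count yields a continuous, smooth
#' gradient ordering (a requirement for low eddy-current behaviour), so the
#' scanner implementation restricts the interleave count to an admissible
#' subset.  The admissibility criterion itself is injected as a predicate;
#' the default accepts every integer and emits a warning that no smoothness
#' screening was applied.
#'
#' @param minimum smallest acceptable interleave count.
#' @param admissible `NULL` (accept all, with a warning) or a predicate
#'   `function(n) -> logical`.
#' @param window maximum search span above `minimum` before giving up.
#' @return smallest integer `>= minimum` accepted by the predicate.
#' @examples
#' select_admissible_interleaves(4446, function(n) n == 4529)  # 4529
#' @export
select_admissible_interleaves <- function(minimum, admissible = NULL,
                                          window = 10000L) {
  if (length(minimum) != 1 || !is.finite(minimum) || minimum <= 0 ||
      minimum != round(minimum))
    stop("minimum must be a positive integer")
  if (is.null(admissible)) {
    warning("no admissibility predicate supplied; accepting the minimum ",
            "interleave count without eddy-current smoothness screening")
    return(as.integer(minimum))
  }
  for (n in seq.int(minimum, minimum + window)) {
    if (isTRUE(admissible(n))) return(as.integer(n))
  }
  stop("no admissible interleave count found within the search window")
}

#' Generate the 3D radial spiral phyllotaxis trajectory
#'
#' Places `Nshots * readouts_per_shot` spoke directions on the unit
#' hemisphere using the spiral phyllotaxis rule: point `n` receives azimuth
#' `n * 137.50776` degrees (the golden angle) and a polar position whose
#' cosine descends linearly from the pole (+z) towards the equator, which
#' yields uniform solid-angle density for full-diameter spokes.  The points
#' are regrouped into interleaves by stride (`interleave s` takes points
#' `s, s + Nshots, s + 2 Nshots, ...`), and the first readout of every
#' interleave is replaced by the +z superior-inferior (SI) self-navigation
#' direction.  Readouts are timestamped `k * TR_ms` in acquisition order.
#'
#' @param design an [acquisition_design()].
#' @return an object of class `freerun_trajectory`: list with `directions`
#'   (N x 3 unit vectors), `timestamps_ms`, `shot_index` (1-based),
#'   `is_si` (logical), and the generating `design`.
#' @export
generate_phyllotaxis <- function(design) {
  stopifnot(inherits(design, "acquisition_design"))
  if (design$readouts_per_shot < 2)
    stop("readouts_per_shot must be >= 2 (no room for imaging readouts)")
  Nshots <- design$Nshots
  per <- design$readouts_per_shot
  N <- Nshots * per
  golden_deg <- 137.50776
  idx <- seq_len(N) - 1
  z <- 1 - (idx + 0.5) / N               # pole -> equator, equal-area
  phi <- idx * golden_deg * pi / 180
  st <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), z)
  # regroup by interleave stride: shot s <- points s, s+Nshots, ...
  shot <- rep(seq_len(Nshots), each = per)
  within <- rep(seq_len(per), times = Nshots)
  spiral_idx <- (within - 1) * Nshots + shot   # 1-based into dirs
  dirs <- dirs[spiral_idx, , drop = FALSE]
  is_si <- within == 1L
  dirs[is_si, ] <- rep(c(0, 0, 1), each = sum(is_si))
  structure(list(directions = dirs,
                 timestamps_ms = (seq_len(N) - 1) * design$TR_ms,
                 shot_index = shot,
                 is_si = is_si,
                 design = design),
            class = "freerun_trajectory")
}

#' @export
print.freerun_trajectory <- function(x, ...) {
  cat(sprintf("Phyllotaxis trajectory: %d readouts (%d SI) in %d interleaves, TR %.3g ms\n",
              nrow(x$directions), sum(x$is_si),
              length(unique(x$shot_index)), x$design$TR_ms))
  invisible(x)
}

#' SI-interval and total-scan-time arithmetic
#'
#' @param design an [acquisition_design()].
#' @return list with `si_interval_ms` (`readouts_per_shot * TR_ms`, the
#'   self-navigation sampling interval) and `scan_time_s`
#'   (`Nshots * readouts_per_shot * TR_ms / 1000`).
#' @export
timing_summary <- function(design) {
  stopifnot(inherits(design, "acquisition_design"))
  list(si_interval_ms = design$readouts_per_shot * design$TR_ms,
       scan_time_s = design$Nshots * design$readouts_per_shot *
         design$TR_ms / 1000)
}

#' K-space sample coordinates for a trajectory
#'
#' Expands spoke directions into per-sample coordinates along full
#' diameters, in cycles/voxel of the reconstruction grid: radii span
#' `[-0.5, 0.5)` in `samples_per_readout` steps.
#'
#' @param traj a [generate_phyllotaxis()] trajectory.
#' @param readout_idx optional subset of readout indices.
#' @return list with `coords` ((n_readouts*n_samples) x 3 matrix, sample
#'   index varying fastest), `radii` (signed radius per sample), and
#'   `n_samples` per readout.
#' @export
trajectory_kspace <- function(traj, readout_idx = NULL) {
  stopifnot(inherits(traj, "freerun_trajectory"))
  if (is.null(readout_idx)) readout_idx <- seq_len(nrow(traj$directions))
  ns <- traj$design$samples_per_readout
  r <- (seq_len(ns) - 1 - ns %/% 2) / ns        # [-0.5, 0.5)
  d <- traj$directions[readout_idx, , drop = FALSE]
  coords <- cbind(as.vector(outer(r, d[, 1])),
                  as.vector(outer(r, d[, 2])),
                  as.vector(outer(r, d[, 3])))
  list(coords = coords, radii = rep(r, times = length(readout_idx)),
       n_samples = ns)
}

#' Write / read a trajectory as plain-text CSV
#'
#' Column layout: `dir_x, dir_y, dir_z, timestamp_ms, shot_index, is_si`.
#'
#' @param traj a `freerun_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `freerun_trajectory` (design fields reconstructed from the
#'   stored header line).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "freerun_trajectory"))
  d <- traj$design
  hdr <- sprintf("# Np=%d Nim=%d Ufactor=%g readouts_per_shot=%d TR_ms=%g Nshots=%d samples_per_readout=%d",
                 d$Np, d$Nim, d$Ufactor, d$readouts_per_shot, d$TR_ms,
                 d$Nshots, d$samples_per_readout)
  df <- data.frame(dir_x = traj$directions[, 1], dir_y = traj$directions[, 2],
                   dir_z = traj$directions[, 3],
                   timestamp_ms = traj$timestamps_ms,
                   shot_index = traj$shot_index, is_si = traj$is_si)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.csv(path, skip = 1)
  design <- acquisition_design(Np = vals[["Np"]], Nim = vals[["Nim"]],
                               Ufactor = vals[["Ufactor"]],
                               readouts_per_shot = vals[["readouts_per_shot"]],
                               TR_ms = vals[["TR_ms"]], Nshots = vals[["Nshots"]],
                               samples_per_readout = vals[["samples_per_readout"]])
  structure(list(directions = as.matrix(df[, 1:3]),
                 timestamps_ms = df$timestamp_ms,
                 shot_index = df$shot_index,
                 is_si = as.logical(df$is_si),
                 design = design),
            class = "freerun_trajectory")
}
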