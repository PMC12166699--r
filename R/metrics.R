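#' Oblique slice-plane specification
#'
#' @param origin plane centre in mm (length-3, volume-centred coordinates).
#' @param normal plane normal (unit length after normalization).
#' @param u_axis,v_axis in-plane axes; orthonormalized against the normal
#'   (Gram-Schmidt).  Defaults pick any pair orthogonal to the normal.
#' @param extent_mm in-plane extent (length-2, mm).
#' @param spacing_mm in-plane sampling step (mm).
#' @param thickness_mm slab thickness to average over (default 8 mm, the
#'   reformatted slice thickness matched to 2D cine protocols).
#' @return an object of class `slice_plane`.
#' @export
slice_plane <- function(origin = c(0, 0, 0), normal = c(0, 0, 1),
                        u_axis = NULL, v_axis = NULL,
                        extent_mm = c(120, 120), spacing_mm = 2,
                        thickness_mm = 8) {
  if (thickness_mm <= 0) stop("thickness must be positive")
  normal <- normal / sqrt(sum(normal^2))
  if (is.null(u_axis)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u_axis <- seed - sum(seed * normal) * normal
  } else {
    u_axis <- u_axis - sum(u_axis * normal) * normal
  }
  u_axis <- u_axis / sqrt(sum(u_axis^2))
  if (is.null(v_axis)) {
    v_axis <- c(normal[2] * u_axis[3] - normal[3] * u_axis[2],
                normal[3] * u_axis[1] - normal[1] * u_axis[3],
                normal[1] * u_axis[2] - normal[2] * u_axis[1])
  } else {
    v_axis <- v_axis - sum(v_axis * normal) * normal -
      sum(v_axis * u_axis) * u_axis
    v_axis <- v_axis / sqrt(sum(v_axis^2))
  }
  structure(list(origin = origin, normal = normal, u_axis = u_axis,
                 v_axis = v_axis, extent_mm = extent_mm,
                 spacing_mm = spacing_mm, thickness_mm = thickness_mm),
            class = "slice_plane")
}

# vectorized trilinear interpolation of a 3D volume at mm coordinates
trilinear <- function(volume, spacing_mm, pts) {
  n <- dim(volume)
  # mm -> 1-based fractional voxel index (centred grid)
  fx <- pts[, 1] / spacing_mm + n[1] %/% 2 + 1
  fy <- pts[, 2] / spacing_mm + n[2] %/% 2 + 1
  fz <- pts[, 3] / spacing_mm + n[3] %/% 2 + 1
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  dx <- fx - i0; dy <- fy - j0; dz <- fz - k0
  out <- numeric(nrow(pts))
  valid <- i0 >= 1 & i0 < n[1] & j0 >= 1 & j0 < n[2] & k0 >= 1 & k0 < n[3]
  if (!any(valid)) return(out)
  gi <- function(i, j, k) volume[cbind(i, j, k)]
  i0 <- i0[valid]; j0 <- j0[valid]; k0 <- k0[valid]
  dx <- dx[valid]; dy <- dy[valid]; dz <- dz[valid]
  out[valid] <-
    gi(i0,     j0,     k0)     * (1 - dx) * (1 - dy) * (1 - dz) +
    gi(i0 + 1, j0,     k0)     * dx       * (1 - dy) * (1 - dz) +
    gi(i0,     j0 + 1, k0)     * (1 - dx) * dy       * (1 - dz) +
    gi(i0 + 1, j0 + 1, k0)     * dx       * dy       * (1 - dz) +
    gi(i0,     j0,     k0 + 1) * (1 - dx) * (1 - dy) * dz +
    gi(i0 + 1, j0,     k0 + 1) * dx       * (1 - dy) * dz +
    gi(i0,     j0 + 1, k0 + 1) * (1 - dx) * dy       * dz +
    gi(i0 + 1, j0 + 1, k0 + 1) * dx       * dy       * dz
  out
}

#' Reformat a 3D volume to an oblique thick-slab 2D slice
#'
#' Trilinear sampling on the plane at the requested in-plane spacing,
#' averaged over equispaced sub-planes across the slab thickness
#' (`ceiling(thickness / voxel)` sub-planes), emulating the reformatting
#' of an isotropic whole-heart volume into thick 2D cine slices.
#'
#' @param volume real 3D array (isotropic voxels).
#' @param voxel_spacing_mm voxel size of `volume` in mm.
#' @param plane a [slice_plane()].
#' @return 2D matrix (u along rows, v along columns) with attributes
#'   `spacing_mm` and `plane`.
#' @export
reformat_slab <- function(volume, voxel_spacing_mm, plane) {
  stopifnot(inherits(plane, "slice_plane"))
  n <- dim(volume)
  half_fov <- (n - 1) / 2 * voxel_spacing_mm
  if (any(abs(plane$origin) > half_fov))
    stop("plane origin lies outside the volume")
  us <- seq(-plane$extent_mm[1] / 2, plane$extent_mm[1] / 2,
            by = plane$spacing_mm)
  vs <- seq(-plane$extent_mm[2] / 2, plane$extent_mm[2] / 2,
            by = plane$spacing_mm)
  nsub <- max(1L, ceiling(plane$thickness_mm / voxel_spacing_mm))
  offs <- if (nsub == 1) 0 else
    seq(-plane$thickness_mm / 2, plane$thickness_mm / 2, length.out = nsub)
  uv <- as.matrix(expand.grid(u = us, v = vs))
  acc <- numeric(nrow(uv))
  for (o in offs) {
    pts <- cbind(plane$origin[1] + uv[, 1] * plane$u_axis[1] +
                   uv[, 2] * plane$v_axis[1] + o * plane$normal[1],
                 plane$origin[2] + uv[, 1] * plane$u_axis[2] +
                   uv[, 2] * plane$v_axis[2] + o * plane$normal[2],
                 plane$origin[3] + uv[, 1] * plane$u_axis[3] +
                   uv[, 2] * plane$v_axis[3] + o * plane$normal[3])
    acc <- acc + trilinear(volume, voxel_spacing_mm, pts)
  }
  out <- matrix(acc / length(offs), nrow = length(us))
  attr(out, "spacing_mm") <- plane$spacing_mm
  attr(out, "plane") <- plane
  out
}

#' Blood-myocardium contrast ratio
#'
#' Ratio of the mean signal in the blood-pool ROI to the mean signal in
#' the myocardium ROI.
#'
#' @param blood_roi,myocardium_roi numeric vectors of ROI pixel values.
#' @return positive scalar.
#' @export
contrast_ratio <- function(blood_roi, myocardium_roi) {
  if (length(blood_roi) == 0 || length(myocardium_roi) == 0)
    stop("both ROIs must be non-empty")
  m <- mean(myocardium_roi)
  if (m == 0) stop("undefined contrast ratio: myocardium mean is zero")
  mean(blood_roi) / m
}

#' Signal-to-noise ratio from signal and noise ROIs
#'
#' Mean signal divided by the standard deviation (denominator n-1) of a
#' noise-only ROI.
#'
#' @param signal_roi,noise_roi numeric vectors of ROI pixel values.
#' @return scalar.
#' @export
snr_measure <- function(signal_roi, noise_roi) {
  if (length(noise_roi) < 2) stop("noise ROI needs at least 2 pixels")
  s <- stats::sd(noise_roi)
  if (s == 0) stop("undefined SNR: noise ROI has zero variance")
  mean(signal_roi) / s
}

#' Variance of the Laplacian: an image-sharpness metric
#'
#' Variance (denominator n-1) of the ROI patch convolved with a 3x3
#' Laplacian kernel, valid region only.  The 4-neighbour kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` is the default; an 8-neighbour variant is
#' available.
#'
#' @param patch 2D numeric matrix, at least 3x3.
#' @param eight_neighbour use the 8-neighbour Laplacian.
#' @return non-negative scalar.
#' @export
laplacian_variance <- function(patch, eight_neighbour = FALSE) {
  if (!is.matrix(patch) || nrow(patch) < 3 || ncol(patch) < 3)
    stop("patch must be a matrix of at least 3 x 3")
  K <- if (eight_neighbour)
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  else
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  nr <- nrow(patch) - 2; nc <- ncol(patch) - 2
  out <- matrix(0, nr, nc)
  for (a in 1:3) for (b in 1:3) {
    out <- out + K[a, b] * patch[a:(a + nr - 1), b:(b + nc - 1)]
  }
  stats::var(as.vector(out))
}

#' Chamber volume by disc summation over slice masks
#'
#' Slice-wise area times slice spacing (thickness plus inter-slice gap),
#' summed over the stack and converted to millilitres - the standard
#' disc-summation volume of slice-wise endocardial contours.
#'
#' @param mask_stack list of logical/0-1 matrices, one per slice.
#' @param pixel_spacing_mm in-plane pixel size (scalar or length-2, mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param gap_mm inter-slice gap (default 0 mm).
#' @return volume in mL.
#' @export
chamber_volume <- function(mask_stack, pixel_spacing_mm, slice_thickness_mm,
                           gap_mm = 0) {
  if (length(mask_stack) == 0) stop("mask stack is empty")
  px_area <- prod(rep(pixel_spacing_mm, length.out = 2))
  areas <- vapply(mask_stack, function(m) sum(m != 0) * px_area, numeric(1))
  sum(areas) * (slice_thickness_mm + gap_mm) / 1000
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param EDV,ESV end-diastolic and end-systolic volumes (mL), with
#'   `0 <= ESV <= EDV`.
#' @return EF in percent, `100 * (EDV - ESV) / EDV`.
#' @export
ejection_fraction <- function(EDV, ESV) {
  if (EDV <= 0) stop("EDV must be positive")
  if (ESV < 0 || ESV > EDV) stop("require 0 <= ESV <= EDV")
  100 * (EDV - ESV) / EDV
}

#' Du Bois body surface area
#'
#' @param weight_kg body weight (kg).
#' @param height_cm body height (cm).
#' @return BSA in m^2: `0.007184 * weight^0.425 * height^0.725`.
#' @export
du_bois_bsa <- function(weight_kg, height_cm) {
  if (weight_kg <= 0 || height_cm <= 0)
    stop("weight and height must be positive")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Biplane area-length left atrial volume index
#'
#' Raw atrial volume `8 A1 A2 / (3 pi Lmin)` from the atrial blood-pool
#' areas on the two orthogonal long-axis views and the shorter long-axis
#' length, converted to mL and indexed to the Du Bois body surface area.
#' For a sphere of radius r (`A1 = A2 = pi r^2`, `Lmin = 2r`) the raw
#' volume is exactly `(4/3) pi r^3`.
#'
#' @param A1,A2 atrial areas on the two long-axis views (mm^2).
#' @param Lmin shortest long-axis length (mm).
#' @param weight_kg,height_cm subject weight and height for the BSA.
#' @return LAVI in mL/m^2.
#' @export
lavi_biplane <- function(A1, A2, Lmin, weight_kg, height_cm) {
  if (A1 < 0 || A2 < 0) stop("areas must be non-negative")
  if (Lmin <= 0) stop("undefined: Lmin must be positive")
  vol_ml <- 8 * A1 * A2 / (3 * pi * Lmin) / 1000
  vol_ml / du_bois_bsa(weight_kg, height_cm)
}

# exact two-sided paired Wilcoxon signed-rank p-value by enumeration over
# sign assignments of the non-zero differences (midranks for ties)
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  # distribution of V over all 2^m sign assignments via convolution on a
  # half-rank lattice (midranks are multiples of 1/2)
  lat <- round(2 * r)
  maxs <- sum(lat)
  probs <- numeric(maxs + 1)
  probs[1] <- 1
  for (l in lat) {
    shifted <- c(rep(0, l), probs[seq_len(maxs + 1 - l)])
    probs <- 0.5 * (probs + shifted)
  }
  support <- (seq_len(maxs + 1) - 1) / 2
  dev <- abs(support - mu)
  p <- sum(probs[dev >= abs(v_obs - mu) - 1e-9])
  min(1, p)
}

#' Bland-Altman agreement and paired comparison statistics
#'
#' For paired measurements of the same quantity by two methods: the bias
#' (mean difference), the 95% limits of agreement (bias +/- 1.96 sd of the
#' differences), the R-squared of the least-squares fit of method A on
#' method B, and the two-sided paired Wilcoxon signed-rank p-value (exact
#' by enumeration for n <= 25 pairs, normal approximation otherwise).
#'
#' @param a,b numeric vectors of paired measurements (method A, method B),
#'   at least 3 pairs.
#' @return list with `bias`, `loa_low`, `loa_high`, `r_squared`,
#'   `wilcoxon_p`, `n`.
#' @export
agreement_stats <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("at least 3 pairs required")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 1
  else suppressWarnings(summary(stats::lm(a ~ b))$r.squared)
  p <- if (length(d) <= 25) wilcoxon_exact_p(d)
  else suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                           exact = FALSE)$p.value)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       r_squared = r2, wilcoxon_p = p, n = length(a))
}
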