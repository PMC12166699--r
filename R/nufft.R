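#' @useDynLib freerun5d, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# admissible oversampled grid sizes: even, 5-smooth (fast mixed-radix FFT)
next_fast_even <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  if (n %% 2L == 1L) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}

# Fourier transform of the Kaiser-Bessel kernel (half-width L, shape beta),
# evaluated at frequency f in grid-sample^-1 units; normalised like the
# kernel itself (divided by I0(beta)).
kb_ft <- function(f, L, beta) {
  z2 <- beta^2 - (2 * pi * L * f)^2
  out <- numeric(length(z2))
  pos <- z2 > 1e-12
  neg <- z2 < -1e-12
  mid <- !(pos | neg)
  out[pos] <- sinh(sqrt(z2[pos])) / sqrt(z2[pos])
  out[neg] <- sin(sqrt(-z2[neg])) / sqrt(-z2[neg])
  out[mid] <- 1
  2 * L * out / besselI(beta, 0)
}

#' Plan a 3D non-uniform FFT on radial sample coordinates
#'
#' Precomputes the oversampled grid geometry, Kaiser-Bessel shape parameter
#' and deapodization profile for a type-2 (image to non-Cartesian samples)
#' NUFFT and its exact adjoint.  The forward model evaluates
#' \eqn{s(k) = \sum_x m(x) e^{-2\pi i k \cdot x}} with image coordinates
#' \eqn{x} in voxels, centred on the grid, and \eqn{k} in cycles/voxel.
#'
#' @param kcoords numeric matrix (n samples x 3) of k-space coordinates in
#'   cycles/voxel; the supported band is \eqn{|k| \le 0.5} per axis.
#' @param n image matrix size per dimension (even positive integer; the
#'   image grid is an n x n x n cube).
#' @param os grid oversampling factor (default 1.5).
#' @param width kernel support in oversampled grid cells (default 4; larger
#'   widths trade speed for accuracy, e.g. 8 for ~1e-7 relative error).
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(kcoords, n, os = 1.5, width = 4) {
  kcoords <- as.matrix(kcoords)
  if (ncol(kcoords) != 3 || !is.numeric(kcoords) || anyNA(kcoords))
    stop("kcoords must be a numeric n x 3 matrix without NAs")
  if (max(abs(kcoords)) > 0.5 + 1e-9)
    stop("k-space coordinates must lie within [-0.5, 0.5] cycles/voxel")
  n <- as.integer(n)
  if (length(n) != 1 || n < 2 || n %% 2L != 0L)
    stop("n must be a single even integer >= 2")
  nos <- next_fast_even(os * n)
  os_eff <- nos / n
  # Beatty et al. choice of the kernel shape parameter
  beta <- pi * sqrt((width / os_eff)^2 * (os_eff - 0.5)^2 - 0.8)
  x1 <- seq_len(n) - 1L - n %/% 2L           # centred voxel coordinates
  deap1 <- kb_ft(x1 / nos, width / 2, beta)
  structure(list(
    coords = kcoords * nos,                  # oversampled-grid units
    n = n, nos = nos, width = width, beta = beta,
    deap1 = deap1,
    wrap_idx = (x1 %% nos) + 1L,             # image voxel -> padded index
    n_samples = nrow(kcoords)
  ), class = "nufft_plan")
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf("NUFFT plan: %d samples, %d^3 image grid, %d^3 oversampled, width %g, beta %.3f\n",
              x$n_samples, x$n, x$nos, x$width, x$beta))
  invisible(x)
}

deapodize <- function(plan, img) {
  img <- img / plan$deap1                                    # along x
  img <- img / rep(plan$deap1, each = plan$n)                # along y
  img / rep(plan$deap1, each = plan$n^2)                     # along z
}

#' Forward NUFFT: image to non-Cartesian k-space samples
#'
#' @param plan a [nufft_plan()].
#' @param image numeric or complex n x n x n array.
#' @return complex vector of length `nrow(kcoords)`.
#' @export
nufft_forward <- function(plan, image) {
  n <- plan$n
  if (!identical(dim(image), rep(n, 3L)) && !identical(dim(image), as.integer(rep(n, 3))))
    stop("image dimensions do not match the plan")
  img <- deapodize(plan, image + 0i)
  pad <- array(0i, rep(plan$nos, 3L))
  iw <- plan$wrap_idx
  pad[iw, iw, iw] <- img
  G <- stats::fft(pad)
  kb_interp_cpp(as.vector(G), rep(plan$nos, 3L), plan$coords,
                plan$width, plan$beta)
}

#' Adjoint NUFFT: non-Cartesian samples to image
#'
#' Exact adjoint of [nufft_forward()] (passes the inner-product test to
#' machine precision).
#'
#' @param plan a [nufft_plan()].
#' @param samples complex vector, one value per k-space sample.
#' @return complex n x n x n array.
#' @export
nufft_adjoint <- function(plan, samples) {
  if (length(samples) != plan$n_samples)
    stop("sample count does not match the plan")
  H <- kb_spread_cpp(as.complex(samples), rep(plan$nos, 3L), plan$coords,
                     plan$width, plan$beta)
  dim(H) <- rep(plan$nos, 3L)
  h <- stats::fft(H, inverse = TRUE)
  iw <- plan$wrap_idx
  deapodize(plan, h[iw, iw, iw])
}

#' Radial density-compensation weights
#'
#' Analytic \eqn{|k|^2} weights for full-diameter radial spokes, used for
#' gridding (adjoint) initialisation and coil-sensitivity estimation only,
#' never inside the iterative reconstruction objective.  The weights
#' approximate the k-space volume element \eqn{k^2\,dk\,d\Omega} so that
#' \eqn{A^H(W s)} approximates the image on the sampled band.
#'
#' @param kcoords n x 3 matrix of k-space sample coordinates (cycles/voxel).
#' @param n_spokes number of distinct spokes (diameters) in `kcoords`.
#' @param n_samples_per_spoke samples along each diameter.
#' @return numeric weight vector matching `nrow(kcoords)`.
#' @export
density_weights <- function(kcoords, n_spokes, n_samples_per_spoke) {
  kr <- sqrt(rowSums(kcoords^2))
  dk <- 1 / n_samples_per_spoke
  dOmega <- 4 * pi / (2 * n_spokes)   # diameters sample antipodal pairs
  w <- kr^2 * dk * dOmega
  # DC cell: sphere of radius dk/2 shared by all spokes crossing the origin
  ndc <- sum(kr < dk / 2)
  if (ndc > 0) w[kr < dk / 2] <- (4 / 3) * pi * (dk / 2)^3 / ndc
  w
}
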