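test_that("axis-aligned thin-slab reformat reproduces the voxel slice", {
  set.seed(1)
  n <- 16
  sp <- 2.5
  vol <- array(stats::rnorm(n^3), rep(n, 3))
  k0 <- 12                                  # slice index, z = (k0-1-n/2)*sp
  z0 <- (k0 - 1 - n %/% 2) * sp
  pl <- slice_plane(origin = c(0, 0, z0), normal = c(0, 0, 1),
                    extent_mm = c((n - 4) * sp, (n - 4) * sp),
                    spacing_mm = sp, thickness_mm = sp)
  sl <- reformat_slab(vol, sp, pl)
  # interior samples coincide with voxel centres of slice k0
  idx <- 3:(n - 1)
  expect_identical(dim(sl), c(length(idx), length(idx)))
  expect_equal(sl, vol[idx, idx, k0], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("constant volumes reformat to constant slabs, any obliquity", {
  vol <- array(7, rep(24, 3))
  pl <- slice_plane(origin = c(1, -2, 3), normal = c(1, 1, 0.5),
                    extent_mm = c(20, 20), spacing_mm = 1, thickness_mm = 8)
  sl <- reformat_slab(vol, 2, pl)
  expect_true(all(abs(sl - 7) < 1e-12))
  expect_error(reformat_slab(vol, 2, slice_plane(origin = c(999, 0, 0))),
               "outside")
})

test_that("oblique slab through a sphere cuts a disc of the chord radius", {
  n <- 48
  sp <- 1
  ax <- (seq_len(n) - 1 - n %/% 2) * sp
  R <- 15
  vol <- array(0, rep(n, 3))
  vol[outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= R^2] <- 1
  pl <- slice_plane(origin = c(0, 0, 0), normal = c(1, 1, 0),
                    extent_mm = c(44, 44), spacing_mm = 0.5,
                    thickness_mm = sp)
  sl <- reformat_slab(vol, sp, pl)
  area <- sum(sl > 0.5) * 0.5^2
  expect_lt(abs(sqrt(area / pi) - R), 1)
})

test_that("contrast ratio is a scale-invariant mean ratio", {
  expect_equal(contrast_ratio(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(contrast_ratio(rep(4.7, 10), rep(1, 10)), 4.7)
  b <- stats::runif(20, 2, 5); m <- stats::runif(20, 0.5, 1.5)
  expect_equal(contrast_ratio(7 * b, 7 * m), contrast_ratio(b, m))
  expect_error(contrast_ratio(numeric(0), 1), "non-empty")
  expect_error(contrast_ratio(1, c(-1, 1)), "zero")
})

test_that("SNR is mean signal over noise standard deviation (n-1)", {
  noise <- c(-1, 1) * sqrt(0.5)              # sd exactly 1 with n-1
  expect_equal(stats::sd(noise), 1)
  expect_equal(snr_measure(rep(77, 5), noise), 77)
  expect_equal(snr_measure(rep(0, 5), noise), 0)
  expect_error(snr_measure(1, 3), "at least 2")
  expect_error(snr_measure(1, c(2, 2)), "zero variance")
})

test_that("Laplacian variance matches a brute-force convolution oracle", {
  expect_equal(laplacian_variance(matrix(3, 5, 5)), 0)
  set.seed(2)
  patch <- matrix(stats::rnorm(64), 8, 8)
  # oracle: explicit double-loop valid convolution + variance
  K <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  conv <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    conv[i, j] <- sum(K * patch[i:(i + 2), j:(j + 2)])
  expect_equal(laplacian_variance(patch), stats::var(as.vector(conv)))
  # quadratic intensity scaling
  expect_equal(laplacian_variance(5 * patch), 25 * laplacian_variance(patch))
  # step edge, computed by the same oracle
  step <- matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), each = 8), 8, 8)
  conv2 <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    conv2[i, j] <- sum(K * step[i:(i + 2), j:(j + 2)])
  expect_equal(laplacian_variance(step), stats::var(as.vector(conv2)))
  expect_error(laplacian_variance(matrix(1, 2, 5)), "3 x 3")
})

test_that("disc summation recovers mask volumes", {
  m <- matrix(0, 12, 12); m[2:11, 2:11] <- 1    # 100 px of 4 mm^2
  expect_equal(chamber_volume(list(m), 2, 8), 3.2)
  expect_equal(chamber_volume(list(m), 4, 8), 4 * 3.2)
  # rasterized ellipsoid across slices vs analytic volume
  a <- 20; b <- 14; cc <- 25
  sp <- 1; thick <- 2
  zs <- seq(-cc + thick / 2, cc - thick / 2, by = thick)
  ax <- seq(-30, 30, by = sp)
  stack <- lapply(zs, function(z) {
    r2 <- 1 - z^2 / cc^2
    outer(ax^2 / a^2, ax^2 / b^2, "+") <= r2
  })
  vol <- chamber_volume(stack, sp, thick)
  expect_lt(abs(vol - (4 / 3) * pi * a * b * cc / 1000) /
              ((4 / 3) * pi * a * b * cc / 1000), 0.05)
  # mask and complement partition the slab volume
  comp <- lapply(stack, `!`)
  slab <- length(stack) * thick * length(ax)^2 * sp^2 / 1000
  expect_equal(chamber_volume(stack, sp, thick) +
                 chamber_volume(comp, sp, thick), slab)
  expect_error(chamber_volume(list(), 1, 8), "empty")
})

test_that("ejection fraction arithmetic and guards", {
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(80, 80), 0)
  expect_equal(ejection_fraction(156, 65), 100 * (156 - 65) / 156)
  expect_error(ejection_fraction(0, 0), "positive")
  expect_error(ejection_fraction(50, 60), "ESV")
})

test_that("Du Bois BSA and the biplane area-length sphere identity", {
  expect_equal(du_bois_bsa(74, 169),
               0.007184 * 74^0.425 * 169^0.725, tolerance = 1e-12)
  expect_equal(du_bois_bsa(74, 169), 1.845, tolerance = 1e-3)
  # sphere: A1 = A2 = pi r^2, Lmin = 2r -> raw volume (4/3) pi r^3 exactly
  for (r in c(10, 17.3, 31)) {
    bsa <- du_bois_bsa(74, 169)
    lavi <- lavi_biplane(pi * r^2, pi * r^2, 2 * r, 74, 169)
    expect_equal(lavi * bsa * 1000, (4 / 3) * pi * r^3, tolerance = 1e-12)
  }
  expect_equal(lavi_biplane(0, 100, 10, 74, 169), 0)
  expect_error(lavi_biplane(10, 10, 0, 74, 169), "Lmin")
})

test_that("agreement statistics: degenerate and offset series", {
  s <- agreement_stats(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(s$bias, 0)
  expect_equal(s$loa_low, 0)
  expect_equal(s$loa_high, 0)
  expect_equal(s$r_squared, 1)
  expect_gt(s$wilcoxon_p, 0)
  expect_lte(s$wilcoxon_p, 1)
  s2 <- agreement_stats(c(1, 2, 3, 4) + 2.5, c(1, 2, 3, 4))
  expect_equal(s2$bias, 2.5)
  expect_equal(s2$loa_low, 2.5)
  expect_equal(s2$loa_high, 2.5)
  expect_equal(s2$r_squared, 1)
  expect_error(agreement_stats(1:2, 1:2), "3 pairs")
})

test_that("agreement statistics match brute-force oracles on a fixed toy set", {
  d <- c(1, -2, 0, 3, -1, 2, 1, -1, 0, 1)
  b <- c(10, 12, 9, 14, 11, 13, 10, 12, 9, 11)
  a <- b + d
  s <- agreement_stats(a, b)
  expect_equal(s$bias, mean(d))
  expect_equal(s$loa_low, mean(d) - 1.96 * stats::sd(d))
  expect_equal(s$loa_high, mean(d) + 1.96 * stats::sd(d))
  expect_equal(s$r_squared, stats::cor(a, b)^2)
  # exhaustive sign-assignment oracle for the exact Wilcoxon p
  dn <- d[d != 0]
  r <- rank(abs(dn))
  mu <- sum(r) / 2
  v_obs <- sum(r[dn > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(dn))))
  v_all <- as.vector(signs %*% r)
  p_oracle <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
  expect_equal(s$wilcoxon_p, p_oracle, tolerance = 1e-12)
  # LoA always bracket the bias
  expect_lte(s$loa_low, s$bias)
  expect_gte(s$loa_high, s$bias)
})

test_that("exact Wilcoxon agrees with wilcox.test when there are no ties", {
  set.seed(9)
  a <- stats::rnorm(12)
  b <- a + stats::rnorm(12, 0.3)
  s <- agreement_stats(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_equal(s$wilcoxon_p, ref, tolerance = 1e-12)
})
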