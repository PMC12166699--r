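# small binned operator on the static scene, with synthetic 2-bin labels
small_operator <- function() {
  cached("small_operator", {
    sim <- static_sim(grid_n = 16, n_shots = 40, n_coils = 2)
    n_ro <- nrow(sim$traj$directions)
    bins <- structure(list(
      cardiac_bin = rep(c(1L, 2L), length.out = n_ro),
      resp_bin = rep(1L, n_ro), n_cardiac_bins = 2L, n_resp = 1L,
      bin_width_ms = 50, phase_ms = rep(0, n_ro),
      resp_amplitude = rep(0, n_ro), trigger_times_ms = c(0, 1, 2),
      median_rr_ms = 1000), class = "freerun_bins")
    op <- mr_operator(sim$traj, bins, sim$coils, sim$grid)
    list(sim = sim, bins = bins, op = op)
  })
}

test_that("binned multi-coil operator passes the adjoint inner-product test", {
  so <- small_operator()
  op <- so$op
  set.seed(31)
  x <- array(stats::rnorm(prod(op$img_dim)) + 1i * stats::rnorm(prod(op$img_dim)),
             op$img_dim)
  y <- stats::rnorm(op$n_samples) + 1i * stats::rnorm(op$n_samples)
  lhs <- sum(forward_model(op, x) * Conj(y))
  rhs <- sum(x * Conj(adjoint_model(op, y)))
  denom <- sqrt(sum(abs(x)^2)) * sqrt(sum(abs(y)^2))
  expect_lt(abs(lhs - rhs) / denom, 1e-6)
})

test_that("zero image maps to zero samples and dimension mismatches error", {
  so <- small_operator()
  op <- so$op
  expect_true(all(forward_model(op, array(0i, op$img_dim)) == 0))
  expect_error(forward_model(op, array(0i, c(8, 8, 8, 2, 1))), "dimensions")
  expect_error(adjoint_model(op, complex(5)), "length")
})

test_that("unregularized single-bin reconstruction matches a CGLS oracle", {
  sim <- static_sim(grid_n = 16, n_shots = 40, n_coils = 2)
  n_ro <- nrow(sim$traj$directions)
  bins <- structure(list(
    cardiac_bin = rep(1L, n_ro), resp_bin = rep(1L, n_ro),
    n_cardiac_bins = 1L, n_resp = 1L, bin_width_ms = 50,
    phase_ms = rep(0, n_ro), resp_amplitude = rep(0, n_ro),
    trigger_times_ms = c(0, 1, 2), median_rr_ms = 1000),
    class = "freerun_bins")
  rec <- reconstruct_5d(sim$raw, bins, sim$coils,
                        recon_config(lambda_c = 0, lambda_r = 0,
                                     outer_iterations = 6,
                                     inner_cg_iterations = 8))
  x_hat <- rec$values[, , , 1, 1] * rec$data_scale
  dim(x_hat) <- rep(16L, 3L)

  # independent oracle: plain CGLS on A^H A x = A^H s built directly on
  # the NUFFT, bypassing mr_operator and the ADMM machinery
  kk <- trajectory_kspace(sim$traj)
  plan <- nufft_plan(kk$coords, 16)
  A <- function(x) {
    c(nufft_forward(plan, sim$coils[, , , 1] * x),
      nufft_forward(plan, sim$coils[, , , 2] * x))
  }
  Ah <- function(s) {
    m <- length(s) / 2
    Conj(sim$coils[, , , 1]) * nufft_adjoint(plan, s[1:m]) +
      Conj(sim$coils[, , , 2]) * nufft_adjoint(plan, s[m + 1:m])
  }
  s_vec <- c(as.vector(sim$raw$samples[, , 1]),
             as.vector(sim$raw$samples[, , 2]))
  b <- Ah(s_vec)
  x <- array(0i, rep(16L, 3L)); r <- b; p <- r
  rs <- Re(sum(Conj(r) * r))
  for (it in 1:30) {
    Ap <- Ah(A(p))
    al <- rs / Re(sum(Conj(p) * Ap))
    x <- x + al * p; r <- r - al * Ap
    rs2 <- Re(sum(Conj(r) * r)); p <- r + (rs2 / rs) * p; rs <- rs2
  }
  expect_lt(nrmse(x_hat, x), 0.05)
  # and both recover the rendered phantom frame
  fr <- render_frame(sim$phantom, 0, sim$grid)
  expect_lt(nrmse(abs(x_hat), fr), 0.35)
  expect_lt(abs(nrmse(abs(x_hat), fr) - nrmse(abs(x), fr)), 0.02)
})

test_that("ADMM objective decreases monotonically (small tolerance)", {
  so <- small_operator()
  rec <- reconstruct_5d(so$sim$raw, so$bins, so$sim$coils,
                        recon_config(outer_iterations = 6,
                                     inner_cg_iterations = 4))
  obj <- rec$objective
  expect_gte(length(obj), 2)
  expect_true(all(diff(obj) <= obj[-length(obj)] * 1e-3))
  # converged data consistency beats the zero image and the initialization
  op <- mr_operator(so$sim$traj, so$bins, so$sim$coils, so$sim$grid)
  s <- freerun5d:::gather_samples(op, so$sim$raw) / rec$data_scale
  x0 <- freerun5d:::dc_adjoint(op, s)
  res <- function(x) sum(abs(forward_model(op, x) - s)^2)
  expect_lt(res(rec$values), sum(abs(s)^2))            # vs zero image
  expect_lt(res(rec$values), res(x0))                  # vs gridding init
})

test_that("estimated coil maps match the simulator's profiles", {
  sim <- static_sim(grid_n = 24, n_shots = 150, n_coils = 2,
                    noise_sigma_ref = 1)
  maps <- estimate_sensitivities(sim$raw)
  rss <- sqrt(apply(abs(maps)^2, 1:3, sum))
  expect_lt(max(abs(rss - 1)), 1e-6)
  fr <- render_frame(sim$phantom, 0, sim$grid)
  support <- fr > 0.1
  for (c in 1:2) {
    est <- maps[, , , c]
    tru <- sim$coils[, , , c]
    # align the global phase before comparing
    al <- sum(est[support] * Conj(tru[support]))
    al <- al / abs(al)
    rel <- abs(est[support] / al - tru[support]) / abs(tru[support])
    expect_lt(stats::median(rel), 0.1)
  }
})

test_that("single-coil sensitivity estimation returns unit maps with a warning", {
  sim <- static_sim(grid_n = 16, n_shots = 20, n_coils = 1)
  expect_warning(maps <- estimate_sensitivities(sim$raw), "single-coil")
  expect_true(all(maps == 1 + 0i))
})

test_that("identical coil profiles estimate to 1/sqrt(n) magnitude on support", {
  sim <- static_sim(grid_n = 16, n_shots = 60, n_coils = 2)
  raw <- sim$raw
  # overwrite: both coils see the same (first) profile
  raw$samples[, , 2] <- raw$samples[, , 1]
  maps <- estimate_sensitivities(raw)
  fr <- render_frame(sim$phantom, 0, sim$grid)
  support <- fr > 0.1
  expect_lt(max(abs(abs(maps[, , , 1][support]) - 1 / sqrt(2))), 1e-6)
})

test_that("temporal total variation measures finite differences along motion dims", {
  x <- array(0i, c(2, 2, 2, 3, 2))
  x[, , , 2, ] <- 1
  x[, , , 3, ] <- 3
  # cardiac diffs: |1-0| + |3-1| = 3 per voxel-line, 16 of them
  expect_equal(temporal_tv(x, "cardiac"), (1 + 2) * 2 * 2 * 2 * 2)
  x2 <- array(0i, c(2, 2, 2, 3, 2))
  x2[, , , , 2] <- 2i
  expect_equal(temporal_tv(x2, "respiratory"), 2 * 2 * 2 * 2 * 3)
  expect_equal(temporal_tv(array(1, c(2, 2, 2, 1, 1)), "cardiac"), 0)
})

test_that("undersampling report counts spokes per bin against Nyquist", {
  so <- small_operator()
  rep <- undersampling_report(so$bins, 16)
  expect_identical(nrow(rep), 2L)
  expect_identical(sum(rep$n_spokes), length(so$bins$cardiac_bin))
  expect_equal(rep$undersampling,
               (pi / 4) * 256 / rep$n_spokes)
})

test_that("recon_config validates its arguments", {
  expect_error(recon_config(lambda_c = -1), "weights")
  expect_error(recon_config(outer_iterations = 0), "iteration")
  cfg <- recon_config()
  expect_equal(cfg$lambda_c, 0.005)
  expect_equal(cfg$lambda_r, 0.005)
})
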