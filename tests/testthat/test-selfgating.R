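test_that("SI matrix has coil-by-position rows and one column per interleave", {
  sim <- static_sim(grid_n = 16, n_shots = 30, n_coils = 2)
  si <- extract_si_matrix(sim$raw)
  expect_identical(dim(si$si_matrix), c(2L * 16L, 30L))
  expect_identical(si$si_times_ms, sim$traj$timestamps_ms[sim$traj$is_si])
  expect_false(is.unsorted(si$si_times_ms, strictly = TRUE))
  # static phantom, zero noise: all projection columns identical
  expect_lt(max(apply(si$si_matrix, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("a pure z-translation circularly shifts the SI projection", {
  g <- voxel_grid(24, 160)
  design <- acquisition_design(Np = 24, Nim = 1, Ufactor = 1, Nshots = 3,
                               samples_per_readout = 24)
  traj <- generate_phyllotaxis(design)
  base <- dynamic_phantom(contraction_frac = 0, resp_amplitude_mm = 0,
                          seed = 1)
  coils <- coil_profiles(g, 1)
  dz_mm <- 2 * g$spacing_mm                  # exactly two samples
  raw0 <- simulate_kspace(base, traj, g, coils, width = 8)
  shifted <- base
  shifted$chambers <- lapply(base$chambers, function(ch) {
    if (freerun5d:::chamber_respiratory(ch)) ch$center[3] <- ch$center[3] + dz_mm
    ch
  })
  raw1 <- simulate_kspace(shifted, traj, g, coils, width = 8)
  p0 <- extract_si_matrix(raw0)$si_matrix[, 1]
  p1 <- extract_si_matrix(raw1)$si_matrix[, 1]
  # best cross-correlation lag recovers the shift within one sample:
  # a +dz translation moves the projection to higher sample indices
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    i <- seq(7, 18)
    stats::cor(p0[i], p1[i + l])
  }, numeric(1))
  expect_lte(abs(lags[which.max(cc)] - 2), 1)
})

test_that("PCA recovers cardiac and respiratory frequencies on the standard scene", {
  gate <- standard_gate()
  sim <- standard_sim()
  fr <- signal_frequencies(gate$physio)
  expect_lt(abs(fr$cardiac_hz - 1000 / sim$phantom$cardiac_period_ms),
            fr$resolution_hz)
  expect_lt(abs(fr$resp_hz - 1000 / sim$phantom$resp_period_ms),
            fr$resolution_hz)
  # selected components track the true motion closely
  dz <- resp_displacement(sim$phantom, gate$physio$si_times_ms)
  expect_gt(abs(stats::cor(gate$physio$respiratory_signal, dz)), 0.9)
  ph <- cardiac_phase(sim$phantom, gate$physio$si_times_ms)$phase
  vols <- vapply(ph, function(p)
    ground_truth_volumes(sim$phantom, p)[["lv_blood"]], numeric(1))
  expect_gt(abs(stats::cor(gate$physio$cardiac_signal, vols)), 0.9)
})

test_that("motionless data fail gating rather than fabricate signals", {
  sim <- static_sim(grid_n = 16, n_shots = 40, n_coils = 2)
  si <- extract_si_matrix(sim$raw)
  expect_error(derive_motion_signals(si, 106.92), "gating failure")
  expect_error(detect_triggers(rep(1, 100), 106.92), "constant")
})

test_that("trigger detection: sinusoid oracle, jitter tracking, guards", {
  dt <- 106.92
  t <- seq(0, 60000, by = dt)
  trig <- detect_triggers(sin(2 * pi * t / 1000), dt, t)
  expect_gte(length(trig), 59)
  expect_lte(length(trig), 61)
  expect_lt(max(abs(diff(trig) - 1000)), dt)
  expect_error(detect_triggers(sin(2 * pi * t[1:5] / 1000), dt, t[1:5]),
               "gating failure")
})

test_that("detected beats track simulated RR jitter", {
  gate <- standard_gate()
  sim <- standard_sim()
  trig <- gate$physio$trigger_times_ms
  rr_det <- diff(trig)
  # align detected beats with the phantom's beat table
  beat_idx <- findInterval(trig[-length(trig)], sim$phantom$beats$onset_ms)
  rr_true <- sim$phantom$beats$rr_ms[beat_idx]
  expect_gt(stats::cor(rr_det, rr_true), 0.8)
})

test_that("bin counts follow floor(median RR / bin width)", {
  design <- acquisition_design(Np = 16, Nim = 1, Ufactor = 1, Nshots = 170,
                               samples_per_readout = 16)
  traj <- generate_phyllotaxis(design)           # ~18.2 s of readouts
  t_end <- max(traj$timestamps_ms)
  mk_physio <- function(rr) {
    trig <- seq(0, t_end + rr, by = rr)
    si_t <- traj$timestamps_ms[traj$is_si]
    physio_signals(cardiac_signal = sin(2 * pi * si_t / rr),
                   respiratory_signal = sin(2 * pi * si_t / 4000),
                   si_times_ms = si_t, trigger_times_ms = trig)
  }
  b1000 <- assign_bins(mk_physio(1000), traj, bin_width_ms = 50, n_resp = 4)
  expect_identical(b1000$n_cardiac_bins, 20L)
  b909 <- assign_bins(mk_physio(909), traj, bin_width_ms = 50, n_resp = 4)
  expect_identical(b909$n_cardiac_bins, 18L)
  expect_error(assign_bins(mk_physio(80), traj, bin_width_ms = 50),
               "median RR")
  # all accounted for: every readout is either binned or rejected
  expect_identical(sum(!is.na(b1000$cardiac_bin)) +
                     sum(is.na(b1000$cardiac_bin)),
                   length(traj$timestamps_ms))
})

test_that("respiratory quantiles split accepted readouts evenly", {
  design <- acquisition_design(Np = 16, Nim = 1, Ufactor = 1, Nshots = 170,
                               samples_per_readout = 16)
  traj <- generate_phyllotaxis(design)
  si_t <- traj$timestamps_ms[traj$is_si]
  trig <- seq(0, max(traj$timestamps_ms) + 1000, by = 1000)
  for (n_resp in c(2L, 4L, 5L)) {
    ph <- physio_signals(sin(2 * pi * si_t / 1000),
                         stats::runif(length(si_t)),
                         si_t, trigger_times_ms = trig)
    bins <- assign_bins(ph, traj, bin_width_ms = 50, n_resp = n_resp)
    pops <- table(bins$resp_bin)
    expect_identical(length(pops), as.integer(n_resp))
    expect_lte(diff(range(pops)), 1)
  }
  # a monotone amplitude ramp splits into exact quartiles
  ph <- physio_signals(sin(2 * pi * si_t / 1000), seq_along(si_t),
                       si_t, trigger_times_ms = trig)
  bins <- assign_bins(ph, traj, bin_width_ms = 50, n_resp = 4)
  acc <- which(!is.na(bins$cardiac_bin))
  expect_false(is.unsorted(bins$resp_bin[acc]))
})

test_that("beats with aberrant RR are rejected wholesale", {
  design <- acquisition_design(Np = 16, Nim = 1, Ufactor = 1, Nshots = 170,
                               samples_per_readout = 16)
  traj <- generate_phyllotaxis(design)
  si_t <- traj$timestamps_ms[traj$is_si]
  # triggers: regular 1000 ms beats with one 1600 ms outlier
  trig <- cumsum(c(0, rep(1000, 7), 1600, rep(1000, 10)))
  ph <- physio_signals(sin(2 * pi * si_t / 1000), sin(si_t / 500), si_t,
                       trigger_times_ms = trig)
  bins <- assign_bins(ph, traj, bin_width_ms = 50, n_resp = 2)
  in_outlier <- traj$timestamps_ms >= trig[8] & traj$timestamps_ms < trig[9]
  expect_true(all(is.na(bins$cardiac_bin[in_outlier])))
  before <- traj$timestamps_ms >= trig[3] & traj$timestamps_ms < trig[4]
  expect_true(any(!is.na(bins$cardiac_bin[before])))
})

test_that("end-expiration bin has the least intra-bin displacement variance", {
  gate <- standard_gate()
  sim <- standard_sim()
  bins <- self_gate(sim$raw, bin_width_ms = 72, n_resp = 4)$bins
  dz <- resp_displacement(sim$phantom, sim$traj$timestamps_ms)
  acc <- !is.na(bins$cardiac_bin)
  vars <- vapply(1:4, function(r) stats::var(dz[acc & bins$resp_bin == r]),
                 numeric(1))
  expect_identical(which.min(vars), 1L)
})
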