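# Shared, lazily built simulation fixtures.  The cache lives for the whole
# test session, so the expensive standard scene is simulated once and
# reused by the gating, reconstruction and end-to-end tests.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard desk-scale study conditions (48^3 grid, 2 coils, 45 s)
standard_sim <- function() {
  cached("standard_sim", simulate_stage(fixture_config("standard", seed = 7)))
}

standard_gate <- function() {
  cached("standard_gate", {
    sim <- standard_sim()
    self_gate(sim$raw, bin_width_ms = 72, n_resp = 2)
  })
}

# full default pipeline run on the standard scene, intermediates kept
standard_report <- function() {
  cached("standard_report", {
    cfg <- fixture_config("standard", seed = 7)
    run_pipeline(cfg, keep_intermediates = TRUE)
  })
}

# small static single-coil scene for operator and SNR tests
static_sim <- function(grid_n = 24, n_shots = 200, noise_sigma_ref = 0,
                       bandwidth = 401, seed = 5, n_coils = 1, width = 4) {
  key <- sprintf("static_%d_%d_%g_%g_%d_%d_%d", grid_n, n_shots,
                 noise_sigma_ref, bandwidth, seed, n_coils, width)
  cached(key, {
    grid <- voxel_grid(grid_n, 160)
    design <- acquisition_design(Np = grid_n, Nim = 1, Ufactor = 1,
                                 Nshots = n_shots,
                                 samples_per_readout = grid_n)
    traj <- generate_phyllotaxis(design)
    phantom <- dynamic_phantom(contraction_frac = 0, resp_amplitude_mm = 0,
                               duration_ms = design$Nshots * 18 * 5.94 + 2000,
                               seed = seed)
    coils <- coil_profiles(grid, n_coils)
    raw <- simulate_kspace(phantom, traj, grid, coils,
                           noise_sigma_ref = noise_sigma_ref,
                           bandwidth_hz_per_px = bandwidth, seed = seed,
                           width = width)
    list(phantom = phantom, traj = traj, grid = grid, coils = coils,
         raw = raw)
  })
}

nrmse <- function(x, ref) {
  sqrt(mean(abs(x - ref)^2)) / sqrt(mean(abs(ref)^2))
}
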