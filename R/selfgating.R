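#' Stack the 1D projections of the SI readouts into a navigator matrix
#'
#' Each superior-inferior (SI) readout is a k-space spoke along +z; its 1D
#' inverse Fourier transform is a head-foot projection of the object.  The
#' magnitude profiles of all coils are stacked along a combined
#' coil-position axis, one column per SI readout in time order.
#'
#' @param raw a [simulate_kspace()] result (or compatible `freerun_raw`).
#' @param traj the matching trajectory; defaults to `raw$traj`.
#' @return list with `si_matrix` ((n_coils * n_samples) x n_SI real
#'   matrix), `si_times_ms`, and `si_readout_idx`.
#' @export
extract_si_matrix <- function(raw, traj = raw$traj) {
  stopifnot(inherits(raw, "freerun_raw"), inherits(traj, "freerun_trajectory"))
  si_idx <- which(traj$is_si)
  if (length(si_idx) == 0) stop("trajectory contains no SI readouts")
  ns <- dim(raw$samples)[1]
  n_coils <- dim(raw$samples)[3]
  shift <- function(v) v[c((ns %/% 2 + 1):ns, 1:(ns %/% 2))]  # fftshift, even ns
  blocks <- vector("list", n_coils)
  for (c in seq_len(n_coils)) {
    spokes <- raw$samples[, si_idx, c, drop = TRUE]
    if (is.null(dim(spokes))) spokes <- matrix(spokes, nrow = ns)
    # profile = |fftshift(ifft(ifftshift(spoke)))|; shifts are symmetric for even ns
    spokes <- apply(spokes, 2, shift)
    prof <- stats::mvfft(spokes, inverse = TRUE) / ns
    blocks[[c]] <- abs(apply(prof, 2, shift))
  }
  list(si_matrix = do.call(rbind, blocks),
       si_times_ms = traj$timestamps_ms[si_idx],
       si_readout_idx = si_idx)
}

# spectral power of series x (sampled at fs Hz) inside band [Hz]:
# absolute in-band power and its fraction of the total
band_power <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  p <- abs(stats::fft(x)[seq_len(n %/% 2 + 1)])^2
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  tot <- sum(p[f > 0])
  inband <- sum(p[f >= band[1] & f <= band[2]])
  c(power = inband, fraction = if (tot > 0) inband / tot else 0)
}

dominant_frequency <- function(x, fs, band = c(0, Inf)) {
  n <- length(x)
  x <- x - mean(x)
  p <- abs(stats::fft(x)[seq_len(n %/% 2 + 1)])^2
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2] & f > 0
  if (!any(sel)) return(NA_real_)
  f[sel][which.max(p[sel])]
}

butter_bandpass <- function(x, fs, band) {
  ny <- fs / 2
  lo <- max(band[1] / ny, 1e-4)
  hi <- min(band[2] / ny, 0.999)
  flt <- signal::butter(2, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(flt, x))
}

#' Derive cardiac and respiratory motion signals from the SI matrix by PCA
#'
#' Principal component analysis along the spatial (coil-position)
#' dimension of the SI navigator matrix yields temporal components; for
#' each physiological band the component with the largest absolute
#' spectral power inside the band (component variance times in-band
#' fraction, which favours large, band-concentrated components over
#' small noise components) is selected, band-pass filtered (2nd-order
#' Butterworth, zero-phase), and sign-oriented so that its sharper extreme
#' points upward (positive skewness) - for the cardiac signal this makes
#' the systolic excursion a maximum.
#'
#' @param si an [extract_si_matrix()] result.
#' @param si_interval_ms navigator sampling interval in ms.
#' @param cardiac_band_hz,resp_band_hz frequency bands (defaults 0.7-3 Hz,
#'   i.e. 42-180 bpm, and 0.08-0.7 Hz, i.e. 5-42 breaths/min).
#' @param n_components number of leading principal components searched.
#' @param min_power_frac minimal in-band power fraction below which gating
#'   is declared failed.
#' @return an object of class `freerun_physio`: `cardiac_signal`,
#'   `respiratory_signal` (at SI times), `si_times_ms`, selected component
#'   indices and in-band power fractions.
#' @export
derive_motion_signals <- function(si, si_interval_ms,
                                  cardiac_band_hz = c(0.7, 3),
                                  resp_band_hz = c(0.08, 0.7),
                                  n_components = 10,
                                  min_power_frac = 0.15) {
  fs <- 1000 / si_interval_ms
  if (fs < 2 * cardiac_band_hz[2])
    stop("SI sampling rate below twice the cardiac band upper edge")
  X <- si$si_matrix
  X <- X - rowMeans(X)
  k <- min(n_components, nrow(X), ncol(X))
  sv <- svd(X, nu = 0, nv = k)
  comps <- sv$v %*% diag(sv$d[seq_len(k)], k)    # temporal components
  pick <- function(band) {
    bp <- apply(comps, 2, band_power, fs = fs, band = band)
    idx <- which.max(bp["power", ])
    list(idx = idx, frac = bp["fraction", idx])
  }
  card <- pick(cardiac_band_hz)
  resp <- pick(resp_band_hz)
  if (card$frac < min_power_frac && resp$frac < min_power_frac)
    stop("gating failure: no principal component has sufficient in-band power")
  orient <- function(x) {
    s <- mean((x - mean(x))^3)
    if (s < 0) -x else x
  }
  cs <- orient(butter_bandpass(comps[, card$idx], fs, cardiac_band_hz))
  rs <- orient(butter_bandpass(comps[, resp$idx], fs, resp_band_hz))
  structure(list(cardiac_signal = cs, respiratory_signal = rs,
                 si_times_ms = si$si_times_ms,
                 cardiac_component = card$idx, cardiac_power_frac = card$frac,
                 resp_component = resp$idx, resp_power_frac = resp$frac,
                 si_interval_ms = si_interval_ms),
            class = "freerun_physio")
}

#' @export
print.freerun_physio <- function(x, ...) {
  cat(sprintf(paste0("Self-gating signals: %d SI samples every %.4g ms; ",
                     "cardiac PC %d (%.0f%% in-band), respiratory PC %d (%.0f%% in-band)\n"),
              length(x$cardiac_signal), x$si_interval_ms,
              x$cardiac_component, 100 * x$cardiac_power_frac,
              x$resp_component, 100 * x$resp_power_frac))
  if (!is.null(x$trigger_times_ms))
    cat(sprintf("  %d cardiac triggers, median RR %.0f ms\n",
                length(x$trigger_times_ms),
                stats::median(diff(x$trigger_times_ms))))
  invisible(x)
}

#' Detect cardiac triggers as local maxima of the cardiac signal
#'
#' One trigger per heartbeat from the band-limited cardiac self-gating
#' signal.  The fundamental heart rate is first estimated from the peak of
#' the autocorrelation function over the plausible RR range (0.33-1.43 s,
#' i.e. 42-180 bpm), which is robust against respiratory-modulation
#' sidebands and harmonics; the signal is then re-filtered to a narrow
#' band around the fundamental, and triggers are placed at its local
#' maxima, greedily pruned to a minimum separation of 60% of the
#' fundamental period (keeping the higher peak) and refined to sub-sample
#' precision by quadratic interpolation through the three samples around
#' each peak.  Triggers whose spacing falls outside [0.5, 1.5] x the
#' median RR are discarded.
#'
#' @param cardiac_signal numeric series at SI sampling times.
#' @param si_interval_ms SI sampling interval (ms).
#' @param si_times_ms optional sample times; defaults to a uniform grid.
#' @return numeric vector of trigger times (ms).
#' @export
detect_triggers <- function(cardiac_signal, si_interval_ms,
                            si_times_ms = NULL) {
  n <- length(cardiac_signal)
  if (is.null(si_times_ms)) si_times_ms <- (seq_len(n) - 1) * si_interval_ms
  if (stats::sd(cardiac_signal) == 0)
    stop("gating failure: cardiac signal is constant")
  fs <- 1000 / si_interval_ms
  # fundamental period from the autocorrelation peak in the 42-180 bpm range
  lag_min <- max(2L, floor(fs / 3))
  lag_max <- min(n - 2L, ceiling(fs * 1.43))
  if (lag_max <= lag_min)
    stop("gating failure: series too short for trigger detection")
  ac <- stats::acf(cardiac_signal, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1]
  lag0 <- (lag_min:lag_max)[which.max(ac[lag_min:lag_max])]
  f0 <- fs / lag0
  min_sep_ms <- 0.6 * 1000 / f0
  # suppress harmonics and modulation sidebands before peak picking
  x <- tryCatch(butter_bandpass(cardiac_signal, fs, c(0.7 * f0, 1.45 * f0)),
                error = function(e) cardiac_signal)
  cand <- which(diff(sign(diff(x))) < 0) + 1L       # strict local maxima
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(si_times_ms[i] - si_times_ms[keep]) >= min_sep_ms))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 3)
    stop("gating failure: fewer than 3 cardiac triggers detected")
  # quadratic sub-sample refinement
  tt <- vapply(keep, function(i) {
    if (i <= 1 || i >= n) return(si_times_ms[i])
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    den <- y0 - 2 * y1 + y2
    delta <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
    si_times_ms[i] + max(-1, min(1, delta)) * si_interval_ms
  }, numeric(1))
  med_rr <- stats::median(diff(tt))
  ok <- c(TRUE, diff(tt) >= 0.5 * med_rr & diff(tt) <= 1.5 * med_rr)
  tt <- tt[ok]
  if (length(tt) < 3)
    stop("gating failure: fewer than 3 plausible cardiac triggers")
  tt
}

#' Assign every readout to a (cardiac, respiratory) bin
#'
#' Cardiac binning is trigger-anchored: a readout at `t` falls into bin
#' `floor((t - last trigger) / bin_width_ms)`; the number of cardiac bins
#' is `floor(median RR / bin_width_ms)` and readouts beyond the last bin of
#' a beat are rejected, as are readouts outside the detected trigger range
#' and whole beats whose RR deviates more than 20% from the median.
#' Respiratory bins are amplitude quantiles of the interpolated
#' respiratory signal over the accepted readouts, with populations equal
#' to within one readout; bin 1 is end expiration (the lowest-amplitude
#' quantile after sign orientation).
#'
#' @param physio a [derive_motion_signals()] result, with triggers either
#'   already attached as `trigger_times_ms` or detected here.
#' @param traj the trajectory whose readouts are to be binned.
#' @param bin_width_ms cardiac bin width (default 50 ms).
#' @param n_resp number of respiratory bins (default 4).
#' @param rr_reject_frac fractional RR deviation from the median beyond
#'   which a beat is rejected (default 0.2).
#' @return an object of class `freerun_bins`: `cardiac_bin` and `resp_bin`
#'   (1-based integers, NA = rejected), `n_cardiac_bins`, `n_resp`,
#'   `bin_width_ms`, `phase_ms` (time since last trigger per readout),
#'   `resp_amplitude` (interpolated per readout), `trigger_times_ms`,
#'   `median_rr_ms`.
#' @export
assign_bins <- function(physio, traj, bin_width_ms = 50, n_resp = 4,
                        rr_reject_frac = 0.2) {
  stopifnot(inherits(physio, "freerun_physio"),
            inherits(traj, "freerun_trajectory"))
  trig <- physio$trigger_times_ms
  if (is.null(trig))
    trig <- detect_triggers(physio$cardiac_signal, physio$si_interval_ms,
                            physio$si_times_ms)
  rr <- diff(trig)
  med_rr <- stats::median(rr)
  if (med_rr < 2 * bin_width_ms)
    stop("median RR shorter than two cardiac bins")
  n_card <- as.integer(med_rr %/% bin_width_ms)
  t_ro <- traj$timestamps_ms
  n_ro <- length(t_ro)

  beat <- findInterval(t_ro, trig)     # 0 = before first trigger
  phase_ms <- rep(NA_real_, n_ro)
  cardiac_bin <- rep(NA_integer_, n_ro)
  in_beat <- beat >= 1 & beat <= length(rr)
  good_beat <- abs(rr - med_rr) <= rr_reject_frac * med_rr
  ok <- in_beat
  ok[ok] <- good_beat[beat[ok]]
  phase_ms[ok] <- t_ro[ok] - trig[beat[ok]]
  cb <- floor(phase_ms[ok] / bin_width_ms) + 1L
  cb[cb > n_card] <- NA_integer_
  cardiac_bin[ok] <- as.integer(cb)

  # respiratory amplitude interpolated linearly to every readout time
  resp_amp <- stats::approx(physio$si_times_ms, physio$respiratory_signal,
                            xout = t_ro, rule = 2)$y
  accepted <- !is.na(cardiac_bin)
  resp_bin <- rep(NA_integer_, n_ro)
  acc_idx <- which(accepted)
  m <- length(acc_idx)
  sizes <- rep(m %/% n_resp, n_resp)
  extra <- m %% n_resp
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- acc_idx[order(resp_amp[acc_idx])]
  resp_bin[ord] <- rep(seq_len(n_resp), times = sizes)

  structure(list(cardiac_bin = cardiac_bin, resp_bin = resp_bin,
                 n_cardiac_bins = n_card, n_resp = as.integer(n_resp),
                 bin_width_ms = bin_width_ms, phase_ms = phase_ms,
                 resp_amplitude = resp_amp, trigger_times_ms = trig,
                 median_rr_ms = med_rr),
            class = "freerun_bins")
}

#' @export
print.freerun_bins <- function(x, ...) {
  acc <- sum(!is.na(x$cardiac_bin))
  cat(sprintf(paste0("Bin assignment: %d cardiac bins x %d respiratory bins ",
                     "(width %g ms, median RR %.0f ms)\n  %d/%d readouts accepted (%.1f%%)\n"),
              x$n_cardiac_bins, x$n_resp, x$bin_width_ms, x$median_rr_ms,
              acc, length(x$cardiac_bin), 100 * acc / length(x$cardiac_bin)))
  invisible(x)
}

#' Run the complete self-gating chain on raw data
#'
#' Convenience wrapper: [extract_si_matrix()], [derive_motion_signals()],
#' [detect_triggers()], [assign_bins()].
#'
#' @param raw a `freerun_raw`.
#' @param bin_width_ms,n_resp see [assign_bins()].
#' @param ... passed to [derive_motion_signals()].
#' @return list with `physio` (triggers attached) and `bins`.
#' @export
self_gate <- function(raw, bin_width_ms = 50, n_resp = 4, ...) {
  si <- extract_si_matrix(raw)
  si_interval <- stats::median(diff(si$si_times_ms))
  physio <- derive_motion_signals(si, si_interval, ...)
  physio$trigger_times_ms <- detect_triggers(physio$cardiac_signal,
                                             si_interval, physio$si_times_ms)
  bins <- assign_bins(physio, raw$traj, bin_width_ms = bin_width_ms,
                      n_resp = n_resp)
  list(physio = physio, bins = bins)
}

#' Construct physiological gating signals directly
#'
#' Builds a `freerun_physio` object from explicit signal series, e.g. for
#' synthetic trigger trains or externally derived gating signals.
#'
#' @param cardiac_signal,respiratory_signal numeric series at the SI
#'   sampling times.
#' @param si_times_ms sampling times (ms).
#' @param si_interval_ms sampling interval (ms); defaults to the median
#'   spacing of `si_times_ms`.
#' @param trigger_times_ms optional pre-computed cardiac trigger times;
#'   when present, [assign_bins()] uses them as is.
#' @return a `freerun_physio` object.
#' @export
physio_signals <- function(cardiac_signal, respiratory_signal, si_times_ms,
                           si_interval_ms = stats::median(diff(si_times_ms)),
                           trigger_times_ms = NULL) {
  if (length(cardiac_signal) != length(si_times_ms) ||
      length(respiratory_signal) != length(si_times_ms))
    stop("signal series and si_times_ms must have equal length")
  if (!is.null(trigger_times_ms) && is.unsorted(trigger_times_ms,
                                                strictly = TRUE))
    stop("trigger times must be strictly increasing")
  structure(list(cardiac_signal = cardiac_signal,
                 respiratory_signal = respiratory_signal,
                 si_times_ms = si_times_ms,
                 si_interval_ms = si_interval_ms,
                 trigger_times_ms = trigger_times_ms),
            class = "freerun_physio")
}

#' Dominant frequencies of the derived gating signals
#'
#' Periodogram-peak frequencies of the cardiac and respiratory signal,
#' with the spectral resolution 1/T of the observation.
#'
#' @param physio a `freerun_physio`.
#' @return list with `cardiac_hz`, `resp_hz`, `resolution_hz`.
#' @export
signal_frequencies <- function(physio) {
  stopifnot(inherits(physio, "freerun_physio"))
  fs <- 1000 / physio$si_interval_ms
  t_obs_s <- diff(range(physio$si_times_ms)) / 1000
  list(cardiac_hz = dominant_frequency(physio$cardiac_signal, fs),
       resp_hz = dominant_frequency(physio$respiratory_signal, fs),
       resolution_hz = 1 / t_obs_s)
}
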