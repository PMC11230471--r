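#' Simulation parameters
#'
#' Parameter set for the synthetic session generator. The generator emulates
#' the statistical structure the normalization pipeline assumes: slow
#' multiplicative photobleaching per channel (double exponential), additive
#' motion artifacts affinely shared between channels (same waveform, channel
#' gain/offset), calcium transients (difference-of-exponentials kernel) whose
#' rate switches with locomotion state, a deterministic activity ramp tied to
#' movement offset (rising for `patch_like` coupling, declining for
#' `matrix_like`), white measurement noise, self-paced treadmill-style
#' velocity with alternating rest/movement epochs, and stimulation trains of
#' 2/5/15 s trials (10 per duration, >= 45 s gaps) with sustained suppression,
#' onset peak and post-offset rebound in the dopamine channel.
#'
#' Overrides are deep-merged into the defaults, e.g.
#' `sim_params(coupling = list(profile = "patch_like"))`.
#'
#' @param ... named sub-list overrides (`duration_s`, `sampling_rate`,
#'   `baseline`, `bleach`, `artifact`, `transient`, `coupling`, `noise`,
#'   `locomotion`, `stim`).
#' @return A list with class `"sim_params"`.
#' @export
sim_params <- function(...) {
  p <- list(
    duration_s = 60,
    sampling_rate = 1000,
    baseline = list(signal = 100, reference = 80),
    bleach = list(
      signal = list(a1 = 0.10, tau1 = 100, a2 = 0.05, tau2 = 1000),
      reference = list(a1 = 0.08, tau1 = 120, a2 = 0.04, tau2 = 1000)),
    artifact = list(rate_per_min = 6, amp_mean = 2, amp_sd = 0.5,
                    kernel_sd_s = 0.15, signal_gain = 1,
                    reference_gain = 0.8, reference_offset = 0,
                    positive_only = FALSE),
    transient = list(rise_s = 0.05, decay_s = 1.0, amplitude = 5,
                     amp_cv = 0.3, rate_move = 0.5, rate_rest = 0.05),
    coupling = list(profile = "none", lead_s = 0.5, amplitude = 5,
                    peak_delay_s = 0.25, decay_s = 0.3,
                    state_threshold_cms = 0.25),
    noise = list(signal_sd = 0.2, reference_sd = 0.2,
                 velocity_rest_sd = 0.05, velocity_move_sd = 0.3),
    locomotion = list(move_mean_s = 3, move_shape = 3, rest_mean_s = 4,
                      rest_shape = 2, move_velocity_mean = 4, ramp_s = 0.3,
                      schedule = NULL),
    stim = list(durations_s = c(2, 5, 15), trials_per_duration = 10,
                min_gap_s = 45, gap_jitter_s = 5, frequency_label = "20Hz",
                depth = -0.2, onset_peak = 0, peak_time_s = 0.4,
                peak_sd_s = 0.05, rebound = 0, rebound_center_s = 5,
                rebound_sd_s = 1, rise_s = 0.2, pre_s = 60)
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) stop("unknown sim_params field(s): ",
                              paste(unknown, collapse = ", "))
    p <- modifyList(p, overrides)
  }
  stopifnot(p$sampling_rate > 0, p$duration_s > 0)
  with(p$bleach$signal, stopifnot(tau1 > 0, tau2 > 0))
  with(p$bleach$reference, stopifnot(tau1 > 0, tau2 > 0))
  stopifnot(p$artifact$rate_per_min >= 0, p$transient$rate_move >= 0,
            p$transient$rate_rest >= 0, p$transient$rise_s > 0,
            p$transient$decay_s > 0, p$noise$signal_sd >= 0,
            p$noise$reference_sd >= 0)
  if (!p$coupling$profile %in% c("none", "patch_like", "matrix_like")) {
    stop("coupling$profile must be one of none / patch_like / matrix_like")
  }
  class(p) <- "sim_params"
  p
}

ground_truth <- function(...) structure(list(...), class = "ground_truth")

# Stationary AR(1) noise with marginal SD `sd` and correlation time `tau_s`.
smooth_noise <- function(n, sd, sampling_rate, tau_s = 0.05) {
  if (sd <= 0 || n == 0) return(numeric(n))
  phi <- exp(-1 / (sampling_rate * tau_s))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Causal convolution of an impulse train with a kernel, truncated to
# length(x). FFT-based, padded to a power of two (arbitrary-length FFTs can
# be orders of magnitude slower).
conv_causal <- function(x, kernel) {
  if (!any(x != 0)) return(numeric(length(x)))
  n <- length(x)
  m <- length(kernel)
  len <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(len - n))) *
                       stats::fft(c(kernel, numeric(len - m))),
                     inverse = TRUE)) / len
  y[seq_len(n)]
}

transient_kernel <- function(rise_s, decay_s, sampling_rate) {
  t <- seq(0, 6 * decay_s, by = 1 / sampling_rate)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)  # unit peak: amplitudes are in fluorescence units
}

gaussian_kernel <- function(sd_s, sampling_rate) {
  t <- seq(-4 * sd_s, 4 * sd_s, by = 1 / sampling_rate)
  exp(-t^2 / (2 * sd_s^2))
}

bleach_curve <- function(t, b) {
  (1 - b$a1 - b$a2) + b$a1 * exp(-t / b$tau1) + b$a2 * exp(-t / b$tau2)
}

#' Simulate self-paced treadmill locomotion
#'
#' Generates a velocity trace of alternating rest (near-zero, noise kept
#' strictly below the 0.25 cm/s movement threshold) and movement epochs
#' (smooth positive velocity around a configurable mean). Epoch durations are
#' gamma-distributed, or fixed exactly by
#' `locomotion$schedule = list(c(on, off), ...)`, in which case the velocity
#' is a plateau exactly inside each scheduled interval so bout boundaries are
#' recoverable to one sample. The generated epochs are recorded in the
#' returned ground truth.
#'
#' @param params a [sim_params()].
#' @param seed integer RNG seed; `(params, seed)` fully determine the output.
#' @return A list with elements `velocity` (a [velocity_trace()]) and `truth`
#'   (a `ground_truth` with `true_bouts`).
#' @export
simulate_locomotion <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (params$duration_s < 10) stop("parameter error: duration_s must be >= 10 s")
  fs <- params$sampling_rate
  dur <- params$duration_s
  n <- round(dur * fs)
  t <- seq(0, length.out = n, by = 1 / fs)
  loc <- params$locomotion
  nz <- params$noise
  with_seed(seed, {
    if (!is.null(loc$schedule)) {
      bouts <- do.call(rbind, lapply(loc$schedule, function(b) {
        data.frame(onset_s = b[1], offset_s = b[2])
      }))
      if (any(bouts$offset_s <= bouts$onset_s) || any(bouts$offset_s > dur)) {
        stop("parameter error: schedule intervals must be increasing and inside the session")
      }
      ramp_s <- 0  # exact plateaus: boundaries recoverable to one sample
    } else if (loc$move_mean_s <= 0) {
      bouts <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
      ramp_s <- loc$ramp_s
    } else {
      if (loc$move_mean_s + loc$rest_mean_s > dur) {
        stop("parameter error: mean epoch length exceeds the session duration")
      }
      ons <- offs <- numeric(0)
      cur <- 0
      repeat {
        rest <- max(1, rgamma(1, shape = loc$rest_shape,
                              scale = loc$rest_mean_s / loc$rest_shape))
        move <- max(1, rgamma(1, shape = loc$move_shape,
                              scale = loc$move_mean_s / loc$move_shape))
        on <- cur + rest
        off <- on + move
        if (off > dur - 0.5) break
        ons <- c(ons, on)
        offs <- c(offs, off)
        cur <- off
      }
      bouts <- data.frame(onset_s = ons, offset_s = offs)
      ramp_s <- loc$ramp_s
    }
    v <- pmin(pmax(smooth_noise(n, nz$velocity_rest_sd, fs), -0.2), 0.2)
    if (nrow(bouts)) {
      wobble <- smooth_noise(n, nz$velocity_move_sd, fs, tau_s = 0.3)
      for (i in seq_len(nrow(bouts))) {
        on <- bouts$onset_s[i]
        off <- bouts$offset_s[i]
        idx <- which(t >= on & t < off)
        vmean <- loc$move_velocity_mean * runif(1, 0.85, 1.15)
        prof <- rep(vmean, length(idx))
        if (ramp_s > 0) {
          up <- pmin(1, (t[idx] - on) / ramp_s)
          down <- pmin(1, (off - t[idx]) / ramp_s)
          prof <- vmean * pmin(up, down)
        }
        v[idx] <- prof + if (ramp_s > 0) wobble[idx] * pmin(1, prof / vmean) else 0
      }
    }
    truth <- ground_truth(true_bouts = bouts, true_coupling_profile = "none",
                          rng_seed = seed)
    list(velocity = velocity_trace(v, fs), truth = truth)
  })
}

coupling_trace <- function(t, bouts, cp, fs) {
  c_t <- numeric(length(t))
  ramp_peaks <- numeric(0)
  if (cp$profile == "none" || nrow(bouts) == 0) {
    return(list(trace = c_t, ramp_peaks = ramp_peaks))
  }
  for (i in seq_len(nrow(bouts))) {
    on <- bouts$onset_s[i]
    off <- bouts$offset_s[i]
    if (cp$profile == "patch_like") {
      # linear rise from (offset - lead) to a peak just after offset, then decay
      start <- max(on, off - cp$lead_s)
      peak_t <- off + cp$peak_delay_s
      rise_idx <- which(t >= start & t < peak_t)
      c_t[rise_idx] <- c_t[rise_idx] +
        cp$amplitude * (t[rise_idx] - start) / (peak_t - start)
      dec_idx <- which(t >= peak_t & t < peak_t + 6 * cp$decay_s)
      c_t[dec_idx] <- c_t[dec_idx] +
        cp$amplitude * exp(-(t[dec_idx] - peak_t) / cp$decay_s)
      ramp_peaks <- c(ramp_peaks, peak_t)
    } else {  # matrix_like: sustained movement activity declining before offset
      start <- max(on, off - cp$lead_s)
      plat_idx <- which(t >= on & t < start)
      c_t[plat_idx] <- c_t[plat_idx] + cp$amplitude
      dec_idx <- which(t >= start & t < off)
      c_t[dec_idx] <- c_t[dec_idx] +
        cp$amplitude * (off - t[dec_idx]) / (off - start)
      ramp_peaks <- c(ramp_peaks, start)
    }
  }
  list(trace = c_t, ramp_peaks = ramp_peaks)
}

#' Simulate a two-channel photometry session
#'
#' Generative model: `signal = bleach_s * (baseline_s + transients + coupling)
#' + gain_s * artifact + noise_s` and `reference = bleach_r * baseline_r +
#' gain_r * artifact + offset_r + noise_r`. Bleaching is multiplicative and
#' channel-specific; the motion artifact is one waveform shared affinely by
#' both channels (exactly the model the RANSAC referencing assumes); calcium
#' transients occur at Poisson times with a rate switched by the locomotion
#' state derived from `velocity`; the coupling ramp follows
#' `params$coupling$profile` (`patch_like` peaks after each movement offset,
#' `matrix_like` declines before it).
#'
#' @param params a [sim_params()].
#' @param velocity optional [velocity_trace()] on the same time base (its
#'   movement state gates the transient rate and anchors the coupling ramp).
#' @param seed integer RNG seed.
#' @return A list with elements `session` (a [photometry_session()]) and
#'   `truth` (a `ground_truth` with the artifact trace, transient times,
#'   bleach parameters, coupling profile and ramp peak times).
#' @export
simulate_photometry <- function(params = sim_params(), velocity = NULL,
                                seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  fs <- params$sampling_rate
  n <- round(params$duration_s * fs)
  t <- seq(0, length.out = n, by = 1 / fs)
  if (!is.null(velocity)) {
    if (length(velocity$velocity) != n ||
        abs(velocity$sampling_rate - fs) > 1e-9) {
      stop("parameter error: velocity time base must match the session")
    }
  }
  with_seed(seed, {
    state <- if (is.null(velocity)) rep(FALSE, n) else
      abs(velocity$velocity) > params$coupling$state_threshold_cms
    runs <- logical_runs(state)
    bouts <- if (nrow(runs)) {
      data.frame(onset_s = t[runs$start], offset_s = t[runs$end] + 1 / fs)
    } else {
      data.frame(onset_s = numeric(0), offset_s = numeric(0))
    }
    tr <- params$transient
    rate <- ifelse(state, tr$rate_move, tr$rate_rest)
    spikes <- runif(n) < rate / fs
    amps <- numeric(n)
    n_sp <- sum(spikes)
    if (n_sp && tr$amplitude > 0) {
      amps[spikes] <- rlnorm(n_sp, meanlog = log(tr$amplitude) - tr$amp_cv^2 / 2,
                             sdlog = tr$amp_cv)
    }
    transients <- conv_causal(amps, transient_kernel(tr$rise_s, tr$decay_s, fs))
    cpl <- coupling_trace(t, bouts, params$coupling, fs)
    ar <- params$artifact
    n_art <- if (ar$rate_per_min > 0)
      rbinom(1, n, min(1, ar$rate_per_min / 60 / fs)) else 0L
    art_imp <- numeric(n)
    if (n_art > 0) {
      at <- sample.int(n, n_art)
      amps <- abs(rnorm(n_art, ar$amp_mean, ar$amp_sd))
      if (!isTRUE(ar$positive_only)) {
        amps <- amps * sample(c(-1, 1), n_art, replace = TRUE)
      }
      art_imp[at] <- amps
    }
    artifact <- conv_causal(art_imp, gaussian_kernel(ar$kernel_sd_s, fs))
    b_s <- bleach_curve(t, params$bleach$signal)
    b_r <- bleach_curve(t, params$bleach$reference)
    noise_s <- if (params$noise$signal_sd > 0)
      rnorm(n, 0, params$noise$signal_sd) else numeric(n)
    noise_r <- if (params$noise$reference_sd > 0)
      rnorm(n, 0, params$noise$reference_sd) else numeric(n)
    signal <- b_s * (params$baseline$signal + transients + cpl$trace) +
      ar$signal_gain * artifact + noise_s
    reference <- b_r * params$baseline$reference +
      ar$reference_gain * artifact + ar$reference_offset + noise_r
    events <- list()
    if (nrow(bouts)) {
      ev_on <- pmin(bouts$onset_s, t[n])
      ev_off <- pmin(bouts$offset_s, t[n])
      ok <- ev_off > ev_on
      if (any(ok)) events <- list(event_train("locomotion", ev_on[ok], ev_off[ok]))
    }
    session <- photometry_session(
      signal = signal, reference = reference, sampling_rate = fs,
      sensor_kind = "gcamp", time = t, events = events,
      meta = list(synthetic = TRUE, rng_seed = seed))
    truth <- ground_truth(
      true_bouts = bouts,
      true_transient_times = t[spikes],
      true_artifact_trace = artifact,
      true_bleach_params = params$bleach,
      true_coupling_profile = params$coupling$profile,
      true_coupling_trace = cpl$trace,
      true_ramp_peaks = cpl$ramp_peaks,
      rng_seed = seed)
    list(session = session, truth = truth)
  })
}

window_mean <- function(x, t, a, b) mean(x[t >= a & t < b])

#' Simulate an optogenetic-stimulation photometry session (dopamine sensor)
#'
#' Builds a stimulation protocol of 2/5/15 s trials (default 10 per duration,
#' shuffled) separated by gaps of at least 45 s, and injects into the rDA3m
#' channel, per trial: a sustained fractional dF/F shift of `stim$depth`
#' (exponential rise/return with time constant `stim$rise_s`), an optional
#' onset transient (Gaussian, centred `stim$peak_time_s` after onset) and an
#' optional post-offset rebound bump (Gaussian, centred `stim$rebound_center_s`
#' after offset). Both channels share one bleaching shape (the signal
#' channel's), which is the regime where a single affine reference map is
#' exact. Session duration is derived from the protocol; `duration_s` is
#' ignored here.
#'
#' The ground truth records, per trial, the injected response averaged over
#' the analysis windows of the stimulation metrics (baseline-subtracted), by
#' directly evaluating the noiseless generative response — no pipeline
#' involved.
#'
#' @param params a [sim_params()]; `params$stim` holds the protocol.
#' @param seed integer RNG seed.
#' @return A list with elements `session` (sensor kind `"rdam"`, with a
#'   `"stim"` event train) and `truth` (per-trial `true_stim_response`).
#' @export
simulate_stim_session <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  st <- params$stim
  if (st$min_gap_s < 45) {
    stop("parameter error: inter-trial gaps below the 45 s protocol minimum")
  }
  fs <- params$sampling_rate
  with_seed(seed, {
    durs <- rep(st$durations_s, each = st$trials_per_duration)
    durs <- durs[sample.int(length(durs))]
    n_tr <- length(durs)
    gaps <- st$min_gap_s + runif(n_tr, 0, st$gap_jitter_s)
    onsets <- numeric(n_tr)
    onsets[1] <- st$pre_s
    if (n_tr > 1) {
      for (i in 2:n_tr) onsets[i] <- onsets[i - 1] + durs[i - 1] + gaps[i - 1]
    }
    offsets <- onsets + durs
    total <- offsets[n_tr] + 15
    n <- round(total * fs)
    t <- seq(0, length.out = n, by = 1 / fs)
    # noiseless fractional response r(t)
    r <- numeric(n)
    for (i in seq_len(n_tr)) {
      on <- onsets[i]; off <- offsets[i]
      idx_on <- which(t >= on & t < off)
      r[idx_on] <- r[idx_on] + st$depth * (1 - exp(-(t[idx_on] - on) / st$rise_s))
      s_off <- st$depth * (1 - exp(-durs[i] / st$rise_s))
      idx_off <- which(t >= off & t < off + 10 * st$rise_s)
      r[idx_off] <- r[idx_off] + s_off * exp(-(t[idx_off] - off) / st$rise_s)
      if (st$onset_peak != 0) {
        pk <- on + st$peak_time_s
        idx <- which(t >= pk - 5 * st$peak_sd_s & t < pk + 5 * st$peak_sd_s)
        r[idx] <- r[idx] + st$onset_peak * exp(-(t[idx] - pk)^2 / (2 * st$peak_sd_s^2))
      }
      if (st$rebound != 0) {
        rc <- off + st$rebound_center_s
        idx <- which(t >= rc - 5 * st$rebound_sd_s & t < rc + 5 * st$rebound_sd_s)
        r[idx] <- r[idx] + st$rebound * exp(-(t[idx] - rc)^2 / (2 * st$rebound_sd_s^2))
      }
    }
    ar <- params$artifact
    n_art <- if (ar$rate_per_min > 0)
      rbinom(1, n, min(1, ar$rate_per_min / 60 / fs)) else 0L
    art_imp <- numeric(n)
    if (n_art > 0) {
      at <- sample.int(n, n_art)
      amps <- abs(rnorm(n_art, ar$amp_mean, ar$amp_sd))
      if (!isTRUE(ar$positive_only)) {
        amps <- amps * sample(c(-1, 1), n_art, replace = TRUE)
      }
      art_imp[at] <- amps
    }
    artifact <- conv_causal(art_imp, gaussian_kernel(ar$kernel_sd_s, fs))
    b <- bleach_curve(t, params$bleach$signal)  # shared bleaching shape
    noise_s <- if (params$noise$signal_sd > 0)
      rnorm(n, 0, params$noise$signal_sd) else numeric(n)
    noise_r <- if (params$noise$reference_sd > 0)
      rnorm(n, 0, params$noise$reference_sd) else numeric(n)
    signal <- b * params$baseline$signal * (1 + r) +
      ar$signal_gain * artifact + noise_s
    reference <- b * params$baseline$reference +
      ar$reference_gain * artifact + ar$reference_offset + noise_r
    resp <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
      on <- onsets[i]; off <- offsets[i]
      base <- window_mean(r, t, on - 2, on)
      data.frame(trial = i, duration_s = durs[i],
                 onset_s = on, offset_s = off,
                 true_baseline = base,
                 true_reduction = window_mean(r, t, off - 0.2, off) - base,
                 true_peak = window_mean(r, t, on + 0.35, on + 0.45) - base,
                 true_post = window_mean(r, t, off + 3, off + 8) - base)
    }))
    session <- photometry_session(
      signal = signal, reference = reference, sampling_rate = fs,
      sensor_kind = "rdam", time = t,
      events = list(event_train("stim", onsets, offsets)),
      meta = list(synthetic = TRUE, rng_seed = seed,
                  stim_frequency = st$frequency_label))
    truth <- ground_truth(
      true_stim_response = resp,
      true_response_trace = r,
      true_artifact_trace = artifact,
      true_bleach_params = params$bleach$signal,
      rng_seed = seed)
    list(session = session, truth = truth)
  })
}
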