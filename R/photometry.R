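#' Sliding-percentile baseline (F0)
#'
#' Estimates the slow baseline F0 as a running percentile (default: 10th
#' percentile over a 5 s window) of the raw fluorescence, which tracks slow
#' correlated changes such as photobleaching while ignoring transients. The
#' window at each sample is centred and clipped at the session bounds
#' (shrinking at the edges, no padding); the percentile uses linear
#' interpolation between order statistics (the `stats::quantile()` type 7
#' rule), so the output equals a brute-force per-window percentile at every
#' sample.
#'
#' @param trace fluorescence series (finite values).
#' @param sampling_rate Hz.
#' @param window_s window width in seconds (default 5).
#' @param percentile percentile rank in (0, 100) (default 10).
#' @return Numeric baseline series, same length as `trace`.
#' @export
sliding_percentile_baseline <- function(trace, sampling_rate, window_s = 5,
                                        percentile = 10) {
  if (window_s <= 0 || percentile <= 0 || percentile >= 100) {
    stop("parameter error: window_s must be > 0 and percentile in (0, 100)")
  }
  if (!all(is.finite(trace))) {
    stop("data error: non-finite value at row ", which(!is.finite(trace))[1])
  }
  nw <- round(window_s * sampling_rate)
  if (nw < 2) stop("parameter error: window shorter than 2 samples")
  half <- nw %/% 2L
  sliding_percentile_cpp(as.numeric(trace), as.integer(half),
                         percentile / 100)
}

#' Pre-normalize a channel: dF/F0
#'
#' `out = (trace - baseline) / baseline`, elementwise. The baseline must stay
#' above a small positive guard (relative to its session median) everywhere.
#'
#' @param trace raw fluorescence series.
#' @param baseline F0 series from [sliding_percentile_baseline()].
#' @param epsilon_rel guard on the divisor, relative to `median(baseline)`.
#' @return dF/F0 series (dimensionless fraction).
#' @export
prenormalize <- function(trace, baseline, epsilon_rel = 1e-9) {
  if (length(trace) != length(baseline)) stop("length mismatch")
  eps <- epsilon_rel * abs(median(baseline))
  bad <- which(baseline <= eps)
  if (length(bad)) {
    stop("numeric-guard error: baseline <= epsilon at index ", bad[1])
  }
  (trace - baseline) / baseline
}

# Zero-phase Butterworth low-pass with odd-reflection padding (~3/fc s) so
# that edge transients from the zero initial conditions of the underlying
# filter passes decay inside the pad, not the data.
zero_phase_lowpass <- function(x, corner_hz, order, sampling_rate) {
  n <- length(x)
  bf <- signal::butter(order, corner_hz / (sampling_rate / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * sampling_rate / corner_hz))
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    y <- signal::filtfilt(bf, c(pre, x, post))
    y[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Low-pass filter the pre-normalized reference
#'
#' Second-order Butterworth low-pass (3 Hz corner by default) applied
#' zero-phase (forward-backward), DC gain 1. Zero-phase filtering is used
#' because the analysis is offline and phase lag would bias event-aligned
#' timing statistics.
#'
#' @param prenorm_reference reference dF/F0 series.
#' @param sampling_rate Hz.
#' @param corner_hz corner frequency (default 3).
#' @param order filter order (default 2; applied twice by the
#'   forward-backward pass, so the tone power response is
#'   `1 / (1 + (f/fc)^(2*order))^2`).
#' @return Filtered series.
#' @export
lowpass_reference <- function(prenorm_reference, sampling_rate,
                              corner_hz = 3, order = 2) {
  if (corner_hz <= 0 || corner_hz >= sampling_rate / 2) {
    stop("parameter error: corner frequency must lie in (0, Nyquist)")
  }
  zero_phase_lowpass(prenorm_reference, corner_hz, order, sampling_rate)
}

#' Robust affine fit of the reference to the signal (RANSAC)
#'
#' Random-sample-consensus ordinary-least-squares regression
#' `signal ~ slope * reference + intercept`, used to transform the reference
#' channel to the signal channel's gain and offset while rejecting samples
#' (e.g. large transients) that do not follow the shared-artifact relation.
#' Candidate lines are fitted through random sample pairs; the consensus set
#' is the samples whose absolute residual does not exceed the threshold
#' (default: one raw median absolute deviation of the signal about its
#' median — the conventional RANSAC residual threshold). Thresholding on the
#' response spread, not on the OLS residual spread, matters here: when
#' artifacts are sparse the OLS residuals are noise-scale, and a noise-scale
#' band would reject the very artifact samples that determine the slope. The
#' winning consensus set (largest, ties by residual sum of squares) is
#' refitted by OLS. Deterministic given `seed`.
#'
#' @param reference,signal equal-length numeric series.
#' @param n_iterations number of random candidate pairs (default 100).
#' @param min_samples samples per candidate (2: a line through two points).
#' @param residual_threshold inlier band half-width; `NA` = 1 MAD of the
#'   signal about its median (raw, unscaled), floored at
#'   `1e-12 * (1 + max|signal|)`.
#' @param seed RNG seed for the candidate sampling.
#' @return A list of class `"ransac_fit"`: `slope`, `intercept`,
#'   `inlier_mask`, `n_iterations`, `residual_threshold`, `min_samples`,
#'   `seed`.
#' @export
fit_reference <- function(reference, signal, n_iterations = 100,
                          min_samples = 2, residual_threshold = NA,
                          seed = 42) {
  n <- length(reference)
  if (length(signal) != n) stop("length mismatch")
  if (n < min_samples) stop("fit error: fewer samples than min_samples")
  if (var(reference) <= 0 || !is.finite(var(reference))) {
    stop("fit error: degenerate reference (zero variance)")
  }
  ols <- function(x, y) {
    b <- cov(x, y) / var(x)
    c(intercept = mean(y) - b * mean(x), slope = b)
  }
  base <- ols(reference, signal)
  thr <- residual_threshold
  if (is.na(thr)) thr <- median(abs(signal - median(signal)))
  thr <- max(thr, 1e-12 * (1 + max(abs(signal))))
  score <- function(fit) {
    res <- abs(signal - (fit[1] + fit[2] * reference))
    mask <- res <= thr
    list(fit = fit, mask = mask, n_in = sum(mask), rss = sum(res[mask]^2))
  }
  best <- score(base)
  with_seed(seed, {
    for (k in seq_len(n_iterations)) {
      idx <- sample.int(n, min_samples)
      x <- reference[idx]
      y <- signal[idx]
      if (var(x) <= 0) next
      cand <- score(ols(x, y))
      if (cand$n_in > best$n_in ||
          (cand$n_in == best$n_in && cand$rss < best$rss)) {
        best <- cand
      }
    }
  })
  if (best$n_in < min_samples) stop("fit error: no consensus set found")
  final <- ols(reference[best$mask], signal[best$mask])
  structure(list(slope = unname(final[2]), intercept = unname(final[1]),
                 inlier_mask = best$mask, n_iterations = n_iterations,
                 residual_threshold = thr, min_samples = min_samples,
                 seed = seed),
            class = "ransac_fit")
}

#' Subtract the transformed reference from the normalized signal
#'
#' `transformed = slope * filtered_reference + intercept` (the "UV dF/F");
#' `dff = prenorm_signal - transformed` is the final dF/F.
#'
#' @param prenorm_signal signal-channel dF/F0 series.
#' @param fit a [fit_reference()] result.
#' @param filtered_reference low-pass-filtered reference dF/F0 series.
#' @return A list with `dff` and `transformed_reference`.
#' @export
reference_subtract <- function(prenorm_signal, fit, filtered_reference) {
  if (length(prenorm_signal) != length(filtered_reference)) {
    stop("length mismatch")
  }
  transformed <- fit$slope * filtered_reference + fit$intercept
  list(dff = prenorm_signal - transformed,
       transformed_reference = transformed)
}

#' Quality-control gate
#'
#' Inclusion rule for GCaMP sessions: the session maximum of dF/F, expressed
#' in percent, must exceed `qc_min_max_dff_percent` (default 1.5), and the
#' Pearson correlation between the GCaMP trace and the transformed UV
#' reference must stay below `qc_max_reference_corr` (default 0.6). Sessions
#' failing either condition are excluded from further analysis.
#'
#' The correlation operand matters: the final dF/F is an OLS residual with
#' respect to the transformed reference, so it is close to orthogonal to it
#' by construction and would make the gate vacuous. The gate therefore
#' correlates the normalized (pre-subtraction) GCaMP trace with the UV dF/F
#' by default — a session dominated by shared artifacts shows a high
#' correlation there and is excluded. Pass `corr_trace` to use another
#' operand.
#'
#' @param dff final dF/F series (used for the amplitude criterion).
#' @param transformed_reference the transformed (UV) reference series.
#' @param corr_trace trace correlated against the reference; defaults to
#'   `dff`. [normalize_gcamp()] passes the trace named by the
#'   `qc_corr_operand` config field (default: the pre-normalized signal).
#' @param min_max_dff_percent,max_reference_corr thresholds.
#' @return A list of class `"qc_result"`: `max_dff_percent`,
#'   `signal_reference_correlation`, `passed`, `thresholds`.
#' @export
qc_gate <- function(dff, transformed_reference, corr_trace = dff,
                    min_max_dff_percent = 1.5, max_reference_corr = 0.6) {
  if (!all(is.finite(dff))) stop("data error: non-finite dff")
  max_pct <- 100 * max(dff)
  r <- if (sd(corr_trace) > 0 && sd(transformed_reference) > 0) {
    cor(corr_trace, transformed_reference)
  } else {
    0
  }
  structure(list(
    max_dff_percent = max_pct,
    signal_reference_correlation = r,
    passed = (max_pct > min_max_dff_percent) && (r < max_reference_corr),
    thresholds = c(min_max_dff_percent = min_max_dff_percent,
                   max_reference_corr = max_reference_corr)),
    class = "qc_result")
}

new_normalized_trace <- function(session, dff, zscore, f0_signal, f0_reference,
                                 prenorm_signal, prenorm_reference,
                                 transformed_reference, fit, qc, chain) {
  structure(list(time = session$time, sampling_rate = session$sampling_rate,
                 dff = dff, zscore = zscore, f0_signal = f0_signal,
                 f0_reference = f0_reference, prenorm_signal = prenorm_signal,
                 prenorm_reference = prenorm_reference,
                 transformed_reference = transformed_reference, fit = fit,
                 qc = qc, chain = chain, events = session$events,
                 meta = session$meta),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %s chain, %d samples @ %g Hz, QC %s (max dF/F %.2f%%, ref corr %.2f)\n",
              x$chain, length(x$dff), x$sampling_rate,
              if (x$qc$passed) "pass" else "FAIL",
              x$qc$max_dff_percent, x$qc$signal_reference_correlation))
  invisible(x)
}

session_zscore <- function(dff) {
  s <- sd(dff)
  if (s > 0) (dff - mean(dff)) / s else dff * 0
}

#' Normalize a GCaMP session (behavioral-analysis chain)
#'
#' Full normalization chain for GCaMP8s recordings: (1) sliding-percentile F0
#' per channel; (2) dF/F0 pre-normalization of both channels; (3) zero-phase
#' Butterworth low-pass of the reference dF/F0; (4) RANSAC affine fit of the
#' filtered reference to the normalized signal; (5) subtraction of the
#' transformed reference as the final dF/F (the transformed trace is kept as
#' UV dF/F); (6) QC gate; (7) z-score using the mean and standard deviation of
#' the entire recording session.
#'
#' If the filtered reference is (numerically) constant, it carries no
#' artifact information and step (4)-(5) degrade to an identity pass
#' (`transformed = 0`, `dff = prenorm_signal`); the fit slot records this.
#'
#' @param session a [photometry_session()] with `sensor_kind == "gcamp"`.
#' @param config a [pipeline_config()].
#' @return A `"normalized_trace"` with all intermediates, the RANSAC fit, the
#'   QC verdict and the session z-score.
#' @export
normalize_gcamp <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "photometry_session"))
  if (session$sensor_kind != "gcamp") {
    stop("precondition error: normalize_gcamp requires a gcamp session")
  }
  fs <- session$sampling_rate
  f0_s <- sliding_percentile_baseline(session$signal, fs,
                                      config$f0_window_s, config$f0_percentile)
  f0_r <- sliding_percentile_baseline(session$reference, fs,
                                      config$f0_window_s, config$f0_percentile)
  pre_s <- prenormalize(session$signal, f0_s, config$baseline_epsilon_rel)
  pre_r <- prenormalize(session$reference, f0_r, config$baseline_epsilon_rel)
  filt_r <- lowpass_reference(pre_r, fs, config$ref_corner_hz,
                              config$ref_filter_order)
  if (var(filt_r) <= 1e-24) {
    fit <- structure(list(slope = 0, intercept = 0, inlier_mask = NULL,
                          degenerate_reference = TRUE),
                     class = "ransac_fit")
  } else {
    fit <- fit_reference(filt_r, pre_s,
                         n_iterations = config$ransac_iterations,
                         min_samples = config$ransac_min_samples,
                         residual_threshold = config$ransac_residual_threshold,
                         seed = config$ransac_seed)
  }
  sub <- reference_subtract(pre_s, fit, filt_r)
  corr_trace <- if (config$qc_corr_operand == "prenorm") pre_s else sub$dff
  qc <- qc_gate(sub$dff, sub$transformed_reference, corr_trace = corr_trace,
                min_max_dff_percent = config$qc_min_max_dff_percent,
                max_reference_corr = config$qc_max_reference_corr)
  new_normalized_trace(session, dff = sub$dff,
                       zscore = session_zscore(sub$dff),
                       f0_signal = f0_s, f0_reference = f0_r,
                       prenorm_signal = pre_s, prenorm_reference = pre_r,
                       transformed_reference = sub$transformed_reference,
                       fit = fit, qc = qc, chain = "gcamp")
}

#' Normalize an rDA3m session (stimulation chain)
#'
#' Referencing chain for red dopamine-sensor recordings under optogenetic
#' stimulation, designed to retain the large sustained offset the stimulation
#' causes: a RANSAC affine regression is fitted between the raw demodulated
#' UV reference and the raw demodulated rDA3m signal (no percentile baseline,
#' no pre-normalization); the referenced signal `F = slope * reference +
#' intercept` is subtracted from the raw signal to give `dF = signal - F`,
#' and `dF/F = dF / F` with a positive-divisor guard. A session z-score of
#' dF/F is also provided.
#'
#' @param session a [photometry_session()] with `sensor_kind == "rdam"`.
#' @param config a [pipeline_config()].
#' @return A `"normalized_trace"` (chain `"rdam"`). The QC slot records the
#'   same two statistics for reference, computed on dF/F vs the referenced F.
#' @export
normalize_rdam <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "photometry_session"))
  if (session$sensor_kind != "rdam") {
    stop("precondition error: normalize_rdam requires an rdam session")
  }
  fit <- fit_reference(session$reference, session$signal,
                       n_iterations = config$ransac_iterations,
                       min_samples = config$ransac_min_samples,
                       residual_threshold = config$ransac_residual_threshold,
                       seed = config$ransac_seed)
  f_ref <- fit$slope * session$reference + fit$intercept
  eps <- config$baseline_epsilon_rel * abs(median(f_ref))
  bad <- which(f_ref <= eps)
  if (length(bad)) {
    stop("numeric-guard error: referenced F <= epsilon at index ", bad[1])
  }
  dff <- (session$signal - f_ref) / f_ref
  qc <- qc_gate(dff, f_ref,
                min_max_dff_percent = config$qc_min_max_dff_percent,
                max_reference_corr = config$qc_max_reference_corr)
  new_normalized_trace(session, dff = dff, zscore = session_zscore(dff),
                       f0_signal = NULL, f0_reference = NULL,
                       prenorm_signal = NULL, prenorm_reference = NULL,
                       transformed_reference = f_ref, fit = fit, qc = qc,
                       chain = "rdam")
}
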