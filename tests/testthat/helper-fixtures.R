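# Shared helpers: independent oracles and small fixture constructors.

# Brute-force per-window percentile (the oracle for the sliding baseline):
# centred window of round(window_s * fs) samples (half-width floor(nw/2)),
# clipped at the bounds, quantile type 7.
brute_percentile <- function(x, fs, window_s, p) {
  half <- round(window_s * fs) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    unname(quantile(x[lo:hi], p / 100, type = 7, names = FALSE))
  }, numeric(1))
}

# A small valid session with deterministic content.
tiny_session <- function(n = 200, fs = 100, sensor_kind = "gcamp",
                         events = list(), meta = list()) {
  t <- seq(0, length.out = n, by = 1 / fs)
  photometry_session(signal = 100 + sin(2 * pi * t),
                     reference = 80 + 0.5 * sin(2 * pi * t),
                     sampling_rate = fs, sensor_kind = sensor_kind,
                     events = events, meta = meta)
}

# A velocity trace holding the given value on each [on, off) interval, zero
# elsewhere.
schedule_velocity <- function(schedule, duration_s, fs = 1000, level = 4) {
  n <- round(duration_s * fs)
  t <- seq(0, length.out = n, by = 1 / fs)
  v <- numeric(n)
  for (b in schedule) v[t >= b[1] & t < b[2]] <- level
  velocity_trace(v, fs)
}

# Construct a normalized-trace-like pair (dff, transformed reference) with a
# target maximum dF/F (percent) and a target correlation, for QC-gate tests.
qc_fixture <- function(max_pct, rho, n = 2000) {
  t <- seq_len(n) / n
  ref <- sin(2 * pi * 4 * t)
  orth <- cos(2 * pi * 4 * t)
  x <- rho * ref + sqrt(1 - rho^2) * orth
  x <- x * (max_pct / 100) / max(x)
  list(dff = x, transformed = ref)
}
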