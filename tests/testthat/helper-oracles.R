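# Shared fixtures and independent oracles used across test files.

.fixture_env <- new.env()

# one standard noiseless plasma/input fixture per test session
fixture_plasma_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    .fixture_env$fits <- fit_plasma_pipeline(simulate_plasma())
  }
  .fixture_env$fits
}

# Brute-force oracle for the forward 2TC model: trapezoidal numerical
# convolution of the impulse response with the input on a fine grid, then
# trapezoidal frame averages. Entirely independent of the closed-form path.
oracle_model_tac <- function(params, input, schedule, dt = 0.005) {
  p <- as.numeric(params[c("K1", "k2", "k3", "k4")])
  tg <- seq(0, max(schedule$start + schedule$duration), by = dt)
  cp <- predict(input, tg)
  S <- p[2] + p[3] + p[4]
  disc <- max(S^2 - 4 * p[2] * p[4], 0)
  a1 <- (S - sqrt(disc)) / 2
  a2 <- (S + sqrt(disc)) / 2
  k34 <- p[3] + p[4]
  h <- if ((a2 - a1) > 1e-9 * max(a2, 1e-12)) {
    p[1] / (a2 - a1) * ((k34 - a1) * exp(-a1 * tg) + (a2 - k34) * exp(-a2 * tg))
  } else {
    a <- S / 2
    p[1] * (exp(-a * tg) + (k34 - a) * tg * exp(-a * tg))
  }
  ct <- dt * stats::convolve(h, rev(cp), type = "open")[seq_along(tg)] -
    dt / 2 * (h * cp[1] + h[1] * cp)
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- which(tg >= schedule$start[i] - 1e-12 &
                   tg <= schedule$start[i] + schedule$duration[i] + 1e-12)
    x <- ct[sel]
    (sum(x) - (x[1] + x[length(x)]) / 2) * dt / schedule$duration[i]
  }, numeric(1))
}

# Hand-computed split-plot sums of squares: scans (subject x condition) are
# the units, condition between units, region within.
oracle_split_plot <- function(data) {
  data$scan <- interaction(data$subject, data$condition, drop = TRUE)
  m <- mean(data$value)
  N <- nlevels(data$scan)
  r <- length(unique(data$region))
  a <- length(unique(data$condition))
  n_per <- N / a
  scan_means <- tapply(data$value, data$scan, mean)
  cond_means <- tapply(data$value, data$condition, mean)
  region_means <- tapply(data$value, data$region, mean)
  cell <- tapply(data$value, list(data$condition, data$region), mean)
  ss_between <- r * sum((scan_means - m)^2)
  ss_cond <- n_per * r * sum((cond_means - m)^2)
  ss_scan_err <- ss_between - ss_cond
  ss_region <- N * sum((region_means - m)^2)
  ss_inter <- n_per * sum((cell - outer(cond_means - m, region_means - m, "+") - m)^2)
  ss_total <- sum((data$value - m)^2)
  ss_within_err <- ss_total - ss_between - ss_region - ss_inter
  df_scan_err <- N - a
  df_within_err <- (r - 1) * (N - a)
  list(
    condition = list(ss = ss_cond, F = (ss_cond / (a - 1)) / (ss_scan_err / df_scan_err),
                     df1 = a - 1, df2 = df_scan_err),
    region = list(ss = ss_region, F = (ss_region / (r - 1)) / (ss_within_err / df_within_err),
                  df1 = r - 1, df2 = df_within_err),
    interaction = list(ss = ss_inter,
                       F = (ss_inter / ((a - 1) * (r - 1))) / (ss_within_err / df_within_err),
                       df1 = (a - 1) * (r - 1), df2 = df_within_err),
    ss_total = ss_total,
    parts = c(ss_cond, ss_scan_err, ss_region, ss_inter, ss_within_err)
  )
}

# Short-time Fourier spectrogram oracle for burst localization: returns the
# peak frequency (Hz) and peak time (ms) of a single-channel signal.
oracle_stft_peak <- function(x, fs, t0_ms, win = 128, step = 16) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, win - 1) / (win - 1)))   # Hann
  starts <- seq(1, n - win + 1, by = step)
  freqs <- (0:(win / 2)) * fs / win
  P <- sapply(starts, function(s) {
    X <- stats::fft(x[s:(s + win - 1)] * w)
    Mod(X[seq_along(freqs)])^2
  })
  idx <- arrayInd(which.max(P), dim(P))
  list(freq = freqs[idx[1]],
       time_ms = t0_ms + (starts[idx[2]] - 1 + win / 2) * 1000 / fs)
}
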