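# Induced gamma-band EEG analysis: cue-locked epochs from a cognitive-control
# task are wavelet-transformed (complex Morlet, omega0 = 7, 20 sub-bands
# spanning 14-80 Hz), baseline corrected to the -300..-100 ms pre-cue
# interval, and summarized as delay-period (500-1500 ms) 42 Hz power over two
# frontal electrodes. "Induced" power averages per-trial power, so activity
# need not be phase-locked to the cue.

#' Construct an EEG epoch collection
#'
#' @param data Numeric array trials x channels x samples, in microvolts.
#' @param fs Sampling rate, Hz (study value 250).
#' @param t0_ms Time of the first sample relative to cue onset, ms (study
#'   epochs span -400 to +1900 ms).
#' @param labels Condition label per trial ("low"/"high" cognitive control).
#' @param channels Channel labels.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs = 250, t0_ms = -400, labels, channels = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (length(labels) != dim(data)[1]) stop("one label per trial is required")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channels) != dim(data)[2]) stop("one name per channel is required")
  structure(list(data = data, fs = fs,
                 times_ms = t0_ms + (seq_len(dim(data)[3]) - 1) * 1000 / fs,
                 labels = as.character(labels), channels = channels),
            class = "epoch_set")
}

#' Simulate cued-task EEG epochs with known induced gamma content
#'
#' Each trial is pink (1/f) background noise plus a condition-scaled
#' sinusoidal burst at `gamma_freq` confined to the delay window, with an
#' independent uniform random phase per trial — induced, not evoked,
#' activity. Trials are split 70%/30% into low/high cognitive-control
#' conditions and interleaved in pseudorandom order.
#'
#' @param n_trials Total trial count (split by `prop_low`).
#' @param prop_low Proportion of low-control trials (study task: 0.7).
#' @param gamma_freq Burst frequency, Hz (default 42).
#' @param gamma_amplitude Named vector `c(low=, high=)` of burst amplitudes,
#'   microvolts.
#' @param noise_sd Pink-noise SD, microvolts.
#' @param fs Sampling rate, Hz.
#' @param window_ms Epoch window relative to cue, ms.
#' @param burst_window_ms Delay window carrying the burst, ms.
#' @param channels Channel labels (the burst is common to all channels).
#' @param seed Optional RNG seed.
#' @return An `epoch_set`.
#' @export
simulate_eeg <- function(n_trials = 300, prop_low = 0.7, gamma_freq = 42,
                         gamma_amplitude = c(low = 2, high = 4),
                         noise_sd = 10, fs = 250,
                         window_ms = c(-400, 1900),
                         burst_window_ms = c(500, 1500),
                         channels = c("E23", "E24"), seed = NULL) {
  stopifnot(all(c("low", "high") %in% names(gamma_amplitude)))
  n_samp <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  times <- window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs
  n_ch <- length(channels)
  in_burst <- times >= burst_window_ms[1] & times <= burst_window_ms[2]
  env <- numeric(n_samp)
  # Hann envelope over the delay window: burst power ramps in and out
  env[in_burst] <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = sum(in_burst))))
  .with_seed(seed, {
    n_low <- round(n_trials * prop_low)
    labels <- sample(c(rep("low", n_low), rep("high", n_trials - n_low)))
    dat <- array(0, dim = c(n_trials, n_ch, n_samp))
    freq_hz <- c(0, seq_len(floor(n_samp / 2)),
                 rev(seq_len(ceiling(n_samp / 2) - 1))) * fs / n_samp
    shape <- c(0, 1 / sqrt(freq_hz[-1]))
    for (tr in seq_len(n_trials)) {
      phase <- stats::runif(1, 0, 2 * pi)
      burst <- gamma_amplitude[[labels[tr]]] * env *
        cos(2 * pi * gamma_freq * (times - burst_window_ms[1]) / 1000 + phase)
      for (ch in seq_len(n_ch)) {
        w <- stats::fft(stats::rnorm(n_samp)) * shape
        pink <- Re(stats::fft(w, inverse = TRUE)) / n_samp
        pink <- pink / stats::sd(pink) * noise_sd
        dat[tr, ch, ] <- pink + burst
      }
    }
    epoch_set(dat, fs = fs, t0_ms = window_ms[1], labels = labels,
              channels = channels)
  })
}

#' Reject trials by amplitude range and sample-to-sample gradient
#'
#' A trial is rejected when any channel's within-epoch amplitude range
#' exceeds `range_limit_uv` or any consecutive-sample step exceeds
#' `gradient_limit_uv` (strict inequalities: a 200 uV range or a 60 uV step
#' is still kept).
#'
#' @param epochs An `epoch_set` in calibrated microvolts.
#' @param range_limit_uv Range threshold, default 200.
#' @param gradient_limit_uv Gradient threshold, default 60.
#' @return Logical vector, `TRUE` for kept trials.
#' @export
reject_artifacts <- function(epochs, range_limit_uv = 200, gradient_limit_uv = 60) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1]
  keep <- logical(n_tr)
  for (tr in seq_len(n_tr)) {
    x <- epochs$data[tr, , , drop = FALSE]
    dim(x) <- dim(epochs$data)[2:3]
    rng <- apply(x, 1, function(v) diff(range(v)))
    grd <- apply(x, 1, function(v) if (length(v) > 1) max(abs(diff(v))) else 0)
    keep[tr] <- all(rng <= range_limit_uv) && all(grd <= gradient_limit_uv)
  }
  keep
}

#' Subset an epoch set by a trial mask
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer trial selector.
#' @export
subset_epochs <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep]
  epochs
}

#' Morlet wavelet analysis specification
#'
#' The mother wavelet is mo(x) = exp(-x^2/2) * exp(i*omega0*x) with
#' omega0 = 7; at center frequency f its temporal SD is omega0/(2*pi*f)
#' seconds. Amplitude normalization is chosen so a unit-amplitude sinusoid at
#' a sub-band's center frequency yields unit peak power, independent of
#' frequency. Sub-bands are 20 linearly spaced center frequencies spanning
#' 14-80 Hz.
#'
#' @param omega0 Morlet parameter (cycles-like), default 7.
#' @param freqs Center frequencies, Hz, strictly increasing.
#' @param baseline_ms Pre-cue baseline window for power correction.
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(omega0 = 7, freqs = seq(14, 80, length.out = 20),
                         baseline_ms = c(-300, -100)) {
  if (any(diff(freqs) <= 0)) stop("frequencies must be strictly increasing")
  if (baseline_ms[2] > 0) stop("baseline window must precede the cue")
  structure(list(omega0 = omega0, freqs = freqs, baseline_ms = baseline_ms),
            class = "wavelet_spec")
}

# complex Morlet kernel at center frequency f (time domain, centered)
.morlet_kernel <- function(f, fs, omega0) {
  sigma_t <- omega0 / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  k <- env * exp(1i * 2 * pi * f * tt)
  # unit sinusoid at f -> |W| = 1 (the counter-rotating term is negligible)
  k * 2 / sum(env)
}

# wavelet coefficients for a samples x series matrix at one frequency,
# FFT-based 'same' convolution
.morlet_coef <- function(xmat, f, fs, omega0) {
  k <- .morlet_kernel(f, fs, omega0)
  L <- length(k)
  n <- nrow(xmat)
  if (L > n) stop("epoch shorter than the wavelet support at ", f, " Hz")
  nfft <- 2^ceiling(log2(n + L - 1))
  kf <- stats::fft(c(k, rep(0, nfft - L)))
  xf <- stats::mvfft(rbind(xmat, matrix(0, nfft - n, ncol(xmat))))
  conv <- stats::mvfft(xf * kf, inverse = TRUE) / nfft
  conv[(L - 1) / 2 + seq_len(n), , drop = FALSE]
}

#' Trial-averaged induced time-frequency power
#'
#' Each trial and channel is convolved with the complex Morlet wavelet at
#' every sub-band; induced power at a time-frequency point is the mean over
#' trials of the per-trial squared magnitude (computed per condition).
#' Baseline correction subtracts the mean power over the pre-cue baseline
#' window, per channel and frequency.
#'
#' @param epochs An `epoch_set` (artifact-rejected).
#' @param spec A `wavelet_spec`.
#' @param baseline_correct Subtract pre-cue baseline power (default TRUE).
#' @return Object of class `tf_power`: `power` is a named list (one
#'   channel x frequency x time array per condition), plus `freqs`,
#'   `times_ms`, `channels`, `conditions`, `n_trials`, `baseline_corrected`.
#' @export
morlet_power <- function(epochs, spec = wavelet_spec(), baseline_correct = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "wavelet_spec"))
  .tf_power(epochs, spec, baseline_correct, mode = "induced")
}

.tf_power <- function(epochs, spec, baseline_correct, mode) {
  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_sa <- dim(d)[3]
  conds <- sort(unique(epochs$labels))
  nf <- length(spec$freqs)
  power <- lapply(conds, function(cond) array(0, dim = c(n_ch, nf, n_sa)))
  names(power) <- conds
  n_trials <- stats::setNames(integer(length(conds)), conds)
  for (cond in conds) {
    idx <- which(epochs$labels == cond)
    n_trials[cond] <- length(idx)
    if (mode == "evoked") {
      # power of the trial-averaged signal: only phase-locked activity survives
      avg <- apply(d[idx, , , drop = FALSE], c(2, 3), mean)
      xmat <- t(avg)                                   # samples x channels
      for (fi in seq_len(nf)) {
        w <- .morlet_coef(xmat, spec$freqs[fi], epochs$fs, spec$omega0)
        power[[cond]][, fi, ] <- t(Mod(w)^2)
      }
    } else {
      xmat <- matrix(aperm(d[idx, , , drop = FALSE], c(3, 1, 2)),
                     nrow = n_sa)                      # samples x (trial*channel)
      for (fi in seq_len(nf)) {
        w <- .morlet_coef(xmat, spec$freqs[fi], epochs$fs, spec$omega0)
        p <- Mod(w)^2
        dim(p) <- c(n_sa, length(idx), n_ch)
        power[[cond]][, fi, ] <- t(apply(p, c(1, 3), mean))
      }
    }
  }
  out <- list(power = power, freqs = spec$freqs, times_ms = epochs$times_ms,
              channels = epochs$channels, conditions = conds,
              n_trials = n_trials, baseline_corrected = FALSE)
  class(out) <- "tf_power"
  if (baseline_correct) out <- baseline_correct_tf(out, spec$baseline_ms)
  out
}

#' Baseline-correct a time-frequency power object
#'
#' Subtracts, per condition, channel and frequency, the mean power over the
#' pre-cue baseline window.
#'
#' @param tf A `tf_power`.
#' @param baseline_ms Window, ms relative to cue.
#' @export
baseline_correct_tf <- function(tf, baseline_ms = c(-300, -100)) {
  stopifnot(inherits(tf, "tf_power"))
  if (tf$baseline_corrected) stop("power is already baseline-corrected")
  sel <- tf$times_ms >= baseline_ms[1] & tf$times_ms <= baseline_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  for (cond in names(tf$power)) {
    base <- apply(tf$power[[cond]][, , sel, drop = FALSE], c(1, 2), mean)
    tf$power[[cond]] <- tf$power[[cond]] - as.vector(base)  # recycles over time
  }
  tf$baseline_corrected <- TRUE
  tf
}

#' Induced and evoked power variants
#'
#' Induced power averages per-trial power (phase-random activity survives);
#' evoked power is the power of the trial-averaged signal (only phase-locked
#' activity survives). Both are baseline corrected.
#'
#' @param epochs An `epoch_set` with >= 2 trials.
#' @param spec A `wavelet_spec`.
#' @return List with `induced` and `evoked` `tf_power` objects.
#' @export
induced_vs_evoked <- function(epochs, spec = wavelet_spec()) {
  if (dim(epochs$data)[1] < 2) stop("need at least 2 trials")
  list(induced = .tf_power(epochs, spec, TRUE, mode = "induced"),
       evoked = .tf_power(epochs, spec, TRUE, mode = "evoked"))
}

#' Frontal delay-period gamma summary
#'
#' Mean baseline-corrected power over two frontal electrodes, the sub-band
#' nearest `band_center`, and the delay window — one scalar per condition,
#' plus the high-minus-low contrast used as the per-subject frontal gamma
#' measure for comparison with PET outcomes.
#'
#' @param tf A baseline-corrected `tf_power`.
#' @param electrodes Two channel labels to average (must exist in `tf`).
#' @param band_center Sub-band center frequency, Hz; the nearest available
#'   sub-band is used (with a warning when not an exact match).
#' @param window_ms Delay window, ms relative to cue.
#' @return List with `per_condition` (named vector), `contrast`
#'   (high - low), `band_freq`, `electrodes`.
#' @export
frontal_gamma_summary <- function(tf, electrodes = c("E23", "E24"),
                                  band_center = 42, window_ms = c(500, 1500)) {
  stopifnot(inherits(tf, "tf_power"))
  chi <- match(electrodes, tf$channels)
  if (anyNA(chi)) {
    stop("electrodes not present: ",
         paste(electrodes[is.na(chi)], collapse = ", "))
  }
  fi <- which.min(abs(tf$freqs - band_center))
  if (abs(tf$freqs[fi] - band_center) > 1e-9) {
    warning(sprintf("band center %g Hz not in spec; using nearest sub-band %.2f Hz",
                    band_center, tf$freqs[fi]))
  }
  sel <- tf$times_ms >= window_ms[1] & tf$times_ms <= window_ms[2]
  vals <- vapply(tf$conditions, function(cond) {
    mean(tf$power[[cond]][chi, fi, sel])
  }, numeric(1))
  contrast <- if (all(c("high", "low") %in% names(vals))) {
    unname(vals["high"] - vals["low"])
  } else NA_real_
  list(per_condition = vals, contrast = contrast,
       band_freq = tf$freqs[fi], electrodes = electrodes)
}
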