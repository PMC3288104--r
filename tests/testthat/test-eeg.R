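make_epochs <- function(mat_list, channels = "E23", fs = 250, t0 = -400,
                        labels = NULL) {
  n <- length(mat_list)
  arr <- array(0, dim = c(n, length(channels), length(mat_list[[1]])))
  for (i in seq_len(n)) arr[i, 1, ] <- mat_list[[i]]
  epoch_set(arr, fs = fs, t0_ms = t0,
            labels = if (is.null(labels)) rep("low", n) else labels,
            channels = channels)
}

test_that("artifact rejection fires strictly above the range/gradient limits", {
  n <- 575
  flat <- rep(0, n)
  ramp <- function(total) seq(0, total, length.out = n)    # tiny per-sample steps
  step <- function(size) c(rep(0, 300), rep(size, n - 300))
  ep <- make_epochs(list(flat,
                         ramp(201), ramp(199),
                         step(61), step(59),
                         c(rep(0, 100), 250, rep(0, n - 101))))
  keep <- reject_artifacts(ep)
  expect_equal(keep, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # monotonicity: tightening either threshold never keeps more trials
  for (rl in c(150, 200, 250)) {
    for (gl in c(40, 60, 80)) {
      expect_lte(sum(reject_artifacts(ep, rl, gl)),
                 sum(reject_artifacts(ep, rl + 50, gl)))
      expect_lte(sum(reject_artifacts(ep, rl, gl)),
                 sum(reject_artifacts(ep, rl, gl + 20)))
    }
  }
})

test_that("Morlet power is zero for zero signal and peaks at the burst band", {
  n <- 575
  times <- -400 + (0:(n - 1)) * 4
  ep0 <- make_epochs(list(rep(0, n), rep(0, n)))
  tf0 <- morlet_power(ep0, baseline_correct = FALSE)
  expect_equal(max(abs(tf0$power[["low"]])), 0)
  # pure 42 Hz sinusoid: maximal power in the sub-band nearest 42 Hz,
  # and near-unit power under the amplitude normalization
  s42 <- sin(2 * pi * 42 * times / 1000)
  tf <- morlet_power(make_epochs(list(s42)), baseline_correct = FALSE)
  mid <- times > 200 & times < 1200            # away from epoch edges
  prof <- sapply(seq_along(tf$freqs), function(fi) mean(tf$power[["low"]][1, fi, mid]))
  expect_equal(tf$freqs[which.max(prof)], tf$freqs[which.min(abs(tf$freqs - 42))])
  expect_equal(max(prof), 1, tolerance = 0.1)
  # epochs shorter than the wavelet support at 14 Hz are refused
  ep_short <- make_epochs(list(rep(0, 100)))
  expect_error(morlet_power(ep_short), "wavelet support")
})

test_that("wavelet and spectrogram oracles agree on burst localization", {
  ep <- simulate_eeg(n_trials = 40, gamma_amplitude = c(low = 8, high = 8),
                     noise_sd = 1, seed = 31)
  tf <- morlet_power(ep, baseline_correct = FALSE)
  # morlet peak (trial-averaged induced power, channel 1)
  P <- tf$power[["low"]][1, , ]
  idx <- arrayInd(which.max(P), dim(P))
  f_morlet <- tf$freqs[idx[1]]
  t_morlet <- tf$times_ms[idx[2]]
  # induced bursts cancel in the trial average, so run the spectrogram
  # oracle on one representative high-SNR trial
  orac <- oracle_stft_peak(ep$data[1, 1, ], fs = ep$fs, t0_ms = -400)
  step_hz <- diff(tf$freqs)[1]
  expect_lt(abs(f_morlet - 42), step_hz)
  expect_lt(abs(orac$freq - 42), 2 * 250 / 128)      # two STFT bins
  expect_lt(abs(t_morlet - 1000), 300)               # burst envelope peaks mid-delay
  expect_lt(abs(orac$time_ms - 1000), 400)
})

test_that("induced power survives phase randomization; evoked power does not", {
  n <- 575
  times <- -400 + (0:(n - 1)) * 4
  env <- as.numeric(times >= 500 & times <= 1500)
  locked <- lapply(1:30, function(i) env * cos(2 * pi * 42 * times / 1000))
  iv_locked <- induced_vs_evoked(make_epochs(locked))
  expect_equal(iv_locked$induced$power[["low"]], iv_locked$evoked$power[["low"]],
               tolerance = 1e-10)
  set.seed(32)
  rand <- lapply(1:100, function(i) {
    env * cos(2 * pi * 42 * times / 1000 + runif(1, 0, 2 * pi))
  })
  iv <- induced_vs_evoked(make_epochs(rand))
  f42 <- which.min(abs(iv$induced$freqs - 42))
  sel <- iv$induced$times_ms >= 500 & iv$induced$times_ms <= 1500
  ind <- mean(iv$induced$power[["low"]][1, f42, sel])
  evo <- mean(iv$evoked$power[["low"]][1, f42, sel])
  expect_lt(evo / ind, 0.1)
  # per-trial phase randomization leaves induced power essentially unchanged
  iv2 <- induced_vs_evoked(make_epochs(locked[1:30]))
  ind_locked <- mean(iv2$induced$power[["low"]][1, f42, sel])
  expect_equal(ind, ind_locked, tolerance = 0.05)
})

test_that("total wavelet power of white noise scales with its variance", {
  set.seed(33)
  n <- 575
  pw <- sapply(c(1, 2, 3), function(s) {
    ep <- make_epochs(lapply(1:20, function(i) rnorm(n, 0, s)))
    tf <- morlet_power(ep, baseline_correct = FALSE)
    mean(tf$power[["low"]])
  })
  expect_equal(pw[2] / pw[1], 4, tolerance = 0.6)
  expect_equal(pw[3] / pw[1], 9, tolerance = 1.3)
})

test_that("the frontal gamma summary contrasts high vs low control", {
  # condition-equal amplitudes: contrast near zero relative to signal power
  ep0 <- simulate_eeg(n_trials = 120, gamma_amplitude = c(low = 3, high = 3),
                      noise_sd = 5, seed = 34)
  tf0 <- morlet_power(ep0)
  fg0 <- suppressWarnings(frontal_gamma_summary(tf0))
  expect_lt(abs(fg0$contrast), 0.5 * mean(abs(fg0$per_condition)))
  # doubled high-control amplitude: positive contrast across seeded runs
  hits <- sapply(1:10, function(s) {
    ep <- simulate_eeg(n_trials = 120, gamma_amplitude = c(low = 2, high = 4),
                       noise_sd = 5, seed = 100 + s)
    fg <- suppressWarnings(frontal_gamma_summary(morlet_power(ep)))
    fg$contrast > 0
  })
  expect_gte(sum(hits), 9)
  # unknown electrodes are an error; off-grid band centers warn
  expect_warning(frontal_gamma_summary(tf0), "nearest sub-band")
  expect_error(suppressWarnings(frontal_gamma_summary(tf0, electrodes = c("E1", "E2"))),
               "not present")
})

test_that("simulated epochs honor the 70/30 split and seeded determinism", {
  ep <- simulate_eeg(n_trials = 200, seed = 35)
  expect_equal(sum(ep$labels == "low"), 140)
  expect_equal(sum(ep$labels == "high"), 60)
  expect_equal(dim(ep$data), c(200, 2, 575))
  expect_equal(range(ep$times_ms), c(-400, 1896))
  ep2 <- simulate_eeg(n_trials = 200, seed = 35)
  expect_identical(ep$data, ep2$data)
  expect_identical(ep$labels, ep2$labels)
  # zero-amplitude bursts: delay-window power matches baseline-window power
  # in expectation (no induced signal)
  ep0 <- simulate_eeg(n_trials = 150, gamma_amplitude = c(low = 0, high = 0),
                      noise_sd = 5, seed = 36)
  tf <- morlet_power(ep0)     # baseline corrected
  f42 <- which.min(abs(tf$freqs - 42))
  sel <- tf$times_ms >= 500 & tf$times_ms <= 1500
  base_sel <- tf$times_ms >= -300 & tf$times_ms <= -100
  raw <- morlet_power(ep0, baseline_correct = FALSE)
  delay_p <- mean(raw$power[["low"]][, f42, sel])
  base_p <- mean(raw$power[["low"]][, f42, base_sel])
  expect_equal(delay_p / base_p, 1, tolerance = 0.35)
})
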