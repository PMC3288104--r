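test_that("VT follows K1/k2*(1 + k3/k4) with its degenerate cases", {
  expect_equal(vt(kinetic_params(0.4, 0.1, 0.15, 0.1)), 10)
  expect_equal(vt(kinetic_params(0.3, 0.06)), 5)              # one-tissue limit
  expect_equal(vt(kinetic_params(0.441, 0.066, 0, 0)), 6.68, tolerance = 1e-3)
  p <- c(K1 = 0.4, k2 = 0.1, k3 = 0.1, k4 = 0)
  expect_error(vt(p), "undefined")
})

test_that("binding-potential outcomes derive from VT and pons VND", {
  o <- outcomes(6.8, 0.9)
  expect_equal(o$bp_p, 5.9)
  expect_equal(o$bp_nd, 6.8 / 0.9 - 1)
  expect_equal(outcomes(5.2, 0.9)$bp_p, 4.3)
  o0 <- outcomes(0.9, 0.9)
  expect_equal(c(o0$bp_p, o0$bp_nd), c(0, 0))                 # pure nonspecific
  expect_error(outcomes(5, 0), "positive")
})

test_that("blood correction subtracts the plasma contribution once", {
  sched <- make_frame_schedule()
  t1 <- tac(rep(10, 19), sched)
  bc <- blood_correct(t1, rep(20, 19), 0.05)
  expect_equal(bc$activity, rep(9, 19))
  expect_true(bc$blood_corrected)
  expect_error(blood_correct(bc, rep(20, 19)), "already")
  # zero plasma leaves the TAC unchanged
  expect_equal(blood_correct(t1, rep(0, 19))$activity, t1$activity)
  # round trip: correcting a simulated TAC with the matching fraction
  # recovers the pure-tissue curve exactly (noiseless)
  fits <- fixture_plasma_fits()
  p <- kinetic_params(0.4, 0.4, 0.3, 0.1)
  sim <- simulate_tac(p, fits$input, sched, blood_volume_fraction = 0.05,
                      total_input = fits$total_input)
  rec <- blood_correct(sim, input_frame_values(fits$total_input, sched), 0.05)
  expect_equal(rec$activity, model_tac(p, fits$input, sched), tolerance = 1e-12)
})

test_that("the closed-form 2TC prediction matches brute-force convolution", {
  fits <- fixture_plasma_fits()
  sched <- make_frame_schedule()
  set.seed(42)
  for (i in 1:10) {
    p <- kinetic_params(runif(1, 0.2, 0.5), runif(1, 0.05, 0.5),
                        runif(1, 0.02, 0.6), runif(1, 0.05, 0.2))
    pred <- model_tac(p, fits$input, sched)
    orac <- oracle_model_tac(p, fits$input, sched)
    expect_lt(max(abs(pred - orac)) / max(orac), 1e-4)
  }
})

test_that("nested and degenerate parameter regimes are handled analytically", {
  fits <- fixture_plasma_fits()
  sched <- make_frame_schedule()
  # k3 = k4 = 0 reduces to the one-tissue model
  p1 <- kinetic_params(0.4, 0.2)
  expect_lt(max(abs(model_tac(p1, fits$input, sched) -
                      oracle_model_tac(p1, fits$input, sched))) /
              max(oracle_model_tac(p1, fits$input, sched)), 1e-4)
  # repeated eigenvalues (k3 = 0, k2 = k4): t*exp(-at) limit, not an error
  p2 <- c(K1 = 0.4, k2 = 0.2, k3 = 0, k4 = 0.2)
  class(p2) <- "kinetic_params"
  expect_lt(max(abs(model_tac(p2, fits$input, sched) -
                      oracle_model_tac(p2, fits$input, sched))) /
              max(oracle_model_tac(p2, fits$input, sched)), 1e-4)
  # zero input gives zero prediction
  null_input <- fits$input
  null_input$pre$value <- 0 * null_input$pre$value
  null_input$tail$A <- 0 * null_input$tail$A
  expect_equal(model_tac(p1, null_input, sched), rep(0, 19))
})

test_that("frame-weighted fitting recovers noiseless parameters and VT", {
  fits <- fixture_plasma_fits()
  sched <- make_frame_schedule()
  p <- kinetic_params(0.40, 0.10, 0.15, 0.10)     # VT = 10
  sim <- simulate_tac(p, fits$input, sched, total_input = fits$total_input)
  bc <- blood_correct(sim, input_frame_values(fits$total_input, sched))
  fit <- fit_2tc(bc, fits$input)
  expect_true(fit$converged)
  expect_equal(fit$vt, 10, tolerance = 1e-3)
  expect_equal(as.numeric(fit$params), as.numeric(p), tolerance = 1e-3)
  # FitResult identity: reported VT always equals vt(params)
  expect_equal(fit$vt, vt(fit$params), tolerance = 1e-12)
  expect_error(fit_2tc(sim, fits$input), "blood-corrected")
})

test_that("early 15-s frames barely move the noiseless VT estimate", {
  fits <- fixture_plasma_fits()
  sched <- make_frame_schedule()
  p <- kinetic_params(0.41, 0.41, 0.58, 0.10)
  sim <- simulate_tac(p, fits$input, sched, total_input = fits$total_input)
  bc <- blood_correct(sim, input_frame_values(fits$total_input, sched))
  vt_full <- fit_2tc(bc, fits$input)$vt
  late <- sched[5:19, ]
  class(late) <- class(sched)
  bc_late <- bc
  bc_late$schedule <- late
  bc_late$activity <- bc$activity[5:19]
  vt_late <- fit_2tc(bc_late, fits$input)$vt
  expect_lt(abs(vt_late - vt_full) / vt_full, 0.005)
})
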