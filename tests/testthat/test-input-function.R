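metab_times <- c(2, 5, 15, 30, 45, 75, 90)

test_that("parent-fraction fit recovers its generating curve", {
  # plateau-only data: amplitude ~ 0, constant carries the level
  pf0 <- fit_parent_fraction(metab_times, rep(0.8, 7))
  expect_lt(abs(pf0$a), 1e-6)
  expect_equal(pf0$c, 0.8, tolerance = 1e-6)
  expect_equal(predict(pf0, c(0, 45, 90)), rep(0.8, 3), tolerance = 1e-6)

  # noiseless exp + constant: parameters recovered essentially exactly;
  # a coarse grid search confirms the optimum is global
  truth <- c(a = 0.55, b = 0.15, c = 0.40)
  y <- truth["a"] * exp(-truth["b"] * metab_times) + truth["c"]
  pf <- fit_parent_fraction(metab_times, y)
  expect_equal(c(pf$a, pf$b, pf$c), unname(truth), tolerance = 1e-6)
  expect_lt(pf$residual_norm, 1e-8)
  grid_rss <- sapply(seq(0.01, 1, by = 0.01), function(b) {
    z <- exp(-b * metab_times)
    min(sum(stats::lm(y ~ z)$residuals^2))
  })
  expect_lt(pf$residual_norm^2, min(grid_rss) + 1e-12)
})

test_that("parent-fraction predictions decrease monotonically to the plateau", {
  y <- 0.5 * exp(-0.2 * metab_times) + 0.3
  pf <- fit_parent_fraction(metab_times, y)
  tt <- seq(0, 90, by = 1)
  expect_true(all(diff(predict(pf, tt)) < 0))
  expect_gt(min(predict(pf, tt)), pf$c - 1e-9)
})

test_that("metabolite correction multiplies totals by the interpolated fraction", {
  pf1 <- fit_parent_fraction(metab_times, rep(1, 7))
  out <- compute_input(c(1, 10, 50), c(100, 80, 20), pf1)
  expect_equal(out$parent, c(100, 80, 20))   # fraction = 1 is the identity

  pf_half <- fit_parent_fraction(metab_times, rep(0.5, 7))
  expect_equal(compute_input(5, 100, pf_half)$parent, 50)

  # round trip against the generator's parent curve
  pl <- simulate_plasma()
  pf <- fit_parent_fraction(pl$metabolites$time, pl$metabolites$fraction)
  parent <- compute_input(pl$plasma$time, pl$plasma$total, pf)
  expect_equal(parent$parent, pl$model$parent_curve(pl$plasma$time),
               tolerance = 1e-8)
})

test_that("tri-exponential tail fit recovers noiseless parameters and AUC", {
  A <- c(8, 3, 1); lam <- c(2, 0.3, 0.03)
  tt <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 7.5, 10, 15, 20, 30, 45,
          60, 75, 90)
  y <- as.vector(exp(outer(tt, lam, function(t, l) -l * t)) %*% A)
  fit <- fit_input_function(tt, y)
  expect_equal(fit$tail$A, A, tolerance = 1e-4)
  expect_equal(fit$tail$lambda, lam, tolerance = 1e-4)
  expect_equal(fit$auc_tail, sum(A / lam), tolerance = 1e-6)
  expect_equal(fit$auc, sum(A / lam), tolerance = 1e-6)  # no pre-peak mass
  expect_lt(fit$residual_norm / max(y), 1e-6)
})

test_that("mono-exponential data collapse the nested tri-exponential model", {
  tt <- seq(0, 90, by = 2)
  y <- 10 * exp(-0.1 * tt)
  fit <- fit_input_function(tt, y)
  expect_equal(fit$auc_tail, 100, tolerance = 1e-4)    # A / lambda
  expect_equal(predict(fit, c(0, 5, 30, 60)), 10 * exp(-0.1 * c(0, 5, 30, 60)),
               tolerance = 1e-5)
})

test_that("the peak is the earliest maximal sample and the AUC is additive", {
  tt <- c(0.5, 1, 1.5, 2, 3, 5, 10, 20, 40, 60, 90)
  y <- c(5, 9, 9, 8, 6.5, 5, 3.5, 2, 1, 0.6, 0.3)   # tie at t = 1 and 1.5
  fit <- fit_input_function(tt, y, n_exp = 2)
  expect_equal(fit$peak_time, 1)                      # earliest tie wins
  expect_equal(fit$auc, fit$auc_pre + fit$auc_tail)
  # doubling all activities doubles the AUC (scale equivariance)
  fit2 <- fit_input_function(tt, 2 * y, n_exp = 2)
  expect_equal(fit2$auc, 2 * fit$auc, tolerance = 1e-6)
})

test_that("clearance follows dose/AUC with the closed mono-exponential form", {
  tt <- seq(0, 90, by = 2)
  fit <- fit_input_function(tt, 10 * exp(-0.1 * tt), n_exp = 1)
  cl <- clearance(740000, fit)
  expect_equal(cl, 740000 * 0.1 / 10, tolerance = 1e-6)   # D * lambda / A
  expect_equal(ml_min_to_l_h(cl), 444, tolerance = 1e-4)
  # scale invariance: scaling dose and plasma together leaves CL unchanged
  fit3 <- fit_input_function(tt, 3 * 10 * exp(-0.1 * tt), n_exp = 1)
  expect_equal(clearance(3 * 740000, fit3), cl, tolerance = 1e-6)
})

test_that("free fraction averages triplicate ratios and corrects for retention", {
  # free tracer passes the filter completely
  expect_equal(free_fraction(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))$fp, 1)
  # plain triplicate mean at unit saline ratio (study magnitude ~58%)
  fa <- free_fraction(rep(100, 3), c(58, 60, 56), rep(100, 3), rep(100, 3))
  expect_equal(fa$fp, 0.58)
  expect_equal(fa$fp_raw, 0.58)
  # retention correction divides by the saline ratio
  fb <- free_fraction(rep(10, 3), rep(3, 3), rep(10, 3), rep(6, 3))
  expect_equal(fb$fp, 0.5)
  expect_error(free_fraction(rep(1, 3), rep(2, 3), rep(1, 3), rep(1, 3)),
               "exceed")
})
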