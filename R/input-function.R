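#' Fit the plasma parent fraction as one exponential plus a constant
#'
#' The fraction of plasma activity representing unmetabolized parent tracer is
#' measured at a handful of times (the study schedule is 2, 5, 15, 30, 45, 75
#' and 90 min) and modeled as f(t) = a*exp(-b*t) + c, the standard
#' interpolant for a tracer whose metabolite fraction plateaus.
#'
#' Fitting is unweighted least squares via Levenberg-Marquardt with
#' multi-start over log-spaced rate seeds; the best residual wins, ties broken
#' by the smaller rate.
#'
#' @param times Sample times, minutes.
#' @param fractions Measured parent fractions in `[0, 1]`.
#' @return An object of class `parent_fraction_fit`: list with elements `a`,
#'   `b`, `c`, `residual_norm`, `n`.
#' @seealso [predict.parent_fraction_fit()], [compute_input()]
#' @export
fit_parent_fraction <- function(times, fractions) {
  stopifnot(length(times) == length(fractions))
  if (length(times) < 4) stop("need at least 4 parent-fraction measurements")
  if (any(fractions < 0 | fractions > 1)) {
    stop("parent fractions must lie in [0, 1]")
  }
  resid_fn <- function(p) fractions - (p[1] * exp(-p[2] * times) + p[3])
  best <- NULL
  for (b0 in c(0.01, 0.1, 1)) {
    st <- c(a = max(fractions) - min(fractions), b = b0, c = min(fractions))
    fit <- try(minpack.lm::nls.lm(par = st, fn = resid_fn,
                                  lower = c(-2, 0, -1), upper = c(2, 10, 2),
                                  control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn - 1e-12 ||
        (abs(rn - best$rn) <= 1e-12 && fit$par[2] < best$par[2])) {
      best <- list(par = fit$par, rn = rn)
    }
  }
  if (is.null(best)) stop("parent-fraction fit failed to converge from all starts")
  out <- list(a = unname(best$par[1]), b = unname(best$par[2]),
              c = unname(best$par[3]), residual_norm = best$rn,
              n = length(times))
  class(out) <- "parent_fraction_fit"
  # invariant: prediction stays a fraction over the scan
  tt <- seq(0, 90, by = 0.5)
  raw <- out$a * exp(-out$b * tt) + out$c
  if (any(raw < -0.05 | raw > 1.05)) {
    warning("fitted parent fraction strays outside [0, 1]; predictions are clamped")
  }
  out
}

#' Predict parent fraction at arbitrary times
#'
#' @param object A `parent_fraction_fit`.
#' @param times Times in minutes.
#' @param ... Unused.
#' @return Predicted fractions, clamped to `[0, 1]`.
#' @export
predict.parent_fraction_fit <- function(object, times, ...) {
  pmin(1, pmax(0, object$a * exp(-object$b * times) + object$c))
}

#' @export
print.parent_fraction_fit <- function(x, ...) {
  cat(sprintf("Parent fraction fit: %.4f * exp(-%.4f t) + %.4f  (n = %d, ||r|| = %.3g)\n",
              x$a, x$b, x$c, x$n, x$residual_norm))
  invisible(x)
}

#' Metabolite-correct total plasma activity
#'
#' The input function is the product of total plasma activity and the
#' interpolated unmetabolized fraction at each sample time.
#'
#' @param times Sample times, minutes.
#' @param totals Total plasma activity concentrations.
#' @param pf A `parent_fraction_fit`.
#' @return data.frame with columns `time` and `parent`.
#' @export
compute_input <- function(times, totals, pf) {
  stopifnot(length(times) == length(totals), inherits(pf, "parent_fraction_fit"))
  if (any(times < 0 | times > 90 + 1e-9)) stop("sample times must lie within [0, 90] min")
  data.frame(time = times, parent = totals * predict(pf, times))
}

#' Fit the metabolite-corrected input function
#'
#' The peak is located as the sample-time maximum (earliest time on ties).
#' Values before the peak are kept as measured and evaluated by linear
#' interpolation (anchored at zero activity at injection); values from the
#' peak onward are fitted to a sum of three exponentials
#' sum_i A_i * exp(-lambda_i * (t - t_peak)) by multi-start
#' Levenberg-Marquardt with rates bounded positive. The area under the curve
#' is the pre-peak trapezoid plus the closed-form tail integral
#' sum_i A_i / lambda_i.
#'
#' @param times Sample times, minutes.
#' @param values Metabolite-corrected plasma activities.
#' @param n_exp Number of tail exponentials (3 for the study model; 1 or 2
#'   accepted for reduced data).
#' @return Object of class `input_fn`: `peak_time`, `pre` (data.frame of
#'   knots time/value including the origin and the measured peak), `tail`
#'   (data.frame A, lambda, sorted by decreasing rate), `auc`, `auc_pre`,
#'   `auc_tail`, `residual_norm`.
#' @export
fit_input_function <- function(times, values, n_exp = 3) {
  stopifnot(length(times) == length(values), n_exp %in% 1:3)
  o <- order(times)
  times <- times[o]; values <- values[o]
  ipk <- which.max(values)          # which.max returns the earliest tie
  tp <- times[ipk]
  post_t <- times[times >= tp] - tp
  post_y <- values[times >= tp]
  if (length(post_t) < 2 * n_exp) {
    stop("fewer post-peak samples than tail parameters")
  }
  resid_fn <- function(p) {
    A <- p[seq_len(n_exp)]; lam <- p[n_exp + seq_len(n_exp)]
    pred <- rowSums(exp(outer(post_t, lam, function(t, l) -l * t)) *
                      rep(A, each = length(post_t)))
    post_y - pred
  }
  lam0 <- c(2, 0.3, 0.03)[seq_len(n_exp)]
  best <- NULL
  for (scale in c(0.3, 1, 3)) {
    st <- c(rep(max(post_y) / n_exp, n_exp), lam0 * scale)
    fit <- try(minpack.lm::nls.lm(par = st, fn = resid_fn,
                                  lower = c(rep(-Inf, n_exp), rep(1e-6, n_exp)),
                                  control = minpack.lm::nls.lm.control(maxiter = 400)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn - 1e-12 ||
        (abs(rn - best$rn) <= 1e-12 &&
         sum(fit$par[n_exp + seq_len(n_exp)]^2) < sum(best$par[n_exp + seq_len(n_exp)]^2))) {
      best <- list(par = fit$par, rn = rn)
    }
  }
  if (is.null(best)) stop("input-function tail fit failed from all starts")
  A <- best$par[seq_len(n_exp)]
  lam <- best$par[n_exp + seq_len(n_exp)]
  if (any(lam <= 0)) stop("fitted tail rate is non-positive")
  ord <- order(lam, decreasing = TRUE)
  A <- unname(A[ord]); lam <- unname(lam[ord])
  # pre-peak knots: zero at injection, measured samples strictly before the
  # peak, and the measured peak value itself
  pre_idx <- which(times < tp)
  pre <- data.frame(time = c(0, times[pre_idx], tp),
                    value = c(0, values[pre_idx], values[ipk]))
  pre <- pre[!duplicated(pre$time), ]
  auc_pre <- if (nrow(pre) > 1) {
    sum(diff(pre$time) * (head(pre$value, -1) + pre$value[-1]) / 2)
  } else 0
  auc_tail <- sum(A / lam)
  out <- list(peak_time = tp, pre = pre,
              tail = data.frame(A = A, lambda = lam),
              auc = auc_pre + auc_tail, auc_pre = auc_pre, auc_tail = auc_tail,
              residual_norm = best$rn)
  class(out) <- "input_fn"
  out
}

#' Evaluate a fitted input function
#'
#' Linear interpolation of the measured values before the peak, fitted
#' tri-exponential at and after the peak.
#'
#' @param object An `input_fn`.
#' @param times Times in minutes (may extend past the last sample).
#' @param ... Unused.
#' @export
predict.input_fn <- function(object, times, ...) {
  out <- numeric(length(times))
  pre <- times < object$peak_time
  if (any(pre)) {
    out[pre] <- stats::approx(object$pre$time, object$pre$value,
                              xout = times[pre], rule = 2)$y
  }
  if (any(!pre)) {
    dt <- times[!pre] - object$peak_time
    out[!pre] <- as.vector(exp(outer(dt, object$tail$lambda, function(t, l) -l * t)) %*%
                             object$tail$A)
  }
  out
}

#' @export
print.input_fn <- function(x, ...) {
  cat(sprintf("Input function: peak at %.3g min, %d pre-peak knots\n",
              x$peak_time, nrow(x$pre)))
  cat("  tail: ", paste(sprintf("%.4g*exp(-%.4g (t-tp))", x$tail$A, x$tail$lambda),
                        collapse = " + "), "\n")
  cat(sprintf("  AUC = %.5g (pre %.4g + tail %.4g)\n", x$auc, x$auc_pre, x$auc_tail))
  invisible(x)
}

#' Plasma clearance of the parent compound
#'
#' Clearance is the injected dose divided by the area under the
#' metabolite-corrected input function. Units follow the inputs (dose in kBq
#' and plasma in kBq/mL/min gives mL/min); [ml_min_to_l_h()] converts to the
#' conventional L/h reporting unit.
#'
#' @param dose Injected dose (activity units matching the plasma data).
#' @param input An `input_fn`.
#' @return Clearance in volume per minute.
#' @export
clearance <- function(dose, input) {
  stopifnot(inherits(input, "input_fn"))
  if (!is.finite(input$auc) || input$auc <= 0) stop("input AUC must be positive")
  dose / input$auc
}

#' @rdname clearance
#' @param x Clearance in mL/min.
#' @export
ml_min_to_l_h <- function(x) x * 60 / 1000

#' Plasma free fraction by ultrafiltration
#'
#' fP is the ratio of ultrafiltrate to total activity, averaged over plasma
#' triplicates. Saline triplicates processed identically measure filter
#' retention of free tracer; the corrected fP divides the plasma ratio by the
#' mean saline ratio. Both corrected and raw values are returned because the
#' reported convention in the field varies.
#'
#' @param plasma_total,plasma_ultra Triplicate total and ultrafiltrate counts
#'   for plasma aliquots.
#' @param saline_total,saline_ultra Triplicate counts for saline aliquots.
#' @return List with `fp` (retention-corrected, clamped to `[0, 1]`),
#'   `fp_raw`, `saline_ratio`.
#' @export
free_fraction <- function(plasma_total, plasma_ultra, saline_total, saline_ultra) {
  stopifnot(length(plasma_total) == length(plasma_ultra),
            length(saline_total) == length(saline_ultra))
  if (any(c(plasma_total, plasma_ultra, saline_total, saline_ultra) <= 0)) {
    stop("all counts must be positive")
  }
  if (any(plasma_ultra > plasma_total) || any(saline_ultra > saline_total)) {
    stop("ultrafiltrate counts cannot exceed totals")
  }
  fp_raw <- mean(plasma_ultra / plasma_total)
  saline_ratio <- mean(saline_ultra / saline_total)
  if (saline_ratio == 0) stop("saline ultrafiltrate ratio is zero")
  list(fp = min(1, max(0, fp_raw / saline_ratio)),
       fp_raw = fp_raw,
       saline_ratio = saline_ratio)
}
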