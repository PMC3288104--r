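#' Kinetic rate-constant set for the two-tissue-compartment model
#'
#' K1 (mL g^-1 min^-1) and k2 (min^-1) govern delivery into and efflux out of
#' the free compartment; k3 and k4 (min^-1) govern association to and
#' dissociation from the benzodiazepine site.
#'
#' @param K1,k2,k3,k4 Rate constants; K1, k2 > 0, k3, k4 >= 0, and k4 > 0
#'   whenever k3 > 0.
#' @return Named numeric vector of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0) {
  if (K1 <= 0 || k2 <= 0) stop("K1 and k2 must be positive")
  if (k3 < 0 || k4 < 0) stop("k3 and k4 must be non-negative")
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  class(p) <- "kinetic_params"
  p
}

#' Total distribution volume from 2TC rate constants
#'
#' VT = K1/k2 * (1 + k3/k4), the equilibrium tissue-to-plasma ratio of parent
#' tracer; reduces to K1/k2 in the one-tissue limit k3 = 0.
#'
#' @param params A `kinetic_params` or named vector with K1, k2, k3, k4.
#' @return VT in mL g^-1.
#' @export
vt <- function(params) {
  p <- as.numeric(params[c("K1", "k2", "k3", "k4")])
  if (p[3] == 0) return(p[1] / p[2])
  if (p[4] <= 0) stop("VT undefined: k3 > 0 with k4 = 0 (irreversible binding)")
  p[1] / p[2] * (1 + p[3] / p[4])
}

#' Binding-potential outcome measures
#'
#' Given a region's VT and the nondisplaceable distribution volume VND
#' (operationally, pons VT), returns BP_P = VT - VND (mL g^-1, proportional to
#' fP*Bmax/KD) and BP_ND = VT/VND - 1.
#'
#' @param vt_roi Region VT, mL g^-1.
#' @param vt_pons Pons VT used as VND; must be positive.
#' @param fp Optional plasma free fraction, carried through for reporting.
#' @return List with `vt`, `vnd`, `bp_p`, `bp_nd`, `fp`.
#' @export
outcomes <- function(vt_roi, vt_pons, fp = NA_real_) {
  if (vt_pons <= 0) stop("VND (pons VT) must be positive")
  list(vt = vt_roi, vnd = vt_pons,
       bp_p = vt_roi - vt_pons,
       bp_nd = vt_roi / vt_pons - 1,
       fp = fp)
}

#' Regional time-activity curve
#'
#' @param activity Frame activity concentrations (one per frame).
#' @param schedule A `frame_schedule`.
#' @param region Region label.
#' @param blood_corrected Has the intravascular contribution been removed?
#' @return Object of class `tac`.
#' @export
tac <- function(activity, schedule, region = "region", blood_corrected = FALSE) {
  assert_schedule(schedule)
  if (length(activity) != nrow(schedule)) {
    stop("one activity value per frame is required")
  }
  structure(list(region = region, schedule = schedule,
                 activity = as.numeric(activity),
                 blood_corrected = isTRUE(blood_corrected)),
            class = "tac")
}

#' Remove the intravascular blood contribution from a regional TAC
#'
#' Tissue activity is the total regional activity minus a fixed blood-volume
#' fraction (default 5%) times total plasma activity at the frame.
#'
#' @param roi_tac A `tac` with `blood_corrected = FALSE`.
#' @param total_plasma Total plasma activity per frame (frame-averaged), same
#'   length as the schedule.
#' @param blood_volume_fraction Fractional blood volume, default 0.05.
#' @return A blood-corrected `tac`.
#' @export
blood_correct <- function(roi_tac, total_plasma, blood_volume_fraction = 0.05) {
  stopifnot(inherits(roi_tac, "tac"))
  if (roi_tac$blood_corrected) stop("TAC is already blood-corrected")
  if (length(total_plasma) != length(roi_tac$activity)) {
    stop("plasma and ROI frame vectors must have equal length")
  }
  roi_tac$activity <- roi_tac$activity - blood_volume_fraction * total_plasma
  roi_tac$blood_corrected <- TRUE
  roi_tac
}

# ---- closed-form convolution of exponentials with the fitted input ----------

# B0 = int_0^D exp(-a v) dv, B1 = int_0^D v exp(-a v) dv, vectorized over D;
# series used where the exact forms cancel catastrophically.
.b0 <- function(a, D) {
  if (a < 1e-12) return(D)
  -expm1(-a * D) / a
}
.b1 <- function(a, D) {
  if (a < 1e-12) return(D^2 / 2)
  z <- a * D
  out <- numeric(length(D))
  small <- z < 1e-3
  if (any(small)) {
    Ds <- D[small]
    out[small] <- Ds^2 / 2 - a * Ds^3 / 3 + a^2 * Ds^4 / 8
  }
  if (any(!small)) {
    out[!small] <- (1 - (1 + z[!small]) * exp(-z[!small])) / a^2
  }
  out
}

# F_alpha(t) = int_0^t exp(-alpha (t - s)) Cp(s) ds for the piecewise input:
# linear between pre-peak knots, multi-exponential tail from the peak.
.conv_exp_input <- function(alpha, t, input) {
  F <- numeric(length(t))
  pt <- input$pre$time; pv <- input$pre$value
  for (j in seq_len(nrow(input$pre) - 1)) {
    a <- pt[j]; b <- pt[j + 1]
    idx <- which(t > a + 1e-14)
    if (!length(idx)) next
    m <- (pv[j + 1] - pv[j]) / (b - a)
    p0 <- pv[j] - m * a
    bj <- pmin(b, t[idx])
    D <- bj - a
    u1 <- t[idx] - bj
    eu <- exp(-alpha * u1)
    I0 <- eu * .b0(alpha, D)
    I1 <- eu * (u1 * .b0(alpha, D) + .b1(alpha, D))
    F[idx] <- F[idx] + (p0 + m * t[idx]) * I0 - m * I1
  }
  tp <- input$peak_time
  idx <- which(t >= tp)
  if (length(idx)) {
    tau <- t[idx] - tp
    for (i in seq_len(nrow(input$tail))) {
      A <- input$tail$A[i]; lam <- input$tail$lambda[i]
      beta <- lam - alpha
      z <- beta * tau
      contrib <- numeric(length(tau))
      small <- abs(z) < 1e-3
      if (any(small)) {
        zs <- z[small]
        contrib[small] <- exp(-lam * tau[small]) * tau[small] *
          (1 + zs / 2 + zs^2 / 6)
      }
      if (any(!small)) {
        contrib[!small] <- (exp(-alpha * tau[!small]) -
                              exp(-lam * tau[!small])) / beta
      }
      F[idx] <- F[idx] + A * contrib
    }
  }
  F
}

# eigenvalues and residues of the 2TC impulse response
# h(t) = K1/(a2-a1) [ (k3+k4-a1) e^(-a1 t) + (a2-k3-k4) e^(-a2 t) ]
.tcm_modes <- function(params) {
  p <- as.numeric(params[c("K1", "k2", "k3", "k4")])
  S <- p[2] + p[3] + p[4]
  disc <- max(S^2 - 4 * p[2] * p[4], 0)
  a1 <- (S - sqrt(disc)) / 2
  a2 <- (S + sqrt(disc)) / 2
  if (a2 - a1 < 1e-7 * max(a2, 1e-10)) {
    # near-repeated eigenvalues (only reachable at k3 = 0, k2 = k4):
    # evaluate the t*exp(-at) limit by symmetric splitting, O(delta^2) exact
    abar <- S / 2
    delta <- max(1e-6 * abar, 1e-9)
    a1 <- abar - delta
    a2 <- abar + delta
  }
  k34 <- p[3] + p[4]
  list(alpha = c(a1, a2),
       phi = p[1] * c(k34 - a1, a2 - k34) / (a2 - a1))
}

# Gauss-Legendre 5-point rule on [-1, 1]
.gl5_x <- c(-0.906179845938664, -0.5384693101056831, 0,
            0.5384693101056831, 0.906179845938664)
.gl5_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891)

# quadrature nodes for frame averages, split at input knots so the integrand
# is smooth on every subinterval; returns nodes, weights (already divided by
# frame duration) and the owning frame index
.frame_quadrature <- function(schedule, input) {
  knots <- sort(unique(c(input$pre$time, input$peak_time)))
  nodes <- numeric(0); wts <- numeric(0); frame <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    T1 <- schedule$start[i]; T2 <- schedule$start[i] + schedule$duration[i]
    brk <- sort(unique(c(T1, knots[knots > T1 & knots < T2], T2)))
    for (j in seq_len(length(brk) - 1)) {
      l <- brk[j]; r <- brk[j + 1]
      nodes <- c(nodes, (l + r) / 2 + (r - l) / 2 * .gl5_x)
      wts <- c(wts, (r - l) / 2 * .gl5_w / schedule$duration[i])
      frame <- c(frame, rep(i, 5L))
    }
  }
  list(nodes = nodes, weights = wts, frame = frame, n = nrow(schedule))
}

#' Forward two-tissue-compartment model prediction per frame
#'
#' The tissue impulse response (two decaying exponentials in the eigenvalues
#' of the compartmental system) is convolved with the fitted input function in
#' closed form — exponential-times-exponential integrals on the fitted tail
#' and exponential-times-linear integrals on the measured pre-peak segment.
#' Each frame value is the time-average of the tissue curve over the frame
#' interval (Gauss-Legendre quadrature between input knots), matching how
#' emission frames integrate activity.
#'
#' @param params `kinetic_params`.
#' @param input An `input_fn` (metabolite-corrected parent input).
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of frame-averaged tissue activity predictions.
#' @export
model_tac <- function(params, input, schedule) {
  assert_schedule(schedule)
  q <- .frame_quadrature(schedule, input)
  modes <- .tcm_modes(params)
  ct <- modes$phi[1] * .conv_exp_input(modes$alpha[1], q$nodes, input) +
    modes$phi[2] * .conv_exp_input(modes$alpha[2], q$nodes, input)
  as.numeric(rowsum(q$weights * ct, q$frame, reorder = TRUE))
}

#' Frame-averaged values of a fitted input function
#'
#' Time-average of the input curve over each frame interval, on the same
#' quadrature used by [model_tac()]. Used for the intravascular blood term.
#'
#' @inheritParams model_tac
#' @return Numeric vector, one value per frame.
#' @export
input_frame_values <- function(input, schedule) {
  assert_schedule(schedule)
  q <- .frame_quadrature(schedule, input)
  cp <- predict(input, q$nodes)
  as.numeric(rowsum(q$weights * cp, q$frame, reorder = TRUE))
}

#' Fit the 2TC model to a blood-corrected TAC
#'
#' Frame-weighted nonlinear least squares: minimizes
#' sum_i duration_i * (obs_i - pred_i)^2 by Levenberg-Marquardt, the weights
#' reflecting the increasing frame acquisition times of the dynamic protocol.
#' Four starting points are tried within numerical-safety bounds
#' (K1 in (0, 2], k2, k3, k4 in (0, 1] min^-1); an unconstrained refit from
#' the best bounded solution is then accepted when it improves the weighted
#' residual and stays physically admissible.
#'
#' @param roi_tac A blood-corrected `tac` with at least 8 frames.
#' @param input An `input_fn`.
#' @param starts Optional matrix of starting values (columns K1, k2, k3, k4);
#'   defaults to four spread starts.
#' @return Object of class `tcm_fit`: `params`, `vt`, `weighted_rss`,
#'   `converged`, `unconstrained` (whether the free refit was kept), `niter`.
#' @export
fit_2tc <- function(roi_tac, input, starts = NULL) {
  stopifnot(inherits(roi_tac, "tac"), inherits(input, "input_fn"))
  if (!roi_tac$blood_corrected) {
    stop("TAC must be blood-corrected before kinetic fitting (see blood_correct)")
  }
  schedule <- roi_tac$schedule
  if (nrow(schedule) < 8) stop("at least 8 frames are required")
  obs <- roi_tac$activity
  sw <- sqrt(schedule$duration)
  q <- .frame_quadrature(schedule, input)
  pred_fn <- function(p) {
    modes <- .tcm_modes(c(K1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4]))
    ct <- modes$phi[1] * .conv_exp_input(modes$alpha[1], q$nodes, input) +
      modes$phi[2] * .conv_exp_input(modes$alpha[2], q$nodes, input)
    as.numeric(rowsum(q$weights * ct, q$frame, reorder = TRUE))
  }
  resid_fn <- function(p) sw * (obs - pred_fn(p))
  if (is.null(starts)) {
    starts <- rbind(c(0.2, 0.05, 0.05, 0.05),
                    c(0.5, 0.20, 0.20, 0.20),
                    c(0.2, 0.20, 0.05, 0.20),
                    c(0.5, 0.05, 0.20, 0.05))
  }
  lower <- rep(1e-6, 4)
  upper <- c(2, 1, 1, 1)
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    any_ok <- TRUE
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info, niter = fit$niter)
    }
  }
  if (!any_ok || is.null(best)) {
    stop("2TC fit failed to converge from all starting points")
  }
  # truly unconstrained polish from the best bounded solution
  unconstrained <- FALSE
  free_fit <- try(minpack.lm::nls.lm(par = best$par, fn = resid_fn,
                                     control = minpack.lm::nls.lm.control(
                                       maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
                  silent = TRUE)
  if (!inherits(free_fit, "try-error")) {
    p <- free_fit$par
    admissible <- p[1] > 0 && p[2] > 0 && p[3] >= 0 && p[4] >= 0 &&
      !(p[3] > 0 && p[4] <= 0)
    if (admissible && sum(free_fit$fvec^2) <= best$rss + 1e-12) {
      best <- list(par = p, rss = sum(free_fit$fvec^2),
                   info = free_fit$info, niter = free_fit$niter)
      unconstrained <- TRUE
    }
  }
  params <- kinetic_params(best$par[1], best$par[2],
                           max(best$par[3], 0), max(best$par[4], 0))
  out <- list(params = params, vt = vt(params),
              weighted_rss = best$rss,
              converged = best$info %in% 1:4,
              unconstrained = unconstrained,
              niter = best$niter)
  class(out) <- "tcm_fit"
  out
}

#' @export
print.tcm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("2TC fit: K1 = %.4f, k2 = %.4f, k3 = %.4f, k4 = %.4f\n",
              p["K1"], p["k2"], p["k3"], p["k4"]))
  cat(sprintf("  VT = %.4f mL/g, weighted RSS = %.4g, converged = %s%s\n",
              x$vt, x$weighted_rss, x$converged,
              if (x$unconstrained) " (unconstrained polish)" else ""))
  invisible(x)
}
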