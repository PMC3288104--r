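# Synthetic-data generators: the ground truth every downstream stage is
# verified against. The plasma model is a linear rise to the peak followed by
# a tri-exponential tail; the parent fraction decays exponentially to a
# plateau; tissue data follow the forward 2TC model with a 5% blood volume
# and per-frame Gaussian noise whose variance scales as prediction/duration
# (a stand-in for counting statistics that justifies frame-duration weights).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# dense-early arterial sampling emulating manual draws every ~6 s for the
# first two minutes then longer intervals (~35 samples total)
default_plasma_times <- function() {
  c(seq(0.1, 2, by = 0.1), 2.5, 3, 4, 5, 7.5, 10, 12.5, 15, 20, 30, 45,
    60, 75, 85, 90)
}

#' Simulate arterial plasma sampling and metabolite measurements
#'
#' Total plasma activity rises linearly from zero at injection to the peak
#' (the pre-peak bolus shape is a modeling choice; only the post-peak curve is
#' ever fitted) and then follows a tri-exponential tail whose value at the
#' peak is the sum of the amplitudes. The parent fraction follows
#' a*exp(-b*t) + c and is sampled at the seven metabolite-processing times.
#'
#' @param peak_time Time of peak plasma activity, minutes.
#' @param tail_amplitudes,tail_rates Tri-exponential tail parameters
#'   (activity units and min^-1); rates must be positive.
#' @param parent Named vector `c(a, b, c)` of parent-fraction parameters; the
#'   implied fraction must stay within `[0, 1]` over the 90-min scan.
#' @param sample_times Plasma sampling times, minutes (default ~35 samples,
#'   dense early).
#' @param metabolite_times Times of metabolite processing (default 2, 5, 15,
#'   30, 45, 75, 90 min).
#' @param noise_sd Proportional noise SD applied to sampled totals (0 =
#'   noiseless).
#' @param seed Optional RNG seed (restores the global RNG state on exit).
#' @return Object of class `plasma_sim`: `plasma` (time, total),
#'   `metabolites` (time, fraction), and `model` (the generating parameters,
#'   including `peak_value`).
#' @export
simulate_plasma <- function(peak_time = 1,
                            tail_amplitudes = c(18, 9, 3),
                            tail_rates = c(2, 0.25, 0.02),
                            parent = c(a = 0.55, b = 0.15, c = 0.40),
                            sample_times = default_plasma_times(),
                            metabolite_times = c(2, 5, 15, 30, 45, 75, 90),
                            noise_sd = 0, seed = NULL) {
  stopifnot(length(tail_amplitudes) == length(tail_rates))
  if (any(tail_rates <= 0)) stop("tail rates must be positive")
  if (peak_time <= 0) stop("peak_time must be positive")
  pf <- function(t) parent[["a"]] * exp(-parent[["b"]] * t) + parent[["c"]]
  grid <- seq(0, 90, by = 0.25)
  if (any(pf(grid) < 0 | pf(grid) > 1)) {
    stop("parent fraction must lie in [0, 1] over [0, 90] min")
  }
  peak_value <- sum(tail_amplitudes)
  total_curve <- function(t) {
    ifelse(t < peak_time,
           t / peak_time * peak_value,
           as.vector(exp(outer(pmax(t - peak_time, 0), tail_rates,
                               function(tt, l) -l * tt)) %*% tail_amplitudes))
  }
  totals <- total_curve(sample_times)
  if (noise_sd > 0) {
    totals <- .with_seed(seed, totals * (1 + stats::rnorm(length(totals), 0, noise_sd)))
    totals <- pmax(totals, 0)
  }
  out <- list(plasma = data.frame(time = sample_times, total = totals),
              metabolites = data.frame(time = metabolite_times,
                                       fraction = pf(metabolite_times)),
              model = list(peak_time = peak_time, peak_value = peak_value,
                           tail_amplitudes = tail_amplitudes,
                           tail_rates = tail_rates, parent = parent,
                           total_curve = total_curve,
                           parent_curve = function(t) total_curve(t) * pf(t)))
  class(out) <- "plasma_sim"
  out
}

#' Fit the full input-function pipeline to simulated (or real) plasma data
#'
#' Convenience wrapper: parent-fraction fit on the metabolite table,
#' metabolite correction of the totals, tri-exponential fit of the parent
#' curve, and a tail fit of the total curve (needed for the intravascular
#' blood term).
#'
#' @param plasma A `plasma_sim` or a list with `plasma` and `metabolites`
#'   data.frames of the same schema.
#' @return List with `parent_fraction` (`parent_fraction_fit`), `input`
#'   (`input_fn` for the metabolite-corrected parent curve) and `total_input`
#'   (`input_fn` for total plasma activity).
#' @export
fit_plasma_pipeline <- function(plasma) {
  pf <- fit_parent_fraction(plasma$metabolites$time, plasma$metabolites$fraction)
  parent <- compute_input(plasma$plasma$time, plasma$plasma$total, pf)
  list(parent_fraction = pf,
       input = fit_input_function(parent$time, parent$parent),
       total_input = fit_input_function(plasma$plasma$time, plasma$plasma$total))
}

#' Simulate a regional time-activity curve from known kinetics
#'
#' Frame values are the forward 2TC prediction plus the blood-volume fraction
#' times total plasma activity, plus zero-mean Gaussian noise with
#' SD = noise_scale * sqrt(prediction / frame_duration) — longer frames are
#' less noisy, which is what the frame-duration weighting of the kinetic fit
#' assumes.
#'
#' @param params `kinetic_params` ground truth.
#' @param input `input_fn` for the parent (metabolite-corrected) input.
#' @param schedule `frame_schedule`.
#' @param blood_volume_fraction Intravascular volume fraction (default 0.05).
#' @param noise_scale Noise dial in activity units; 0 gives the exact model
#'   output. See [calibrate_noise_scale()].
#' @param total_input `input_fn` for total plasma activity (defaults to
#'   `input`, i.e. no metabolites).
#' @param region Region label.
#' @param seed Optional RNG seed.
#' @return A `tac` (not blood-corrected; the blood term is included).
#' @export
simulate_tac <- function(params, input, schedule, blood_volume_fraction = 0.05,
                         noise_scale = 0, total_input = input,
                         region = "region", seed = NULL) {
  tissue <- model_tac(params, input, schedule)
  blood <- blood_volume_fraction * input_frame_values(total_input, schedule)
  pred <- tissue + blood
  act <- pred
  if (noise_scale > 0) {
    sd <- noise_scale * sqrt(pmax(pred, 0) / schedule$duration)
    act <- .with_seed(seed, pred + stats::rnorm(length(pred), 0, sd))
  }
  tac(act, schedule, region = region, blood_corrected = FALSE)
}

#' Choose a noise scale producing a target early-frame coefficient of variation
#'
#' With frame SD = noise_scale * sqrt(pred/duration), the CV of frame i is
#' noise_scale / sqrt(pred_i * duration_i); this returns the noise_scale whose
#' median CV over the chosen (early) frames equals `target_cv`.
#'
#' @param pred Noiseless frame predictions (tissue + blood).
#' @param schedule `frame_schedule`.
#' @param target_cv Target coefficient of variation (default 0.10).
#' @param frames Frame indices to calibrate on (default the four 15-s frames).
#' @export
calibrate_noise_scale <- function(pred, schedule, target_cv = 0.10, frames = 1:4) {
  target_cv * stats::median(sqrt(pred[frames] * schedule$duration[frames]))
}

#' Ground truth for a simulated baseline/post-drug scan pair
#'
#' Encodes the study conditions: ten component-ROI baseline distribution
#' volumes at realistic magnitudes, delivery constants K1 at cortical/limbic
#' magnitudes, a shared nondisplaceable volume, and a regionally uniform
#' multiplicative affinity shift s applied to the specific distribution
#' volume, so that VT_post = vnd + s * (VT_base - vnd) exactly before noise.
#'
#' @param vt_base Named vector of baseline regional VT (mL g^-1).
#' @param k1 Named vector of regional K1 (mL g^-1 min^-1), same names.
#' @param affinity_shift Multiplicative shift s > 0 of the specific
#'   distribution volume (1 = no change; 1.27 = 27% affinity increase).
#' @param vnd_true Nondisplaceable distribution volume shared by all regions;
#'   must be below every baseline VT.
#' @param k4 Baseline dissociation rate (min^-1); the shift is implemented as
#'   k4_post = k4 / s with K1, k2, k3 unchanged (an affinity change slows
#'   dissociation; delivery is untouched).
#' @param blood_volume_fraction,noise_scale,seed Generator dials.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(vt_base = c(DLPFC = 6.7, OFC = 6.7, MPFC = 7.1,
                                     ACC = 7.2, PC = 6.6, OC = 7.0,
                                     AMY = 5.2, HIP = 5.1, ENT = 5.1,
                                     PHG = 5.4),
                         k1 = c(DLPFC = 0.407, OFC = 0.394, MPFC = 0.419,
                                ACC = 0.408, PC = 0.412, OC = 0.408,
                                AMY = 0.295, HIP = 0.287, ENT = 0.264,
                                PHG = 0.293),
                         affinity_shift = 1.27, vnd_true = 1.0, k4 = 0.1,
                         blood_volume_fraction = 0.05, noise_scale = 0,
                         seed = 1L) {
  stopifnot(setequal(names(vt_base), names(k1)))
  k1 <- k1[names(vt_base)]
  if (affinity_shift <= 0) stop("affinity_shift must be positive")
  if (vnd_true >= min(vt_base)) {
    stop("vnd_true must be below every baseline VT (Lassen geometry undefined)")
  }
  structure(list(vt_base = vt_base, k1 = k1, affinity_shift = affinity_shift,
                 vnd_true = vnd_true, k4 = k4,
                 blood_volume_fraction = blood_volume_fraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "ground_truth")
}

# per-region kinetic parameters implied by a ground truth, one condition
.truth_params <- function(truth, condition = c("baseline", "post")) {
  condition <- match.arg(condition)
  s <- if (condition == "post") truth$affinity_shift else 1
  k4 <- if (condition == "post") truth$k4 / truth$affinity_shift else truth$k4
  regions <- names(truth$vt_base)
  out <- lapply(regions, function(r) {
    k2 <- truth$k1[[r]] / truth$vnd_true
    k3 <- truth$k4 * (truth$vt_base[[r]] / truth$vnd_true - 1)
    kinetic_params(truth$k1[[r]], k2, k3, if (k3 > 0) k4 else 0)
  })
  names(out) <- regions
  out
}

#' Simulate a baseline / post-drug scan pair for one subject
#'
#' Generates plasma data, runs the input-function pipeline on it, builds the
#' per-region 2TC parameters implied by the ground truth (shift applied by
#' scaling k4, leaving K1 and k2 fixed), and simulates TACs for both
#' conditions. A pons region with VT = vnd_true (pure nondisplaceable uptake)
#' is included for the binding-potential outcome measures.
#'
#' @param truth A `ground_truth`.
#' @param schedule `frame_schedule` (default the 19-frame study schedule).
#' @param include_pons Add a "PON" region with no specific binding.
#' @param k1_pons Pons delivery constant.
#' @return Object of class `scan_pair`: `truth_params` (data.frame region x
#'   condition with rate constants and exact VT), `tacs` (list
#'   baseline/post of named `tac` lists), `input`, `total_input`,
#'   `parent_fraction`, `schedule`, `truth`.
#' @export
simulate_subject_pair <- function(truth, schedule = make_frame_schedule(),
                                  include_pons = TRUE, k1_pons = 0.25) {
  stopifnot(inherits(truth, "ground_truth"))
  plasma <- simulate_plasma(seed = truth$seed)
  fits <- fit_plasma_pipeline(plasma)
  params <- list(baseline = .truth_params(truth, "baseline"),
                 post = .truth_params(truth, "post"))
  if (include_pons) {
    pon <- kinetic_params(k1_pons, k1_pons / truth$vnd_true, 0, 0)
    params$baseline$PON <- pon
    params$post$PON <- pon
  }
  tacs <- list()
  rows <- list()
  for (cond in c("baseline", "post")) {
    tacs[[cond]] <- list()
    for (i in seq_along(params[[cond]])) {
      r <- names(params[[cond]])[i]
      p <- params[[cond]][[i]]
      sub_seed <- truth$seed + 1000L * match(cond, c("baseline", "post")) + i
      tacs[[cond]][[r]] <- simulate_tac(
        p, fits$input, schedule,
        blood_volume_fraction = truth$blood_volume_fraction,
        noise_scale = truth$noise_scale,
        total_input = fits$total_input, region = r, seed = sub_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, condition = cond, K1 = p[["K1"]], k2 = p[["k2"]],
        k3 = p[["k3"]], k4 = p[["k4"]], vt = vt(p))
    }
  }
  structure(list(truth_params = do.call(rbind, rows),
                 tacs = tacs, input = fits$input,
                 total_input = fits$total_input,
                 parent_fraction = fits$parent_fraction,
                 schedule = schedule, truth = truth),
            class = "scan_pair")
}

#' Refit a simulated scan pair with the 2TC model
#'
#' Blood-corrects every simulated TAC with the fitted total-plasma curve and
#' the generator's blood-volume fraction, then runs the frame-weighted 2TC
#' fit; the measurement route whose outputs feed the Lassen and statistics
#' stages.
#'
#' @param pair A `scan_pair`.
#' @return data.frame: region, condition, K1, k2, k3, k4, vt, vt_true,
#'   converged.
#' @export
fit_scan_pair <- function(pair) {
  stopifnot(inherits(pair, "scan_pair"))
  plasma_frames <- input_frame_values(pair$total_input, pair$schedule)
  rows <- list()
  for (cond in names(pair$tacs)) {
    for (r in names(pair$tacs[[cond]])) {
      bc <- blood_correct(pair$tacs[[cond]][[r]], plasma_frames,
                          pair$truth$blood_volume_fraction)
      fit <- fit_2tc(bc, pair$input)
      tp <- pair$truth_params
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, condition = cond,
        K1 = fit$params[["K1"]], k2 = fit$params[["k2"]],
        k3 = fit$params[["k3"]], k4 = fit$params[["k4"]],
        vt = fit$vt,
        vt_true = tp$vt[tp$region == r & tp$condition == cond],
        converged = fit$converged)
    }
  }
  do.call(rbind, rows)
}
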