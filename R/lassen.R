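#' Lassen-plot estimation of the affinity shift
#'
#' Ordinary least-squares regression of the per-region distribution-volume
#' difference (baseline - post) on baseline VT. When a challenge changes
#' binding uniformly across regions, the points fall on a line whose slope is
#' the fractional change in binding potential (delta BP) and whose x-intercept
#' is the nondisplaceable distribution volume VND. The affinity shift is
#' 1 - slope (a slope of -0.27 means a 27% affinity increase).
#'
#' @param vt_baseline,vt_post Paired per-region VT values (>= 3 regions).
#' @param region Optional region labels, carried into the returned data.
#' @return Object of class `lassen_fit`: `slope`, `intercept`, `x_intercept`
#'   (NA, flagged via `x_intercept_defined`, when the slope is zero),
#'   `delta_bp` (= slope), `affinity_shift` (= 1 - slope), `r_squared`,
#'   `n_regions`, `data`.
#' @export
lassen_fit <- function(vt_baseline, vt_post, region = NULL) {
  stopifnot(length(vt_baseline) == length(vt_post))
  n <- length(vt_baseline)
  if (n < 3) stop("at least 3 paired regions are required")
  if (stats::var(vt_baseline) == 0) {
    stop("zero variance in baseline VT: Lassen regression undefined")
  }
  y <- vt_baseline - vt_post
  fit <- stats::lm(y ~ vt_baseline)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  defined <- abs(slope) > .Machine$double.eps^0.5
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  out <- list(slope = slope,
              intercept = intercept,
              x_intercept = if (defined) -intercept / slope else NA_real_,
              x_intercept_defined = defined,
              delta_bp = slope,
              affinity_shift = 1 - slope,
              r_squared = r2,
              n_regions = n,
              data = data.frame(region = if (is.null(region)) seq_len(n) else region,
                                vt_baseline = vt_baseline, vt_post = vt_post,
                                diff = y))
  class(out) <- "lassen_fit"
  out
}

#' @export
print.lassen_fit <- function(x, ...) {
  cat(sprintf("Lassen fit (%d regions): slope (delta BP) = %.4f, x-intercept (VND) = %s\n",
              x$n_regions, x$slope,
              if (x$x_intercept_defined) sprintf("%.4f", x$x_intercept) else "undefined (slope ~ 0)"))
  cat(sprintf("  affinity shift = 1 - slope = %.4f (R^2 = %.4f)\n",
              x$affinity_shift, x$r_squared))
  invisible(x)
}

#' Group summary of per-subject Lassen fits
#'
#' Unweighted means and SDs of slope, x-intercept and affinity shift across
#' subjects (each subject fitted separately, then summarized — not a pooled
#' regression). With a single subject the SDs are NA by convention.
#'
#' @param fits List of `lassen_fit` objects, one per subject.
#' @return data.frame with rows slope, x_intercept, affinity_shift and
#'   columns mean, sd, n.
#' @export
group_shift_summary <- function(fits) {
  if (!length(fits)) stop("no Lassen fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "lassen_fit")))
  g <- function(field) vapply(fits, `[[`, numeric(1), field)
  sds <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  vals <- list(slope = g("slope"), x_intercept = g("x_intercept"),
               affinity_shift = g("affinity_shift"))
  data.frame(measure = names(vals),
             mean = vapply(vals, function(v) mean(v, na.rm = TRUE), numeric(1)),
             sd = vapply(vals, function(v) sds(v[is.finite(v)]), numeric(1)),
             n = length(fits), row.names = NULL)
}
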