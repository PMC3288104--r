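# Group-level statistical battery: paired t with Cohen's d, per-subject
# percent change, the split-plot repeated-measures ANOVA (regions within
# scan, condition between scans), and Pearson correlation gated by a
# Kolmogorov-Smirnov normality pre-check. No multiple-testing correction is
# applied anywhere (uncorrected alpha = 0.05 convention).

#' Paired two-tailed t-test with Cohen's d
#'
#' Cohen's d uses the paired-difference convention
#' d = mean(base - post) / sd(base - post), so d is negative when values
#' increase post-challenge.
#'
#' @param baseline,post Subject-paired vectors, n >= 2.
#' @return List with `t`, `df`, `p`, `cohen_d` (NA, with `d_defined = FALSE`,
#'   when the differences have zero variance), `mean_diff`, `n`.
#' @export
paired_t <- function(baseline, post) {
  stopifnot(length(baseline) == length(post))
  n <- length(baseline)
  if (n < 2) stop("need at least 2 pairs")
  d <- baseline - post
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = if (mean(d) == 0) 0 else NaN, df = n - 1,
                p = if (mean(d) == 0) 1 else NaN,
                cohen_d = NA_real_, d_defined = FALSE,
                mean_diff = mean(d), n = n))
  }
  tt <- stats::t.test(baseline, post, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = mean(d) / sdd, d_defined = TRUE,
       mean_diff = mean(d), n = n)
}

#' Per-subject percent change, summarized
#'
#' Computes 100 * (post - base) / base per subject, then its mean and SD.
#' Note the mean of per-subject ratios is not the ratio of group means; group
#' means cannot reproduce this column.
#'
#' @param baseline,post Subject-paired vectors; baseline values must be
#'   nonzero.
#' @return List with `mean`, `sd`, `per_subject`.
#' @export
percent_change <- function(baseline, post) {
  stopifnot(length(baseline) == length(post))
  if (any(baseline == 0)) stop("percent change undefined: zero baseline value")
  pc <- 100 * (post - baseline) / baseline
  list(mean = mean(pc), sd = if (length(pc) > 1) stats::sd(pc) else NA_real_,
       per_subject = pc)
}

#' Split-plot repeated-measures ANOVA (regions within scan, condition between)
#'
#' Each scan (subject x condition) is the experimental unit; brain region is
#' the within-scan factor and condition (baseline vs post-drug) the
#' between-scan factor. The univariate sums-of-squares decomposition is
#' computed via `stats::aov` with an `Error(scan)` stratum: condition is
#' tested against between-scan error, region and region x condition against
#' within-scan error.
#'
#' @param data data.frame with columns `subject`, `region`, `condition`,
#'   `value`; the design must be complete and balanced.
#' @return data.frame with rows condition, region, region:condition and
#'   columns effect, df1, df2, F, p, ss.
#' @export
rm_anova <- function(data) {
  stopifnot(all(c("subject", "region", "condition", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$region <- factor(data$region)
  data$condition <- factor(data$condition)
  counts <- table(data$subject, data$region, data$condition)
  if (any(counts != 1)) stop("design must be complete and balanced (one value per cell)")
  data$scan <- interaction(data$subject, data$condition, drop = TRUE)
  fit <- stats::aov(value ~ condition * region + Error(scan), data = data)
  sm <- summary(fit)
  between <- sm[["Error: scan"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    j <- grep("Residuals", trimws(rownames(tab)))[1]
    data.frame(effect = term,
               df1 = tab[i, "Df"], df2 = tab[j, "Df"],
               F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
               ss = tab[i, "Sum Sq"], row.names = NULL)
  }
  rbind(pick(between, "condition"),
        pick(within, "region"),
        pick(within, "condition:region"))
}

#' Pearson correlation with a Kolmogorov-Smirnov normality pre-check
#'
#' Each variable is first tested against a normal distribution with its own
#' sample mean and SD (estimated-parameter KS reference); the Pearson
#' product-moment correlation and two-tailed p follow.
#'
#' @param x,y Paired vectors, n >= 3, each with positive variance.
#' @return List with `r`, `p`, `n`, `ks_p_x`, `ks_p_y`, `ks_pass` (both KS
#'   p-values above 0.05).
#' @export
pearson_with_normality <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ks_x <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  ks_y <- suppressWarnings(stats::ks.test(y, "pnorm", mean(y), stats::sd(y)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       ks_p_x = ks_x$p.value, ks_p_y = ks_y$p.value,
       ks_pass = ks_x$p.value > 0.05 && ks_y$p.value > 0.05)
}

#' Paired-comparison table for regional outcomes
#'
#' One row per region: baseline and post means with SD, percent change
#' (mean over per-subject percents), Cohen's d and the paired-t p value —
#' the layout of the study's regional outcome tables.
#'
#' @param data data.frame with columns `subject`, `region`, `condition`
#'   (values "baseline"/"post") and `value`.
#' @return data.frame, one row per region.
#' @export
paired_region_table <- function(data) {
  stopifnot(all(c("subject", "region", "condition", "value") %in% names(data)))
  regions <- unique(data$region)
  rows <- lapply(regions, function(r) {
    d <- data[data$region == r, ]
    d <- d[order(d$subject), ]
    base <- d$value[d$condition == "baseline"]
    post <- d$value[d$condition == "post"]
    tt <- paired_t(base, post)
    pc <- percent_change(base, post)
    data.frame(region = r,
               baseline_mean = mean(base), baseline_sd = stats::sd(base),
               post_mean = mean(post), post_sd = stats::sd(post),
               pct_change_mean = pc$mean, pct_change_sd = pc$sd,
               cohen_d = tt$cohen_d, p = tt$p, row.names = NULL)
  })
  do.call(rbind, rows)
}
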