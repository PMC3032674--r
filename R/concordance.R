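# Cross-method concordance: deep-sequencing per-CpG levels versus bulk
# pyrosequencing levels. Difference sign convention throughout:
# diff = level_deep - level_bulk.

#' Pair deep-sequencing and bulk per-CpG measurements
#'
#' Inner join on (sample, locus, cpg_index). Bins flagged low-coverage
#' and sites without coverage are excluded; exclusions are logged with a
#' reason in the `"excluded"` attribute.
#'
#' @param deep Per-CpG table from [profile_table()] (columns sample,
#'   locus, cpg_index, level_pct, coverage, low_coverage).
#' @param bulk Bulk table (sample, locus, cpg_index, level_pct).
#' @param drop_low_coverage Exclude low-coverage bins (default `TRUE`).
#' @return Data frame: sample, locus, cpg_index, level_deep, level_bulk,
#'   coverage_deep; attribute `excluded` records dropped pairs.
#' @export
pair_measurements <- function(deep, bulk, drop_low_coverage = TRUE) {
  mg <- merge(deep, bulk, by = c("sample", "locus", "cpg_index"),
              suffixes = c("_deep", "_bulk"))
  if (!nrow(mg))
    stop("no overlapping (sample, locus, cpg_index) keys between ",
         "deep and bulk tables")
  drop_lc <- drop_low_coverage & mg$low_coverage
  drop_cov <- !drop_lc & (is.na(mg$level_pct_deep) | mg$coverage == 0)
  excl <- mg[drop_lc | drop_cov, c("sample", "locus", "cpg_index")]
  excl$reason <- ifelse(drop_lc[drop_lc | drop_cov], "low_coverage",
                        "no_coverage")
  row.names(excl) <- NULL
  keep <- !(drop_lc | drop_cov)
  out <- data.frame(sample = mg$sample[keep], locus = mg$locus[keep],
                    cpg_index = mg$cpg_index[keep],
                    level_deep = mg$level_pct_deep[keep],
                    level_bulk = mg$level_pct_bulk[keep],
                    coverage_deep = mg$coverage[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$locus, out$cpg_index), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

pair_diffs <- function(pairs) {
  if (is.data.frame(pairs)) pairs$level_deep - pairs$level_bulk
  else as.numeric(pairs)
}

#' Bland-Altman agreement statistics
#'
#' Differences (deep - bulk), their mean and SD, and the 95% band. The
#' default band is the limits of agreement, `mean +/- 1.96 * SD`; with
#' `method = "tolerance"` a 95%/95% normal tolerance interval
#' (Howe's k-factor) is used instead.
#'
#' @param pairs Paired data frame from [pair_measurements()], or a
#'   numeric vector of differences.
#' @param method `"loa"` (default) or `"tolerance"`.
#' @return List: `n`, `mean_diff`, `sd_diff`, `lower_95`, `upper_95`,
#'   `k` (band multiplier), `table` (mean_of_two, diff) for plotting.
#' @export
bland_altman <- function(pairs, method = c("loa", "tolerance")) {
  method <- match.arg(method)
  d <- pair_diffs(pairs)
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs")
  m <- mean(d); s <- sd(d)
  k <- if (method == "loa") 1.96
       else qnorm(0.975) * sqrt((n - 1) * (1 + 1 / n) /
                                qchisq(0.05, n - 1))
  tab <- if (is.data.frame(pairs))
    data.frame(mean_of_two = (pairs$level_deep + pairs$level_bulk) / 2,
               diff = d)
  else data.frame(mean_of_two = NA_real_, diff = d)
  list(n = n, mean_diff = m, sd_diff = s,
       lower_95 = m - k * s, upper_95 = m + k * s, k = k, table = tab)
}

#' Regression of deep-sequencing on bulk levels
#'
#' Ordinary least squares of `level_deep` on `level_bulk`, with an
#' intercept by default or through the origin.
#'
#' @param pairs Paired data frame.
#' @param through_origin Fit without intercept (default `FALSE`).
#' @return List: `n`, `slope`, `intercept` (`NA` through origin), `r2`,
#'   `slope_ci_low`, `slope_ci_high`, `p_value`.
#' @export
regression <- function(pairs, through_origin = FALSE) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (sd(pairs$level_bulk) == 0)
    stop("zero variance in bulk levels")
  fit <- if (through_origin) lm(level_deep ~ 0 + level_bulk, data = pairs)
         else lm(level_deep ~ level_bulk, data = pairs)
  sm <- summary(fit)
  ci <- confint(fit, "level_bulk", level = 0.95)
  co <- sm$coefficients["level_bulk", ]
  list(n = nrow(pairs),
       slope = unname(co["Estimate"]),
       intercept = if (through_origin) NA_real_
                   else unname(coef(fit)["(Intercept)"]),
       r2 = sm$r.squared,
       slope_ci_low = ci[1], slope_ci_high = ci[2],
       p_value = unname(co["Pr(>|t|)"]))
}

#' Congruence fractions at deviation thresholds
#'
#' Fraction of pairs whose absolute difference is below each threshold;
#' below 10 percentage points is the customary acceptability criterion
#' given the 2-10 point technical variability of bulk pyrosequencing.
#'
#' @param pairs Paired data frame or numeric differences.
#' @param thresholds Deviation thresholds in percentage points.
#' @return Data frame: threshold, n_within, pct_within (one decimal,
#'   truncated); attribute `n` is the number of pairs.
#' @export
congruence_fractions <- function(pairs, thresholds = c(2, 5, 10)) {
  d <- abs(pair_diffs(pairs))
  if (!length(d)) stop("need at least 1 pair")
  out <- data.frame(
    threshold = thresholds,
    n_within = vapply(thresholds, function(t) sum(d < t), 0L),
    pct_within = vapply(thresholds,
                        function(t) funnel_pct(sum(d < t), length(d)), 0))
  attr(out, "n") <- length(d)
  out
}

#' Coverage versus congruence
#'
#' Emits the (coverage, |diff|) scatter table and the coverage threshold:
#' the smallest observed coverage `c` such that every pair with coverage
#' at least `c` lies inside the overall Bland-Altman 95% band
#' (`|diff - mean_diff| <= 1.96 * SD`). `NA` if no such coverage exists.
#'
#' @param pairs Paired data frame (must carry `coverage_deep`).
#' @param band Optional [bland_altman()] result; computed from `pairs`
#'   when missing.
#' @return List: `table` (coverage, abs_diff, in_band),
#'   `coverage_threshold`.
#' @export
coverage_vs_congruence <- function(pairs, band = NULL) {
  if (is.null(pairs$coverage_deep)) stop("pairs must carry coverage_deep")
  if (is.null(band)) band <- bland_altman(pairs)
  d <- pair_diffs(pairs)
  ok <- abs(d - band$mean_diff) <= 1.96 * band$sd_diff
  tab <- data.frame(coverage = pairs$coverage_deep, abs_diff = abs(d),
                    in_band = ok)
  o <- order(tab$coverage)
  cov_s <- tab$coverage[o]; ok_s <- ok[o]
  # all pairs with coverage >= c are in band <=> no failure at or above c
  bad_above <- rev(cummax(rev(as.integer(!ok_s)))) == 1L
  cand <- cov_s[!bad_above]
  list(table = tab,
       coverage_threshold = if (length(cand)) min(cand) else NA_real_)
}

#' Correlation of amplicon length with read yield
#'
#' @param per_amplicon Data frame with columns `length` and `mean_reads`.
#' @return List: `r` (Pearson correlation), `n`.
#' @export
correlate_yield <- function(per_amplicon) {
  if (nrow(per_amplicon) < 3) stop("need at least 3 amplicons")
  if (sd(per_amplicon$length) == 0 || sd(per_amplicon$mean_reads) == 0)
    stop("zero variance in amplicon lengths or read counts")
  list(r = cor(per_amplicon$length, per_amplicon$mean_reads),
       n = nrow(per_amplicon))
}

#' Full concordance report
#'
#' @param pairs Paired data frame from [pair_measurements()].
#' @param through_origin Regression mode (see [regression()]).
#' @param ba_method Band type (see [bland_altman()]).
#' @return List with `n_pairs`, `bland_altman`, `regression`,
#'   `congruence` and `coverage_threshold`, mirroring the statistics of a
#'   method-comparison study.
#' @export
concordance_report <- function(pairs, through_origin = FALSE,
                               ba_method = c("loa", "tolerance")) {
  ba <- bland_altman(pairs, method = ba_method)
  cov <- coverage_vs_congruence(pairs, band = bland_altman(pairs))
  list(n_pairs = nrow(pairs),
       bland_altman = ba[c("mean_diff", "sd_diff", "lower_95",
                           "upper_95")],
       regression = regression(pairs, through_origin = through_origin),
       congruence = congruence_fractions(pairs),
       coverage_threshold = cov$coverage_threshold)
}
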