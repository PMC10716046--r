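# Dual-initiation promoter (DIP) calling and YC:YR transcription dynamics:
# ratio statistics, paired cohort comparisons, trajectory-gene selection,
# gene-set intersections, and small closed-form utilities.

#' DIP-calling parameters
#'
#' @param min_class_tpm Per-class TPM threshold; a sample qualifies when
#'   both YR and YC TPM are strictly greater. Default 1.
#' @param majority_fraction Fraction of samples that must qualify (strict
#'   greater-than). Default 0.5.
#' @param pseudocount TPM added to numerator and denominator of YC:YR
#'   ratios. Default 0.01.
#' @return A list of class `dip_params`.
#' @export
dip_params <- function(min_class_tpm = 1, majority_fraction = 0.5,
                       pseudocount = 0.01) {
  stopifnot(min_class_tpm >= 0, majority_fraction > 0, majority_fraction <= 1,
            pseudocount > 0)
  structure(list(min_class_tpm = min_class_tpm,
                 majority_fraction = majority_fraction,
                 pseudocount = pseudocount), class = "dip_params")
}

#' Call dual-initiation promoters
#'
#' A promoter is a DIP when the number of samples with both YR and YC
#' expression strictly above `min_class_tpm` exceeds
#' `majority_fraction * n_samples`.
#'
#' @param yc,yr Matrices of per-promoter (rows), per-sample (columns)
#'   TPM for the YC and YR classes, with matching dimnames.
#' @param params A [dip_params()] object. `majority_n`, if given, overrides
#'   the fraction with an absolute sample count (at least this many
#'   qualifying samples).
#' @param majority_n Optional integer override of the majority rule.
#' @return Logical vector (named by promoter) of DIP status.
#' @export
call_dips <- function(yc, yr, params = dip_params(), majority_n = NULL) {
  stopifnot(all(dim(yc) == dim(yr)))
  qual <- (yc > params$min_class_tpm) & (yr > params$min_class_tpm)
  nq <- rowSums(qual)
  if (!is.null(majority_n)) {
    out <- nq >= majority_n
  } else {
    out <- nq > params$majority_fraction * ncol(yc)
  }
  stats::setNames(out, rownames(yc))
}

#' YC:YR expression ratios
#'
#' Per promoter and sample, `r = (YC + eps) / (YR + eps)`; the normalized
#' ratio divides by the promoter's arithmetic-mean ratio across samples,
#' so `rowMeans(r_norm) == 1` per promoter.
#'
#' @param yc,yr TPM matrices (promoters x samples).
#' @param eps Pseudocount. Default 0.01.
#' @return A list with matrices `r`, `r_norm`, `log2_r`.
#' @export
yc_yr_ratio <- function(yc, yr, eps = 0.01) {
  r <- (yc + eps) / (yr + eps)
  r_norm <- r / rowMeans(r)
  list(r = r, r_norm = r_norm, log2_r = log2(r))
}

#' Paired comparison of YC:YR ratios
#'
#' Per promoter, the log2 fold change `d = log2(r_condition) -
#' log2(r_reference)` is averaged over the supplied sample pairs; the mean
#' `d` across promoters is tested against 0 with a one-sample two-tailed
#' t-test. With fewer than 3 promoters the test is skipped (with a
#' warning) and only the mean is reported. A zero-variance nonzero `d` is
#' reported with `p = 0` and `degenerate = TRUE`.
#'
#' @param r Ratio matrix (promoters x samples), e.g. `yc_yr_ratio()$r`.
#' @param pairs A data.frame with columns `condition` and `reference`
#'   naming sample columns of `r`.
#' @return A list: `d` (per-promoter mean log2FC), `mean_log2fc`, `t`,
#'   `p`, `n`, `degenerate`.
#' @export
paired_ratio_test <- function(r, pairs) {
  stopifnot(all(c(pairs$condition, pairs$reference) %in% colnames(r)))
  d_each <- log2(r[, pairs$condition, drop = FALSE]) -
    log2(r[, pairs$reference, drop = FALSE])
  d <- rowMeans(d_each)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3L) {
    warnf("paired ratio test skipped: only %d promoter(s) with finite values", n)
    return(list(d = d, mean_log2fc = mean(d), t = NA_real_, p = NA_real_,
                n = n, degenerate = FALSE))
  }
  if (stats::sd(d) == 0) {
    mean_d <- mean(d)
    return(list(d = d, mean_log2fc = mean_d, t = if (mean_d == 0) 0 else Inf,
                p = if (mean_d == 0) 1 else 0, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(d = d, mean_log2fc = mean(d), t = unname(tt$statistic),
       p = tt$p.value, n = n, degenerate = FALSE)
}

#' Chi-squared test of summed YR vs YC expression between two groups
#'
#' Sums YC and YR TPM over the samples of each group, rounds to integers,
#' and applies Pearson's chi-squared test without continuity correction to
#' the 2x2 table. A zero cell triggers a Haldane correction (+0.5 to every
#' cell) with a flag. TPM totals are not counts; the rounding caveat is
#' deliberate and mirrors figure-level practice.
#'
#' @param yc,yr TPM matrices (promoters x samples).
#' @param group_a,group_b Character vectors of sample columns.
#' @return A list: `table` (2x2), `statistic`, `p`, `odds_ratio`,
#'   `haldane` flag.
#' @export
class_total_chisq <- function(yc, yr, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stopf("empty sample group")
  tab <- rbind(a = c(YC = round(sum(yc[, group_a])), YR = round(sum(yr[, group_a]))),
               b = c(YC = round(sum(yc[, group_b])), YR = round(sum(yr[, group_b]))))
  haldane <- any(tab == 0)
  work <- if (haldane) tab + 0.5 else tab
  if (any(rowSums(work) == 0) || any(colSums(work) == 0))
    stopf("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(stats::chisq.test(work, correct = FALSE))
  or <- (work[1, 1] * work[2, 2]) / (work[1, 2] * work[2, 1])
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       odds_ratio = or, haldane = haldane)
}

#' Select trajectory promoters along a cohort order
#'
#' A promoter is selected when its cohort-level metric is strictly
#' monotone decreasing along `cohort_order` (first cohort highest). The
#' metric is the cohort mean of `log2 r` (`"ratio"`, i.e. the geometric
#' mean ratio) or the cohort mean change in `log2 r` upon treatment
#' (`"delta"`, requiring `pairs`).
#'
#' @param r Ratio matrix (promoters x samples).
#' @param cohorts Named character vector mapping sample column to cohort.
#' @param cohort_order Cohort labels from highest to lowest expected value.
#' @param metric `"ratio"` or `"delta"`.
#' @param pairs For `"delta"`: data.frame with `condition` and `reference`
#'   sample columns (e.g. irradiated vs control), one row per pair.
#' @return A list: `selected` (promoter names), `cohort_means` (promoters
#'   x cohorts matrix of the metric), `monotone` (logical vector).
#' @export
trajectory_select <- function(r, cohorts, cohort_order,
                              metric = c("ratio", "delta"), pairs = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(cohort_order) >= 2)
  if (metric == "ratio") {
    vals <- log2(r)
    sample_cohort <- cohorts[colnames(r)]
  } else {
    if (is.null(pairs)) stopf("metric 'delta' needs `pairs`")
    vals <- log2(r[, pairs$condition, drop = FALSE]) -
      log2(r[, pairs$reference, drop = FALSE])
    colnames(vals) <- pairs$condition
    sample_cohort <- cohorts[pairs$condition]
  }
  miss <- setdiff(cohort_order, unique(sample_cohort))
  if (length(miss)) stopf("cohort(s) with zero samples: %s",
                          paste(miss, collapse = ", "))
  means <- sapply(cohort_order, function(co)
    rowMeans(vals[, sample_cohort == co, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(r), cohort_order))
  mono <- apply(means, 1, function(v) all(diff(v) < 0))
  list(selected = rownames(r)[mono], cohort_means = means, monotone = mono)
}

#' All Venn regions of named gene sets
#'
#' Identifiers are case-normalized (upper) and deduplicated. Every
#' non-empty combination of membership gets an exclusive region plus the
#' full pairwise/overall intersections.
#'
#' @param sets Named list of character vectors.
#' @return A list: `regions` (exclusive region label -> sorted members),
#'   `region_counts`, `intersections` (every subset of two or more sets:
#'   label -> sorted full intersection), `intersection_counts`.
#' @export
intersect_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  sets <- lapply(sets, function(s) sort(unique(toupper(s))))
  universe <- sort(unique(unlist(sets)))
  memb <- sapply(sets, function(s) universe %in% s)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe),
                                         dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- split(universe, pattern)
  regions <- lapply(regions, sort)
  nm <- names(sets)
  combos <- unlist(lapply(2:max(2, length(nm)), function(k)
    if (k <= length(nm)) utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  intersections <- list()
  for (cmb in combos) {
    lab <- paste(cmb, collapse = "&")
    intersections[[lab]] <- sort(Reduce(intersect, sets[cmb]))
  }
  list(regions = regions,
       region_counts = vapply(regions, length, 0L),
       intersections = intersections,
       intersection_counts = vapply(intersections, length, 0L))
}

#' Indirect YC expression by qPCR subtraction
#'
#' The long (YR-initiating) transcript level measured by 5'-specific
#' primers is subtracted from total expression measured by internal
#' primers; the remainder estimates the YC contribution. Negative
#' differences are clipped to zero; a shortfall beyond `tolerance`
#' (relative) is flagged as a primer inconsistency.
#'
#' @param total,yr Non-negative expression values on the same relative
#'   scale.
#' @param tolerance Relative tolerance for `yr > total`. Default 0.05.
#' @return A list: `yc`, `ratio` (yc / yr), `flag_inconsistent`.
#' @export
qpcr_yc_estimate <- function(total, yr, tolerance = 0.05) {
  stopifnot(all(total >= 0), all(yr >= 0))
  yc <- pmax(total - yr, 0)
  flag <- yr > total * (1 + tolerance)
  list(yc = yc, ratio = yc / yr, flag_inconsistent = flag)
}

#' Cell doubling time
#'
#' `T * ln(2) / ln(X / seed)` days for a culture seeded with `seed_count`
#' cells and counted at `final_count` after `elapsed_days`.
#'
#' @param elapsed_days Days between seeding and counting.
#' @param final_count Final cell count.
#' @param seed_count Seeded cells. Default 50000.
#' @return Doubling time in days.
#' @export
doubling_time <- function(elapsed_days, final_count, seed_count = 50000) {
  stopifnot(elapsed_days > 0)
  if (any(final_count <= seed_count))
    stopf("no growth: final count must exceed the %g seeded cells", seed_count)
  elapsed_days * log(2) / log(final_count / seed_count)
}

#' Relative survival of treated vs control cultures
#'
#' Mean treated viability over mean control viability, with the standard
#' error propagated from replicate s.e.m.s. A single replicate per arm
#' yields an undefined s.e. with a flag.
#'
#' @param treated,control Replicate viability measurements.
#' @return A list: `fraction`, `se`, `flag_single_replicate`.
#' @export
relative_survival <- function(treated, control) {
  if (mean(control) <= 0) stopf("control viability must be positive")
  frac <- mean(treated) / mean(control)
  single <- length(treated) < 2 || length(control) < 2
  se <- if (single) NA_real_ else {
    se_t <- stats::sd(treated) / sqrt(length(treated))
    se_c <- stats::sd(control) / sqrt(length(control))
    frac * sqrt((se_t / mean(treated))^2 + (se_c / mean(control))^2)
  }
  list(fraction = frac, se = se, flag_single_replicate = single)
}

#' Fixed-bin frequency distribution of log2 ratios
#'
#' 32 equal log2-spaced bins over [-5, 5], for plotting YC:YR ratio
#' distributions; values outside the range land in the edge bins.
#'
#' @param r Vector or matrix of ratios (must be positive).
#' @return A data.frame with `bin_low`, `bin_high` (log2 scale), `count`.
#' @export
ratio_freq_table <- function(r) {
  v <- pmin(pmax(log2(as.numeric(r)), -5), 5)
  breaks <- seq(-5, 5, length.out = 33)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  data.frame(bin_low = breaks[-33], bin_high = breaks[-1], count = h$counts)
}

#' Benjamini-Hochberg adjustment helper for batched promoter tests
#'
#' @param p Raw p-values.
#' @return FDR-adjusted p-values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")
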