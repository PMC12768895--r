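# Diagnostic statistics: arm-level aberration calls, Wilcoxon tests,
# ROC/AUC with Youden-optimal cutoffs, and confusion-matrix metrics.

#' Arm-level gain/loss calls from a Z-profile
#'
#' Per chromosome arm the bin Z-scores are Stouffer-combined,
#' `aggregate_z = sum(z) / sqrt(n)`, over unmasked bins; an arm is called a
#' gain when `aggregate_z >= z_threshold`, a loss when `<= -z_threshold`,
#' otherwise none. Arms with fewer than `min_bins` usable bins are reported
#' as `none` with `low_bins = TRUE`.
#'
#' @param zp a [zscore()] profile.
#' @param bins the bin frame.
#' @param z_threshold call threshold on the aggregate Z (default 3).
#' @param min_bins minimum usable bins per arm (default 5).
#' @return data.frame: `chrom`, `arm`, `n_bins`, `aggregate_z`,
#'   `direction`, `low_bins`.
#' @export
arm_calls <- function(zp, bins, z_threshold = 3, min_bins = 5) {
  stopifnot(length(zp$z) == nrow(bins))
  key <- arm_key(bins)
  keys <- unique(key)
  rows <- lapply(keys, function(k) {
    sel <- key == k & !is.na(zp$z)
    n <- sum(sel)
    az <- if (n > 0) sum(zp$z[sel]) / sqrt(n) else NA_real_
    low <- n < min_bins
    dir <- if (low || is.na(az)) "none"
      else if (az >= z_threshold) "gain"
      else if (az <= -z_threshold) "loss" else "none"
    first <- which(key == k)[1]
    data.frame(chrom = bins$chrom[first], arm = bins$arm[first],
               n_bins = n, aggregate_z = az, direction = dir,
               low_bins = low, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sample_id") <- zp$sample_id
  out
}

# midranks with ties
midranks <- function(v) rank(v, ties.method = "average")

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact by complete enumeration of all `choose(n1+n2, n1)` group
#' assignments when `n1 + n2 <= 12` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' Identical multisets return p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @return list of class `group_comparison`: `statistic` (Mann-Whitney U of
#'   `x`), `p`, `n1`, `n2`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  all_v <- c(x, y)
  r <- midranks(all_v)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (isTRUE(all.equal(stats::var(all_v), 0)) || length(unique(all_v)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(statistic = U, p = 1, n1 = n1, n2 = n2,
                          method = "degenerate"),
                     class = "group_comparison"))
  }
  if (n <= 12 && !has_ties) {
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p_le <- mean(ws <= W + 1e-9)
    p_ge <- mean(ws >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    method <- "normal approximation"
  }
  structure(list(statistic = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "group_comparison")
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. Exact by enumeration of all `2^n` sign
#' patterns when `n <= 16` and the absolute differences are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @return list of class `group_comparison` (statistic = V, the positive
#'   rank sum of `pre - post`).
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  d <- as.numeric(pre) - as.numeric(post)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = 0, p = 1, n1 = 0, n2 = 0,
                          method = "degenerate"),
                     class = "group_comparison"))
  }
  r <- midranks(abs(d))
  V <- sum(r[d > 0])
  # sign-flip enumeration stays exact under tied |d| (midranks are fixed;
  # only the signs are random under the null)
  if (n <= 16) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p_le <- mean(vs <= V + 1e-9)
    p_ge <- mean(vs >= V - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(V - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    method <- "normal approximation"
  }
  structure(list(statistic = V, p = p, n1 = n, n2 = n, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s): statistic = %g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p, x$n1, x$n2))
  invisible(x)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC via the Mann-Whitney rank identity (ties count 1/2); the CI is a
#' stratified percentile bootstrap (cases and controls resampled
#' separately).
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels binary labels (logical or 0/1), both classes present.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return list of class `roc_result`: `auc`, `ci` (lo, hi), `curve`
#'   (data.frame threshold/sensitivity/specificity for rule "positive if
#'   score >= threshold").
#' @export
roc <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("roc requires both classes present")
  auc_rank <- function(s, l) {
    r <- rank(s, ties.method = "average")
    n1 <- sum(l); n0 <- sum(!l)
    (sum(r[l]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_rank(scores, labels)
  restore <- local_seed(seed)
  pos <- scores[labels]; neg <- scores[!labels]
  boots <- replicate(n_boot, {
    sp <- sample(pos, replace = TRUE); sn <- sample(neg, replace = TRUE)
    auc_rank(c(sp, sn), c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
  })
  restore()
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  thr <- sort(unique(scores))
  curve <- do.call(rbind, lapply(c(-Inf, thr, Inf), function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & labels) / sum(labels),
               specificity = sum(!pred & !labels) / sum(!labels))
  }))
  structure(list(auc = auc, ci = ci, curve = curve, n_pos = sum(labels),
                 n_neg = sum(!labels)),
            class = "roc_result")
}

#' Youden-optimal cutoff
#'
#' Brute-force over the observed score values as candidate thresholds
#' (rule: positive if `score >= cutoff`), maximizing
#' `J = sensitivity + specificity - 1`. Ties in J break toward higher
#' specificity, then the lower cutoff.
#'
#' @param scores,labels as in [roc()].
#' @return the cutoff value.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("youden_cutoff requires both classes present")
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cutoff = t, j = j, spec = spec)
    }
  }
  best$cutoff
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn non-negative integer counts; `tp + fn >= 1` and
#'   `tn + fp >= 1`.
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (NA where a denominator is zero) plus the counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fn >= 1, tn + fp >= 1)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Integer confusion counts implied by printed sensitivity/specificity
#'
#' Reconstructs (tp, fp, tn, fn) from a rounded sensitivity and specificity
#' and the group sizes, as the nearest integer counts.
#'
#' @param sensitivity,specificity printed (possibly rounded) fractions.
#' @param n_pos,n_neg group sizes.
#' @return list with tp, fp, tn, fn.
#' @export
implied_counts <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  list(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Evaluate one diagnostic contrast on a cohort table
#'
#' Scores (TFx) of the positive group against the negative group: ROC with
#' bootstrap CI, Youden-optimal cutoff, then confusion metrics at that
#' cutoff.
#'
#' @param sample_table data.frame with a `tfx` column.
#' @param positives,negatives logical masks over rows of `sample_table`
#'   (non-overlapping, each non-empty).
#' @param group label carried into the result.
#' @param n_boot,seed bootstrap settings for [roc()].
#' @return list of class `diagnostic_result`: `group`, `auc`, `ci`,
#'   `cutoff`, metrics and counts.
#' @export
evaluate_group <- function(sample_table, positives, negatives,
                           group = NA_character_, n_boot = 2000, seed = 1L) {
  stopifnot(is.logical(positives), is.logical(negatives),
            length(positives) == nrow(sample_table),
            length(negatives) == nrow(sample_table))
  if (any(positives & negatives))
    stop("positive and negative groups overlap")
  if (!any(positives) || !any(negatives))
    stop("both groups must be non-empty")
  scores <- c(sample_table$tfx[positives], sample_table$tfx[negatives])
  labels <- c(rep(TRUE, sum(positives)), rep(FALSE, sum(negatives)))
  rc <- roc(scores, labels, n_boot = n_boot, seed = seed)
  cut <- youden_cutoff(scores, labels)
  pred <- scores >= cut
  cm <- confusion_metrics(tp = sum(pred & labels), fp = sum(pred & !labels),
                          tn = sum(!pred & !labels), fn = sum(!pred & labels))
  structure(c(list(group = group, auc = rc$auc, ci = rc$ci, cutoff = cut),
              cm),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(
    "diagnostic_result '%s': AUC %.2f (%.2f-%.2f), cutoff %.4g\n",
    x$group, x$auc, x$ci[1], x$ci[2], x$cutoff))
  cat(sprintf(
    "  sens %.2f  spec %.2f  ppv %.2f  npv %.2f  accuracy %.2f\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Paired pre/post-treatment TFx summary
#'
#' Medians and ranges per arm of the pairing plus a two-sided signed-rank
#' test of the change. With fewer than 5 pairs only descriptive statistics
#' are returned (with a warning).
#'
#' @param pre,post paired TFx vectors (fractions or percents, consistently).
#' @return list: `median_pre`, `median_post`, `range_pre`, `range_post`,
#'   `p`, `n_pairs`.
#' @export
paired_tfx_report <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  n <- length(pre)
  p <- NA_real_
  if (n >= 5) {
    p <- wilcoxon_signed_rank(pre, post)$p
  } else {
    warning("fewer than 5 pairs; descriptive summary only")
  }
  list(median_pre = stats::median(pre), median_post = stats::median(post),
       range_pre = range(pre), range_post = range(post),
       p = p, n_pairs = n)
}
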