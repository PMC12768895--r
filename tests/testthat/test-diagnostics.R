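zp_fixture <- function(z, bins) {
  structure(list(sample_id = "s", z = z, ratio = z, mask = !is.na(z)),
            class = "z_profile")
}

test_that("arm-level Stouffer aggregation and thresholding", {
  kt <- karyotype(c("c1", "c2"), c(4e7, 2e7), c(2e7, 1e7))
  bins <- make_bins(kt, 2e5)  # arms of 100 bins each on c1, 50 on c2

  calls <- arm_calls(zp_fixture(rep(0, nrow(bins)), bins), bins)
  expect_true(all(calls$direction == "none"))

  z <- rep(0, nrow(bins))
  z[bins$chrom == "c1" & bins$arm == "p"] <- 0.5    # 100 bins
  calls2 <- arm_calls(zp_fixture(z, bins), bins)
  c1p <- calls2[calls2$chrom == "c1" & calls2$arm == "p", ]
  expect_equal(c1p$aggregate_z, 5)  # 0.5 * 100 / sqrt(100)
  expect_equal(c1p$direction, "gain")
  expect_equal(calls2$direction[calls2$chrom == "c2"], c("none", "none"))

  # arms with < 5 usable bins are flagged, never called
  z2 <- rep(10, nrow(bins))
  z2[bins$chrom == "c2" & bins$arm == "p"][-(1:3)] <- NA
  calls3 <- arm_calls(zp_fixture(z2, bins), bins)
  c2p <- calls3[calls3$chrom == "c2" & calls3$arm == "p", ]
  expect_true(c2p$low_bins)
  expect_equal(c2p$direction, "none")
})

test_that("rank-sum test: exact enumeration and worked example", {
  g <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(g$p, 0.1, tolerance = 1e-12)  # 2 / choose(6, 3)
  expect_equal(g$method, "exact enumeration")

  expect_warning(g2 <- wilcoxon_ranksum(c(2, 2), c(2, 2)), "identical")
  expect_equal(g2$p, 1)

  # identical multisets, with ties: no separation
  g3 <- wilcoxon_ranksum(c(1, 2, 2, 5), c(2, 5, 1, 2))
  expect_equal(g3$p, 1)
})

test_that("rank-sum agrees with the stats::wilcox.test oracle", {
  set.seed(51)
  for (r in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    if (n1 + n2 <= 12) {
      expect_equal(wilcoxon_ranksum(x, y)$p,
                   wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  }
  for (r in 1:20) {
    x <- rnorm(25); y <- rnorm(30, 0.3)
    expect_equal(wilcoxon_ranksum(x, y)$p,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-8)
    # tie correction path
    xt <- round(rnorm(25), 1); yt <- round(rnorm(30, 0.3), 1)
    expect_equal(wilcoxon_ranksum(xt, yt)$p,
                 wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("rank-sum type-I error is near nominal", {
  set.seed(52)
  rej <- replicate(400, wilcoxon_ranksum(rnorm(40), rnorm(40))$p < 0.05)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("signed-rank test: exact floor, identity, oracle agreement", {
  pre <- rnorm(16)
  g <- wilcoxon_signed_rank(pre, pre - 1)
  expect_equal(g$p, 2 * 2^-16, tolerance = 1e-12)

  expect_warning(g2 <- wilcoxon_signed_rank(pre, pre), "zero")
  expect_equal(g2$p, 1)

  set.seed(53)
  for (r in 1:15) {
    a <- rnorm(12); b <- rnorm(12, 0.5)
    expect_equal(wilcoxon_signed_rank(a, b)$p,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  for (r in 1:10) {
    a <- rnorm(40); b <- rnorm(40, 0.3)
    expect_equal(wilcoxon_signed_rank(a, b)$p,
                 wilcox.test(a, b, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("AUC follows the rank identity and the trapezoid oracle", {
  r <- roc(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 200, seed = 1)
  expect_equal(r$auc, 1)
  r2 <- roc(c(1, 2, 3, 4), c(0, 1, 0, 1), n_boot = 200, seed = 1)
  expect_equal(r2$auc, 0.75)

  trapezoid_auc <- function(curve) {
    fpr <- 1 - curve$specificity; tpr <- curve$sensitivity
    o <- order(fpr, tpr)
    sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  }
  set.seed(54)
  for (rep in 1:10) {
    scores <- c(rnorm(20), rnorm(15, 1))
    if (rep %% 2 == 0) scores <- round(scores, 1)  # with ties
    labels <- rep(c(FALSE, TRUE), c(20, 15))
    rr <- roc(scores, labels, n_boot = 100, seed = rep)
    expect_equal(rr$auc, trapezoid_auc(rr$curve), tolerance = 1e-12)
    expect_true(rr$ci[1] <= rr$ci[2])
  }

  # label shuffling gives a null AUC
  set.seed(55)
  rn <- roc(rnorm(200), sample(rep(0:1, 100)), n_boot = 100, seed = 2)
  expect_gte(rn$auc, 0.4)
  expect_lte(rn$auc, 0.6)

  expect_error(roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Youden cutoff maximizes J with the documented tie rules", {
  # enumeration of the worked case: J ties at 0.2 and 0.4, higher
  # specificity wins
  expect_equal(youden_cutoff(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.4)

  # separated classes: smallest positive-class score
  expect_equal(youden_cutoff(c(1, 2, 10, 11), c(0, 0, 1, 1)), 10)

  # property: J at the returned cutoff is a global maximum
  set.seed(56)
  for (r in 1:20) {
    scores <- round(rnorm(30), 1)
    labels <- runif(30) < plogis(scores)
    if (!any(labels) || all(labels)) next
    cut <- youden_cutoff(scores, labels)
    jfun <- function(t) {
      mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
    }
    jbest <- max(sapply(unique(scores), jfun))
    expect_equal(jfun(cut), jbest, tolerance = 1e-12)
  }
})

test_that("confusion metrics reproduce printed diagnostic rows", {
  nb <- confusion_metrics(tp = 36, fn = 5, tn = 11, fp = 0)
  expect_equal(round(nb$sensitivity, 2), 0.88)
  expect_equal(round(nb$accuracy, 2), 0.90)
  expect_equal(round(nb$npv, 2), 0.69)
  expect_equal(nb$ppv, 1)

  gnb <- confusion_metrics(tp = 10, fn = 12, tn = 9, fp = 2)
  expect_equal(round(gnb$accuracy, 2), 0.58)
  expect_equal(round(gnb$ppv, 2), 0.83)
  expect_equal(round(gnb$npv, 2), 0.43)

  corner <- confusion_metrics(tp = 0, fn = 1, tn = 1, fp = 0)
  expect_equal(corner$sensitivity, 0)
  expect_equal(corner$specificity, 1)
  expect_equal(corner$accuracy, 0.5)
  expect_true(is.na(corner$ppv))  # zero denominator -> missing, not error

  expect_error(confusion_metrics(0, 0, 0, 0))
})

test_that("accuracy identity holds for emitted rows", {
  set.seed(57)
  for (r in 1:20) {
    cm <- confusion_metrics(tp = rpois(1, 10), fp = rpois(1, 3),
                            tn = rpois(1, 8) + 1, fn = rpois(1, 4) + 1)
    n <- cm$tp + cm$fp + cm$tn + cm$fn
    expect_equal(cm$accuracy,
                 (cm$sensitivity * (cm$tp + cm$fn) +
                    cm$specificity * (cm$tn + cm$fp)) / n,
                 tolerance = 1e-12)
  }
})

test_that("evaluate_group ties ROC, cutoff and confusion together", {
  tab <- data.frame(tfx = c(rnorm(10, 0.3, 0.02), rnorm(8, 0.001, 0.0005)),
                    grp = rep(c("tumor", "hc"), c(10, 8)))
  res <- evaluate_group(tab, tab$grp == "tumor", tab$grp == "hc",
                        group = "tumor", n_boot = 200, seed = 3)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$tp + res$fn, 10)

  expect_error(evaluate_group(tab, tab$grp == "tumor", tab$grp == "tumor"),
               "overlap")
  expect_error(evaluate_group(tab, rep(FALSE, 18), tab$grp == "hc"),
               "non-empty")
})

test_that("paired TFx report computes medians, ranges and the test", {
  rep0 <- suppressWarnings(paired_tfx_report(1:4, 1:4))
  expect_equal(rep0$median_pre, 2.5)

  r1 <- paired_tfx_report(1:16, (1:16) / 10)
  expect_equal(r1$median_pre, 8.5)
  expect_equal(r1$median_post, 0.85)
  expect_equal(r1$range_pre, c(1, 16))
  expect_lt(r1$p, 0.001)

  r2 <- suppressWarnings(paired_tfx_report(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)))
  expect_equal(r2$p, 1)
})
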