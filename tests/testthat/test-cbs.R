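test_that("max_circular_t equals the exhaustive double-loop oracle", {
  # an arc touching position 0 or n and its circular complement describe
  # the same split; compare the induced interior boundary set
  bset <- function(res, n) sort(setdiff(c(res$i, res$j), c(0, n)))
  set.seed(101)
  for (r in 1:60) {
    n <- sample(6:30, 1)
    x <- rnorm(n)
    got <- max_circular_t(x, 2)
    want <- oracle_max_t(x, 2)
    expect_equal(bset(got, n), bset(want, n))
    expect_equal(got$t, want$t, tolerance = 1e-9)
  }
})

test_that("degenerate and clean-step inputs behave as documented", {
  expect_false(max_circular_t(c(0, 0, 0, 0), 2)$found)
  expect_false(max_circular_t(c(1, 2), 2)$found)

  # the (0,3] arc and its circular complement (3,6] are the same split
  # with identical |t|; the lexicographic tie rule returns (0,3]
  m <- max_circular_t(c(0, 0, 0, 5, 5, 5), 2)
  expect_true(m$found)
  expect_equal(c(m$i, m$j), c(0, 3))
  expect_equal(m$t, oracle_max_t(c(0, 0, 0, 5, 5, 5))$t)
})

test_that("split_p_value has the permutation form and sentinel behavior", {
  # overwhelming step: no permutation can reach the observed statistic
  x <- c(rnorm(20), rnorm(20, 10))
  m <- max_circular_t(x, 2)
  p <- split_p_value(x, m$t, segmentation_params(n_perm = 500, seed = 5))
  expect_equal(p, 1 / 501)

  # no-split sentinel
  expect_equal(split_p_value(x, 0, segmentation_params(n_perm = 100)), 1)
  expect_equal(split_p_value(x, -Inf, segmentation_params(n_perm = 100)), 1)

  # deterministic under seed
  y <- rnorm(40)
  my <- max_circular_t(y, 2)
  p1 <- split_p_value(y, my$t, segmentation_params(n_perm = 300, seed = 9))
  p2 <- split_p_value(y, my$t, segmentation_params(n_perm = 300, seed = 9))
  expect_identical(p1, p2)
})

test_that("null rejection rate is near alpha", {
  set.seed(77)
  rej <- replicate(120, {
    x <- rnorm(50)
    m <- max_circular_t(x, 2)
    split_p_value(x, m$t, segmentation_params(n_perm = 400)) < 0.05
  })
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
})

test_that("segmentation recovers clean structure and conserves means", {
  bins <- make_bins(karyotype(c("c1", "c2"), c(4e6, 3e6), c(2e6, 1e6)), 1e5)
  # flat noiseless genome: one segment per chromosome
  vals <- rep(1.5, nrow(bins))
  seg <- cbs_segment(vals, bins, segmentation_params(n_perm = 200, seed = 1))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$mean_value, c(1.5, 1.5))

  # one clean step on c1 (40 bins), flat c2 (30 bins)
  set.seed(12)
  vals2 <- c(rnorm(20, 0, 0.05), rnorm(20, 2, 0.05), rnorm(30, 0, 0.05))
  seg2 <- cbs_segment(vals2, bins, segmentation_params(n_perm = 200, seed = 2))
  s1 <- seg2[seg2$chrom == "c1", ]
  expect_equal(nrow(s1), 2)
  expect_equal(s1$start_bin, c(0, 20))
  expect_equal(nrow(seg2[seg2$chrom == "c2", ]), 1)
  # conservation: segment means reconstruct member-bin means
  for (k in seq_len(nrow(s1))) {
    memb <- vals2[(s1$start_bin[k] + 1):s1$end_bin[k]]
    expect_equal(s1$mean_value[k], mean(memb), tolerance = 1e-9)
  }
})

test_that("segmentation is invariant to adding a constant", {
  bins <- make_bins(karyotype("c1", 6e6, 3e6), 1e5)
  set.seed(13)
  x <- c(rnorm(25), rnorm(35, 1.5))
  s1 <- cbs_segment(x, bins, segmentation_params(n_perm = 300, seed = 4))
  s2 <- cbs_segment(x + 100, bins, segmentation_params(n_perm = 300, seed = 4))
  expect_equal(s1$start_bin, s2$start_bin)
  expect_equal(s1$mean_value + 100, s2$mean_value, tolerance = 1e-9)
})

test_that("masked bins are dropped and coordinates span surviving bins", {
  bins <- make_bins(karyotype("c1", 3e6, 1.5e6), 1e5)
  x <- rep(0, 30); x[c(1, 2, 30)] <- NA
  seg <- cbs_segment(x, bins, segmentation_params(n_perm = 200, seed = 3))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_bins, 27)
  expect_equal(seg$start_bp, bins$start[3])
  expect_equal(seg$end_bp, bins$end[29])
})

test_that("merge_undo applies the pooled-SD rule", {
  bins <- make_bins(karyotype("c1", 1.5e7, 7e6), 1e5)
  set.seed(14)
  # three constructed segments: means 0, 0.05, 2 with within-SD 1
  x <- c(rnorm(50, 0), rnorm(50, 0.05), rnorm(50, 2))
  seg <- make_segment_set(rep("c1", 3), c("p", "p", "q"),
                          c(0, 5e6, 1e7), c(5e6, 1e7, 1.5e7),
                          c(50, 50, 50), c(mean(x[1:50]), mean(x[51:100]),
                                           mean(x[101:150])))
  seg$start_bin <- c(0L, 50L, 100L); seg$end_bin <- c(50L, 100L, 150L)
  merged <- merge_undo(seg, x, bins, undo_sd = 1)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$n_bins, c(100, 50))
  expect_equal(merged$mean_value[1], mean(x[1:100]), tolerance = 1e-9)

  # widely separated means survive
  kept <- merge_undo(seg, x, bins, undo_sd = 0.001)
  expect_equal(nrow(kept), 3)
})
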