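# Shared fixtures. Simulation-heavy tests run on a rescaled frame that is
# statistically equivalent to the stated world (200-kb bins at ~60 expected
# read pairs per bin): 2-Mb bins at depth 600 with dispersion 2 * depth
# preserve per-arm aggregate Z and segment-mean standard errors while
# cutting segmentation cost ~100x.

scaled_bins <- function() {
  if (is.null(.fixture_env$bins2mb))
    .fixture_env$bins2mb <- make_bins(hg19_karyotype(), 2e6)
  .fixture_env$bins2mb
}
.fixture_env <- new.env()

SCALED_DEPTH <- 600

# simulate one tumor + 11 controls, return the analyzed pieces
sim_analyzed <- function(f, events, seed, bins = scaled_bins(),
                         n_perm = 400, by = "arm") {
  spec <- sim_sample_spec("s", f, events, depth = SCALED_DEPTH, seed = seed)
  co <- simulate_cohort(list(spec), 11, bins, seed = seed + 500000L,
                        depth = SCALED_DEPTH)
  bl <- build_baseline(co$profiles[co$sample_sheet$is_control])
  zp <- zscore(co$profiles$s, bl)
  seg <- segment_profile(zp, bins, segmentation_params(n_perm = n_perm),
                         by = by)
  list(zp = zp, seg = seg, baseline = bl, truth = co$truths$s, bins = bins)
}

# minimal hand-built segment set for TFx / LGA unit tests
make_segment_set <- function(chrom, arm, start_bp, end_bp, n_bins,
                             mean_ratio, resid_mad = NULL) {
  seg <- data.frame(chrom = chrom, arm = arm,
                    start_bin = seq_along(chrom) - 1L,
                    end_bin = seq_along(chrom),
                    start_bp = start_bp, end_bp = end_bp, n_bins = n_bins,
                    mean_value = mean_ratio, mean_z = NA_real_,
                    mean_ratio = mean_ratio, mad_value = 0,
                    split_p = NA_real_, stringsAsFactors = FALSE)
  attr(seg, "sample_id") <- "fixture"
  if (!is.null(resid_mad)) attr(seg, "resid_mad") <- resid_mad
  class(seg) <- c("segment_set", "data.frame")
  seg
}

# brute-force oracle for the maximal circular t-statistic (O(n^2) double
# loop, no prefix sums) kept deliberately independent of the C++ path
oracle_max_t <- function(x, min_width = 2) {
  n <- length(x)
  best <- list(i = -1L, j = -1L, t = 0, found = FALSE)
  if (n < 2 * min_width || n < 3) return(best)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      n1 <- j - i; n2 <- n - n1
      if (n1 < min_width || n2 < min_width) next
      a <- x[(i + 1):j]; b <- x[-((i + 1):j)]
      pv <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
      pv <- max(pv, 1e-12)
      tt <- abs(mean(a) - mean(b)) / sqrt(pv * (1 / n1 + 1 / n2))
      if (tt > best$t + 1e-15) best <- list(i = i, j = j, t = tt, found = TRUE)
    }
  }
  if (best$t <= 1e-5) best$found <- FALSE
  best
}
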