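# Control-panel construction built so each control depth-normalizes to the
# spec's worked values: bin 1 norm coverage {10, 12, 14}/12 across controls.
panel_controls <- function() {
  list(coverage_profile("c1", c(10, 14)),
       coverage_profile("c2", c(12, 12)),
       coverage_profile("c3", c(14, 10)))
}

test_that("depth_normalize scales to genome mean 1", {
  expect_equal(depth_normalize(coverage_profile("a", c(2, 2, 2)))$norm,
               c(1, 1, 1))
  expect_equal(depth_normalize(coverage_profile("a", c(1, 2, 3)))$norm,
               c(0.5, 1, 1.5))
  set.seed(4)
  p <- depth_normalize(coverage_profile("a", rpois(100, 50)))
  expect_equal(mean(p$norm), 1, tolerance = 1e-12)
  expect_error(depth_normalize(coverage_profile("a", rep(0, 5))),
               "degenerate")
})

test_that("baseline mean/SD use the n-1 denominator and mask degeneracy", {
  bl <- build_baseline(panel_controls())
  expect_equal(bl$mean[1], 1, tolerance = 1e-12)
  expect_equal(bl$sd[1], 2 / 12, tolerance = 1e-12)
  expect_equal(bl$n_controls, 3)

  # n denominator switch
  bln <- build_baseline(panel_controls(), sd_denominator = "n")
  expect_equal(bln$sd[1], sqrt(8 / 3) / 12, tolerance = 1e-12)

  # zero-variance controls are masked out
  flat <- list(coverage_profile("c1", c(1, 1)), coverage_profile("c2", c(1, 1)))
  blf <- build_baseline(flat)
  expect_false(any(blf$mask))

  expect_error(build_baseline(panel_controls()[1]), "at least 2")
  expect_error(build_baseline(list(coverage_profile("a", 1:3),
                                   coverage_profile("b", 1:4))),
               "same bin frame")
})

test_that("Z formula matches the hand-computed worked example exactly", {
  bl <- build_baseline(panel_controls())
  # sample coverage 16 at bin 1 with equal depths: (16-12)/2 = 2 on the
  # normalized scale
  zp <- zscore(coverage_profile("s", c(16, 8)), bl)
  expect_equal(zp$z[1], 2, tolerance = 1e-12)

  # formula center and scale
  center <- coverage_profile("s", c(12, 12))
  expect_equal(zscore(center, bl)$z[1], 0, tolerance = 1e-12)
  expect_equal(zscore(center, bl)$ratio[1], 0, tolerance = 1e-12)
})

test_that("zscore is affine-equivariant in the baseline scale", {
  set.seed(9)
  controls <- lapply(1:4, function(i)
    coverage_profile(paste0("c", i), rpois(50, 100)))
  bl <- build_baseline(controls)
  s <- depth_normalize(coverage_profile("s", rpois(50, 100)))
  z1 <- zscore(s, bl)$z
  k <- 3.7
  bl2 <- bl; bl2$mean <- bl$mean * k; bl2$sd <- bl$sd * k
  s2 <- s; s2$norm <- s$norm * k
  z2 <- zscore(s2, bl2)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("leave-one-out control Z-scores are calibrated on simulation", {
  bins <- make_bins(toy_karyotype(2), 2e5)  # 900 bins
  co <- simulate_cohort(list(), 11, bins, seed = 21, depth = SCALED_DEPTH)
  ctrl <- co$profiles
  meds <- sds <- numeric(0)
  for (i in seq_len(3)) {  # three leave-one-out folds are plenty
    bl <- build_baseline(ctrl[-i])
    zp <- zscore(ctrl[[i]], bl)
    meds <- c(meds, median(zp$z, na.rm = TRUE))
    sds <- c(sds, sd(zp$z, na.rm = TRUE))
  }
  expect_true(all(abs(meds) < 0.5))
  expect_true(all(sds > 0.7 & sds < 1.4))
})

test_that("bin-count TSV round-trips against the bin frame", {
  bins <- make_bins(toy_karyotype(1), 1e6)
  prof <- coverage_profile("s1", seq_len(nrow(bins)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(prof, bins, path)
  back <- read_bin_counts(path, bins = bins)
  expect_equal(back$raw, prof$raw)
  expect_equal(back$n_reads_total, sum(prof$raw))
})

test_that("bin_reads counts primary high-mapq read starts per bin", {
  skip_if_not_installed("Rsamtools")
  kt <- karyotype(c("chr1", "chr2"), c(1e6, 6e5), c(4e5, 2e5))
  bins <- make_bins(kt, 2e5)

  set.seed(31)
  n <- 100
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos1 <- ifelse(chrom == "chr1", sample.int(1e6 - 50, n, replace = TRUE),
                 sample.int(6e5 - 50, n, replace = TRUE))
  mapq <- sample(c(0, 10, 30, 60), n, replace = TRUE)
  flag <- sample(c(0L, 16L, 256L, 1024L), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.1, 0.1))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000000",
    "@SQ\tSN:chr2\tLN:600000",
    {
      ord <- order(match(chrom, c("chr1", "chr2")), pos1)
      sprintf("r%03d\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t%s\t%s",
              seq_len(n), flag[ord], chrom[ord], pos1[ord], mapq[ord],
              strrep("A", 50), strrep("I", 50))
    }), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  prof <- bin_reads(bam, bins, min_mapq = 20)

  # independent interval-membership oracle
  keep <- mapq >= 20 & !bitwAnd(flag, 256L) & !bitwAnd(flag, 1024L)
  expected <- numeric(nrow(bins))
  for (k in which(keep)) {
    hit <- which(bins$chrom == chrom[k] & bins$start <= pos1[k] - 1 &
                   bins$end > pos1[k] - 1)
    expected[hit] <- expected[hit] + 1
  }
  expect_equal(prof$raw, expected)
  expect_equal(prof$n_reads_total, sum(expected))

  expect_error(bin_reads(withr::local_tempfile(fileext = ".bam"), bins),
               "index")
})

test_that("three reads at known positions land in the right 200-kb bins", {
  skip_if_not_installed("Rsamtools")
  kt <- karyotype("chr1", 1e6, 4e5)
  bins <- make_bins(kt, 2e5)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000000",
    sprintf("r%d\t0\tchr1\t%d\t60\t50M\t*\t0\t0\t%s\t%s",
            1:3, c(11, 150001, 250001), strrep("A", 50), strrep("I", 50))),
    sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  prof <- bin_reads(bam, bins, min_mapq = 20)
  expect_equal(prof$raw, c(2, 1, 0, 0, 0))
})
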