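# Coverage profiles, control baseline, per-bin Z-scores.
#
# The per-bin standardized score follows the control-panel formula
#     Z_b = (coverage_b - mean(coverage_controls_b)) / sd(coverage_controls_b)
# applied to depth-normalized coverage (each sample scaled to genome mean 1
# over usable bins) so that samples of unequal sequencing depth are
# comparable. The SD uses the n-1 (sample) denominator by default.

#' Construct a coverage profile
#'
#' @param sample_id character id.
#' @param raw per-bin read counts (non-negative).
#' @param norm optional depth-normalized coverage (genome mean 1); filled by
#'   [depth_normalize()].
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(sample_id, raw, norm = NULL) {
  raw <- as.numeric(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("raw counts must be >= 0")
  structure(list(sample_id = as.character(sample_id), raw = raw, norm = norm,
                 n_reads_total = sum(raw)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s': %d bins, %s reads%s\n", x$sample_id,
              length(x$raw), format(x$n_reads_total, big.mark = ","),
              if (is.null(x$norm)) " (not depth-normalized)" else ""))
  invisible(x)
}

#' Read a per-bin count table (TSV: chrom, start, end, count)
#'
#' @param path TSV path.
#' @param bins optional `genome_bins` frame to validate against.
#' @param sample_id id for the profile (default: file base name).
#' @return A [coverage_profile()].
#' @export
read_bin_counts <- function(path, bins = NULL, sample_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("bin-count file must have columns: ", paste(need, collapse = ", "))
  if (!is.null(bins)) {
    if (nrow(df) != nrow(bins) || !all(df$chrom == bins$chrom) ||
        !all(df$start == bins$start))
      stop("bin-count file does not match the bin frame")
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  coverage_profile(sample_id, df$count)
}

#' Write a per-bin count table
#' @param profile a [coverage_profile()].
#' @param bins the matching `genome_bins` frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(profile, bins, path) {
  utils::write.table(
    data.frame(chrom = bins$chrom,
               start = format(bins$start, scientific = FALSE, trim = TRUE),
               end = format(bins$end, scientific = FALSE, trim = TRUE),
               count = profile$raw),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count aligned reads per bin from a BAM file
#'
#' Counts primary, non-duplicate alignments with mapping quality >=
#' `min_mapq` by the bin membership of their leftmost aligned position
#' (5'-start counting; strand is ignored). Requires the `Rsamtools`
#' package; the BAM must be coordinate-sorted and indexed.
#'
#' @param bam_path path to an indexed BAM.
#' @param bins a `genome_bins` frame.
#' @param min_mapq minimum mapping quality (default 20).
#' @param sample_id profile id (default: file base name).
#' @return A [coverage_profile()].
#' @export
bin_reads <- function(bam_path, bins, min_mapq = 20, sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("bin_reads requires the Rsamtools package")
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index not found; the BAM must be coordinate-sorted and indexed")
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  aln <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  keep <- !is.na(aln$pos) & !is.na(aln$mapq) & aln$mapq >= min_mapq
  chrom <- as.character(aln$rname)[keep]
  pos0 <- aln$pos[keep] - 1L  # BAM pos is 1-based
  raw <- numeric(nrow(bins))
  bin_size <- attr(bins, "bin_size")
  first_idx <- tapply(seq_len(nrow(bins)), bins$chrom, min)
  for (ch in unique(chrom)) {
    if (!ch %in% names(first_idx)) next
    sel <- chrom == ch
    j <- first_idx[[ch]] + floor(pos0[sel] / bin_size)
    j <- j[j <= max(which(bins$chrom == ch))]
    tab <- table(j)
    raw[as.integer(names(tab))] <- raw[as.integer(names(tab))] + as.integer(tab)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam_path))
  coverage_profile(sample_id, raw)
}

#' Depth-normalize a coverage profile to genome mean 1
#'
#' @param profile a [coverage_profile()].
#' @param mask optional logical vector of usable bins; the normalizing mean
#'   is taken over `mask`-true bins only.
#' @return The profile with `norm = raw / mean(raw[mask])`.
#' @export
depth_normalize <- function(profile, mask = NULL) {
  raw <- profile$raw
  if (is.null(mask)) mask <- rep(TRUE, length(raw))
  m <- mean(raw[mask])
  if (!is.finite(m) || m <= 0)
    stop("degenerate profile: no unmasked bins with positive coverage")
  profile$norm <- raw / m
  profile
}

#' Build the control baseline from a panel of control profiles
#'
#' Each control is depth-normalized, then per-bin mean and SD across
#' controls are computed. Bins with zero mean, or SD below `sd_floor` times
#' the genome-median SD, are masked as unusable; floored-but-kept bins have
#' their SD replaced by the floor so no bin can produce unboundedly large
#' Z-scores.
#'
#' @param controls list of >= 2 [coverage_profile()] on one bin frame.
#' @param sd_floor relative SD floor (fraction of the median per-bin SD,
#'   default 0.05).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return An object of class `control_baseline` with fields `mean`, `sd`,
#'   `mask`, `n_controls`.
#' @export
build_baseline <- function(controls, sd_floor = 0.05,
                           sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(controls) < 2) stop("baseline needs at least 2 controls")
  nb <- length(controls[[1]]$raw)
  if (!all(vapply(controls, function(p) length(p$raw) == nb, logical(1))))
    stop("control profiles are not on the same bin frame")
  mat <- vapply(controls, function(p) {
    if (is.null(p$norm)) p <- depth_normalize(p)
    p$norm
  }, numeric(nb))
  mu <- rowMeans(mat)
  n <- ncol(mat)
  ss <- rowSums((mat - mu)^2)
  sdv <- sqrt(ss / if (sd_denominator == "n-1") (n - 1) else n)
  med_sd <- stats::median(sdv[mu > 0])
  floor_abs <- sd_floor * med_sd
  mask <- mu > 0 & sdv > 0
  low <- mask & sdv < floor_abs
  sdv[low] <- floor_abs
  structure(list(mean = mu, sd = sdv, mask = mask, n_controls = n,
                 sd_floor = sd_floor),
            class = "control_baseline")
}

#' @export
print.control_baseline <- function(x, ...) {
  cat(sprintf("control_baseline: %d controls, %d bins (%d usable)\n",
              x$n_controls, length(x$mean), sum(x$mask)))
  invisible(x)
}

#' Per-bin Z-scores and log2 ratios against the control baseline
#'
#' `z[b] = (norm[b] - mean[b]) / sd[b]` and
#' `ratio[b] = log2(norm[b] / mean[b])` on usable bins; masked bins are NA.
#' Zero coverage is clamped to `1e-6` before the log so dropout bins stay
#' finite.
#'
#' @param profile a depth-normalized [coverage_profile()] (normalized here
#'   if needed, over the baseline mask).
#' @param baseline a [build_baseline()] result on the same bin frame.
#' @return An object of class `z_profile` with fields `sample_id`, `z`,
#'   `ratio`, `mask`.
#' @export
zscore <- function(profile, baseline) {
  nb <- length(baseline$mean)
  if (length(profile$raw) != nb)
    stop("profile and baseline are not on the same bin frame")
  if (is.null(profile$norm)) profile <- depth_normalize(profile, baseline$mask)
  z <- ratio <- rep(NA_real_, nb)
  m <- baseline$mask
  z[m] <- (profile$norm[m] - baseline$mean[m]) / baseline$sd[m]
  ratio[m] <- log2(pmax(profile$norm[m], 1e-6) / baseline$mean[m])
  structure(list(sample_id = profile$sample_id, z = z, ratio = ratio,
                 mask = m),
            class = "z_profile")
}

#' Write a Z/ratio table as TSV keyed by bin
#' @param zp a [zscore()] result.
#' @param bins the matching bin frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_z_table <- function(zp, bins, path) {
  utils::write.table(
    data.frame(chrom = bins$chrom,
               start = format(bins$start, scientific = FALSE, trim = TRUE),
               end = format(bins$end, scientific = FALSE, trim = TRUE),
               arm = bins$arm, z = zp$z, ratio = zp$ratio, mask = zp$mask),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
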