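#' Karyotype tables
#'
#' A karyotype table describes the chromosomes over which all binning,
#' normalization, segmentation and scoring operate: one row per chromosome
#' with its length in base pairs and the midpoint of its centromere, which
#' defines the p/q arm boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp.
#' @param centromere_mid centromere midpoint in bp, strictly inside
#'   `(0, length)`.
#' @param included logical; chromosomes excluded here are dropped before
#'   binning (autosomes are included by default).
#'
#' @return A `data.frame` of class `karyotype` with columns `chrom`,
#'   `length`, `centromere_mid`, `included`.
#' @export
karyotype <- function(chrom, length, centromere_mid, included = TRUE) {
  if (length(chrom) == 0L) stop("karyotype must contain at least one chromosome")
  length <- as.numeric(length)
  centromere_mid <- as.numeric(centromere_mid)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in karyotype")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  if (any(centromere_mid <= 0) || any(centromere_mid >= length))
    stop("centromere_mid must lie strictly inside (0, length)")
  kt <- data.frame(
    chrom = as.character(chrom),
    length = length,
    centromere_mid = centromere_mid,
    included = rep_len(as.logical(included), length(chrom)),
    stringsAsFactors = FALSE
  )
  class(kt) <- c("karyotype", "data.frame")
  kt
}

#' Read a karyotype from a TSV file
#'
#' Expects columns `chrom`, `length`, `centromere_mid` and optionally
#' `included`.
#'
#' @param path path to a tab-separated file.
#' @return A [karyotype()] table.
#' @export
read_karyotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "length", "centromere_mid")
  if (!all(need %in% names(df)))
    stop("karyotype file must have columns: ", paste(need, collapse = ", "))
  inc <- if ("included" %in% names(df)) df$included else TRUE
  karyotype(df$chrom, df$length, df$centromere_mid, inc)
}

#' Bundled hg19-like autosome karyotype
#'
#' Lengths and approximate centromere midpoints for the 22 human autosomes
#' (hg19 coordinates, ~2.88 Gb total). Sex chromosomes are excluded by
#' default because control panels typically mix sexes, which would make
#' chrX/chrY baselines bimodal.
#'
#' @return A [karyotype()] table with 22 rows.
#' @export
hg19_karyotype <- function() {
  path <- system.file("extdata", "hg19_autosomes.tsv", package = "plasmacna",
                      mustWork = TRUE)
  read_karyotype(path)
}

#' A small scaled-down karyotype for examples and fast tests
#'
#' The full autosome frame at 200-kb bins has ~14,400 bins; examples and
#' unit tests use this reduced frame (a handful of chromosomes, shorter
#' lengths) so simulation and segmentation run in seconds.
#'
#' @param n_chrom number of chromosomes (max 6).
#' @param scale multiplier on the built-in toy lengths.
#' @return A [karyotype()] table.
#' @export
toy_karyotype <- function(n_chrom = 4, scale = 1) {
  stopifnot(n_chrom >= 1, n_chrom <= 6)
  lens <- c(100e6, 80e6, 60e6, 50e6, 40e6, 30e6)[seq_len(n_chrom)] * scale
  cents <- lens * c(0.5, 0.4, 0.3, 0.45, 0.35, 0.25)[seq_len(n_chrom)]
  karyotype(paste0("chr", seq_len(n_chrom)), lens, cents)
}
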