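#' Tile a karyotype into fixed-width genomic bins
#'
#' Cuts every included chromosome into consecutive `bin_size` windows
#' (0-based, half-open). The last bin of each chromosome is shortened to the
#' chromosome end, so per-chromosome bin count is `ceiling(length /
#' bin_size)`. Bin indices are dense, zero-based, and follow karyotype row
#' order.
#'
#' @param karyotype a [karyotype()] table.
#' @param bin_size bin width in bp (default 200 kb, minimum 10 kb).
#' @return A `data.frame` of class `genome_bins` with columns `chrom`,
#'   `start`, `end`, `bin_index`, `arm`, and attributes `bin_size` and
#'   `karyotype`.
#' @export
make_bins <- function(karyotype, bin_size = 200000L) {
  if (!inherits(karyotype, "karyotype")) stop("karyotype must be a karyotype table")
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size < 10000)
    stop("bin_size must be a single value >= 10,000 bp")
  kt <- karyotype[karyotype$included, , drop = FALSE]
  if (nrow(kt) == 0L) stop("karyotype has no included chromosomes")
  pieces <- lapply(seq_len(nrow(kt)), function(i) {
    len <- kt$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    data.frame(chrom = kt$chrom[i], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_index <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size
  attr(bins, "karyotype") <- kt
  class(bins) <- c("genome_bins", "data.frame")
  assign_arms(bins, kt)
}

#' Assign chromosome-arm labels to bins
#'
#' A bin belongs to the p arm when its midpoint lies left of the centromere
#' midpoint, to the q arm otherwise (midpoint exactly at the centromere goes
#' to q; the tie rule is arbitrary but fixed).
#'
#' @param bins a `genome_bins` frame.
#' @param karyotype the [karyotype()] the bins were built from.
#' @return `bins` with its `arm` column (re)computed.
#' @export
assign_arms <- function(bins, karyotype) {
  cm <- stats::setNames(karyotype$centromere_mid, karyotype$chrom)
  if (!all(bins$chrom %in% names(cm)))
    stop("chromosome missing from karyotype: ",
         paste(setdiff(unique(bins$chrom), names(cm)), collapse = ", "))
  mid <- (bins$start + bins$end) / 2
  bins$arm <- ifelse(mid < cm[bins$chrom], "p", "q")
  bins
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins of %s bp on %d chromosomes\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Export bins as a BED file (0-based half-open)
#'
#' @param bins a `genome_bins` frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  name <- paste0(bins$chrom, ":", bins$arm, ":", bins$bin_index)
  utils::write.table(
    data.frame(bins$chrom, format(bins$start, scientific = FALSE, trim = TRUE),
               format(bins$end, scientific = FALSE, trim = TRUE), name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# per-chromosome arm key ("chr1:p", ...) used by segmentation and arm calls
arm_key <- function(bins) paste0(bins$chrom, ":", bins$arm)
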