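# Homologous-recombination-deficiency score: count of large genomic
# alterations (LGAs). An LGA is a copy-level break between two directly
# adjacent segments on the same chromosome arm, both spanning at least
# min_size (10 Mb) and differing in mean log2 ratio by at least delta_min.
# Breaks straddling the centromere are never counted.

#' Count large genomic alterations (the HRD score)
#'
#' Segments shorter than `smooth_size` are first smoothed into whichever
#' adjacent same-arm segment has the closer mean, so small interstitial
#' fragments do not interrupt the adjacency of their large neighbors. Then,
#' per chromosome arm, every directly adjacent segment pair with both
#' flanks >= `min_size` bp and `|mean ratio difference| >= delta_min` counts
#' one LGA.
#'
#' @param segments a `segment_set`.
#' @param min_size minimum bp span of both flanking segments (default 10
#'   Mb).
#' @param delta_min minimum |log2-ratio step| for a copy-level break
#'   (default 0.1).
#' @param smooth_size segments below this span are merged into the
#'   closer-mean neighbor before counting (default 3 Mb).
#' @return list of class `scar_score`: `sample_id`, `lga_count`,
#'   `qualifying_breaks` (data.frame chrom, arm, position, left_len,
#'   right_len, delta).
#' @export
lga_count <- function(segments, min_size = 10e6, delta_min = 0.1,
                      smooth_size = 3e6) {
  breaks <- list()
  if (!is.null(segments) && nrow(segments) > 0) {
    key <- paste0(segments$chrom, ":", segments$arm)
    for (k in unique(key)) {
      s <- segments[key == k, , drop = FALSE]
      s <- s[order(s$start_bp), , drop = FALSE]
      s <- smooth_small_segments(s, smooth_size)
      if (nrow(s) < 2) next
      for (i in seq_len(nrow(s) - 1)) {
        left <- s$end_bp[i] - s$start_bp[i]
        right <- s$end_bp[i + 1] - s$start_bp[i + 1]
        delta <- abs(s$mean_ratio[i + 1] - s$mean_ratio[i])
        if (left >= min_size && right >= min_size && delta >= delta_min) {
          breaks[[length(breaks) + 1L]] <- data.frame(
            chrom = s$chrom[i], arm = s$arm[i], position = s$end_bp[i],
            left_len = left, right_len = right, delta = delta,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  qb <- if (length(breaks)) do.call(rbind, breaks) else
    data.frame(chrom = character(), arm = character(), position = numeric(),
               left_len = numeric(), right_len = numeric(),
               delta = numeric(), stringsAsFactors = FALSE)
  structure(list(sample_id = attr(segments, "sample_id"),
                 lga_count = nrow(qb), qualifying_breaks = qb),
            class = "scar_score")
}

# merge segments spanning < smooth_size bp into the adjacent same-arm
# neighbor with the closer mean ratio (bp-length-weighted recombination of
# means); repeats until stable
smooth_small_segments <- function(s, smooth_size) {
  repeat {
    if (nrow(s) < 2) return(s)
    len <- s$end_bp - s$start_bp
    small <- which(len < smooth_size)
    if (length(small) == 0) return(s)
    i <- small[which.min(len[small])]
    nb <- c(if (i > 1) i - 1L, if (i < nrow(s)) i + 1L)
    j <- nb[which.min(abs(s$mean_ratio[nb] - s$mean_ratio[i]))]
    a <- min(i, j); b <- max(i, j)
    w <- len[c(a, b)]
    s$mean_ratio[a] <- sum(s$mean_ratio[c(a, b)] * w) / sum(w)
    s$mean_value[a] <- s$mean_ratio[a]
    s$end_bp[a] <- s$end_bp[b]
    s$end_bin[a] <- s$end_bin[b]
    s$n_bins[a] <- s$n_bins[a] + s$n_bins[b]
    s <- s[-b, , drop = FALSE]
  }
}

#' @export
print.scar_score <- function(x, ...) {
  cat(sprintf("scar_score '%s': %d large genomic alterations\n",
              if (is.null(x$sample_id)) "?" else x$sample_id, x$lga_count))
  invisible(x)
}

#' Write qualifying LGA breaks as TSV
#' @param score a [lga_count()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lga_breaks <- function(score, path) {
  utils::write.table(score$qualifying_breaks, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
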