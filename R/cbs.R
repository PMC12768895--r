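# Circular binary segmentation (CBS) with permutation significance.
#
# Each chromosome is scanned for the circular arc whose mean differs most
# from its complement (maximal two-sample |t|); the split is accepted when
# its permutation p-value is below alpha and the procedure recurses into the
# resulting pieces. Accepted boundaries are finally re-examined by an
# undo-SD merge that removes splits whose segment means differ by less than
# undo_sd pooled within-segment SDs.

#' Segmentation parameters
#'
#' @param alpha permutation significance threshold for accepting a split
#'   (default 0.05).
#' @param n_perm permutations per split test (default 1000, minimum 100).
#' @param min_width minimum bins per segment (default 2).
#' @param undo_sd merge threshold in pooled-SD units (default 1.0; 0
#'   disables the merge pass).
#' @param seed integer seed for the permutation stream (NULL leaves the RNG
#'   state alone).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(alpha = 0.05, n_perm = 1000L, min_width = 2L,
                                undo_sd = 1.0, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 1,
            undo_sd >= 0)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), undo_sd = undo_sd,
                 seed = seed),
            class = "segmentation_params")
}

#' Maximal circular t-statistic of one vector
#'
#' Scans all circular arc boundary pairs `i < j` (the arc being elements
#' `(i+1):j`, its complement wrapping around) that leave both sides at least
#' `min_width` long, and returns the pair maximizing the absolute two-sample
#' t-statistic. Ties break to the smallest `i`, then smallest `j`. A
#' constant or too-short vector returns `found = FALSE` with `t = 0`.
#'
#' @param x numeric vector.
#' @param min_width minimum elements on each side of the split.
#' @return list with `i`, `j` (0-based boundaries), `t` (the maximal |t|),
#'   `found`.
#' @export
max_circular_t <- function(x, min_width = 2L) {
  x <- as.numeric(x)
  if (length(x) < 2 * min_width)
    return(list(i = -1L, j = -1L, t = 0, found = FALSE))
  cpp_max_circular_t(x, as.integer(min_width))
}

#' Permutation p-value of an observed split statistic
#'
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)` where permutations
#' shuffle `x` and recompute the maximal circular t-statistic. With
#' `early_stop = TRUE` the loop aborts once the exceedance count proves
#' `p >= alpha`; the reported p is then based on the permutations actually
#' run (conservative; the accept/reject decision is unchanged).
#'
#' @param x numeric vector the statistic was computed on.
#' @param t_obs observed maximal |t| from [max_circular_t()]; a no-split
#'   sentinel (`found = FALSE` / `t = 0` on constant input) gives p = 1.
#' @param params a [segmentation_params()]; `params$seed`, when non-NULL,
#'   seeds the permutation stream.
#' @param early_stop allow early termination at `params$alpha`.
#' @return numeric p-value.
#' @export
split_p_value <- function(x, t_obs, params = segmentation_params(),
                          early_stop = TRUE) {
  if (!is.finite(t_obs) || t_obs <= 0) return(1)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_split_p(as.numeric(x), t_obs, params$n_perm, params$min_width,
                     if (early_stop) params$alpha else 0)
  res$p
}

# recursive CBS over positions 1..n of one chromosome's unmasked values;
# returns list(pieces = list of integer position vectors, p = split p per
# piece)
cbs_chromosome <- function(x, params) {
  n <- length(x)
  out_pieces <- list()
  out_p <- numeric()
  rec <- function(pos) {
    x_sub <- x[pos]
    mct <- max_circular_t(x_sub, params$min_width)
    pv <- if (mct$found) {
      pp <- params; pp$seed <- NULL
      split_p_value(x_sub, mct$t, pp, early_stop = TRUE)
    } else 1
    if (mct$found && pv < params$alpha) {
      i <- mct$i; j <- mct$j; m <- length(pos)
      cuts <- list()
      if (i > 0) cuts[[length(cuts) + 1L]] <- pos[seq_len(i)]
      cuts[[length(cuts) + 1L]] <- pos[(i + 1):j]
      if (j < m) cuts[[length(cuts) + 1L]] <- pos[(j + 1):m]
      for (cc in cuts) {
        if (length(cc) >= 2 * params$min_width) {
          rec_piece <- rec(cc)
        } else {
          out_pieces[[length(out_pieces) + 1L]] <<- cc
          out_p[length(out_p) + 1L] <<- pv
        }
      }
    } else {
      out_pieces[[length(out_pieces) + 1L]] <<- pos
      out_p[length(out_p) + 1L] <<- pv
    }
    invisible(NULL)
  }
  rec(seq_len(n))
  ord <- order(vapply(out_pieces, min, numeric(1)))
  list(pieces = out_pieces[ord], p = out_p[ord])
}

# undo-SD merge on one chromosome's piece list (positions into x)
undo_merge_pieces <- function(pieces, x, undo_sd) {
  if (undo_sd <= 0 || length(pieces) < 2) return(pieces)
  repeat {
    if (length(pieces) < 2) break
    means <- vapply(pieces, function(p) mean(x[p]), numeric(1))
    k <- length(pieces)
    stat <- rep(Inf, k - 1)
    for (i in seq_len(k - 1)) {
      a <- x[pieces[[i]]]; b <- x[pieces[[i + 1]]]
      ssq <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      df <- length(a) + length(b) - 2
      psd <- if (df > 0) sqrt(ssq / df) else 0
      if (psd <= 1e-12) {
        stat[i] <- if (abs(means[i + 1] - means[i]) <= 1e-12) 0 else Inf
      } else {
        stat[i] <- abs(means[i + 1] - means[i]) / psd
      }
    }
    i <- which.min(stat)
    if (!is.finite(stat[i]) || stat[i] >= undo_sd) break
    pieces[[i]] <- c(pieces[[i]], pieces[[i + 1]])
    pieces[[i + 1]] <- NULL
  }
  pieces
}

#' Segment per-bin values into constant-copy segments
#'
#' Runs circular binary segmentation independently on every chromosome of a
#' per-bin statistic (by default the log2 ratio), with permutation
#' significance at `params$alpha` and a final undo-SD merge. Masked (NA)
#' bins are dropped before segmentation; segment bp coordinates span the
#' surviving member bins.
#'
#' @param values per-bin numeric vector aligned to `bins`; NA = masked.
#' @param bins a [make_bins()] frame.
#' @param params a [segmentation_params()].
#' @param z optional second per-bin statistic (e.g. the Z-score) averaged
#'   per segment into `mean_z`.
#' @param sample_id carried into the output attribute.
#' @param by `"chromosome"` (default): the circular scan runs over whole
#'   chromosomes; `"arm"`: each chromosome arm is segmented independently,
#'   so the centromere is always a segment boundary. The pipeline uses
#'   `"arm"`: centromeres are a-priori copy-number discontinuities and the
#'   downstream LGA rule is arm-bounded anyway, and forcing the boundary
#'   preserves arm-level signal that a whole-chromosome scan dilutes at
#'   low tumor fraction.
#' @return A `data.frame` of class `segment_set`: `chrom`, `arm`,
#'   `start_bin`, `end_bin` (half-open bin indices), `start_bp`, `end_bp`,
#'   `n_bins`, `mean_value`, `mean_z`, `mean_ratio`, `mad_value`,
#'   `split_p`.
#' @export
cbs_segment <- function(values, bins, params = segmentation_params(),
                        z = NULL, sample_id = NA_character_,
                        by = c("chromosome", "arm")) {
  stopifnot(length(values) == nrow(bins))
  by <- match.arg(by)
  if (!is.null(params$seed)) set.seed(params$seed)
  unit <- if (by == "arm") arm_key(bins) else bins$chrom
  rows <- list()
  for (ch in unique(unit)) {
    sel <- which(unit == ch & !is.na(values))
    if (length(sel) == 0L) next
    x <- values[sel]
    res <- cbs_chromosome(x, params)
    pieces <- undo_merge_pieces(res$pieces, x, params$undo_sd)
    pvals <- res$p[match(vapply(pieces, min, numeric(1)),
                         vapply(res$pieces, min, numeric(1)))]
    for (k in seq_along(pieces)) {
      memb <- sel[pieces[[k]]]
      first <- memb[1]; last <- memb[length(memb)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = bins$chrom[first],
        arm = bins$arm[first],
        start_bin = bins$bin_index[first],
        end_bin = bins$bin_index[last] + 1L,
        start_bp = bins$start[first],
        end_bp = bins$end[last],
        n_bins = length(memb),
        mean_value = mean(values[memb]),
        mean_z = if (is.null(z)) NA_real_ else mean(z[memb], na.rm = TRUE),
        mean_ratio = mean(values[memb]),
        mad_value = stats::mad(values[memb]),
        split_p = pvals[k],
        stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  seg <- seg[order(match(seg$chrom, unique(bins$chrom)), seg$start_bin), ]
  rownames(seg) <- NULL
  attr(seg, "sample_id") <- sample_id
  attr(seg, "params") <- params
  # pooled bin-level noise: MAD of within-segment residuals over all bins;
  # more robust than per-segment spreads, which are biased small for
  # segments carved around noise extremes
  fitted <- rep(seg$mean_value, seg$n_bins)
  resid <- values[!is.na(values)] - fitted
  attr(seg, "resid_mad") <- stats::mad(resid)
  class(seg) <- c("segment_set", "data.frame")
  seg
}

#' Undo-SD merge of adjacent segments
#'
#' Iteratively merges adjacent same-chromosome segments whose means differ
#' by less than `undo_sd` pooled within-segment SDs, recomputing segment
#' statistics after each merge.
#'
#' @param segments a `segment_set`.
#' @param values the per-bin vector the segments were built from.
#' @param bins the bin frame.
#' @param undo_sd merge threshold in pooled-SD units.
#' @return A `segment_set`.
#' @export
merge_undo <- function(segments, values, bins, undo_sd = 1.0) {
  out <- list()
  for (ch in unique(segments$chrom)) {
    sch <- segments[segments$chrom == ch, , drop = FALSE]
    memb <- lapply(seq_len(nrow(sch)), function(i) {
      which(bins$chrom == ch & !is.na(values) &
              bins$bin_index >= sch$start_bin[i] &
              bins$bin_index < sch$end_bin[i])
    })
    pieces <- undo_merge_pieces(memb, values, undo_sd)
    for (p in pieces) {
      first <- p[1]; last <- p[length(p)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, arm = bins$arm[first],
        start_bin = bins$bin_index[first],
        end_bin = bins$bin_index[last] + 1L,
        start_bp = bins$start[first], end_bp = bins$end[last],
        n_bins = length(p),
        mean_value = mean(values[p]),
        mean_z = NA_real_, mean_ratio = mean(values[p]),
        mad_value = stats::mad(values[p]), split_p = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  attr(seg, "sample_id") <- attr(segments, "sample_id")
  class(seg) <- c("segment_set", "data.frame")
  seg
}

#' Segment a Z-profile
#'
#' Convenience wrapper: segments the log2 ratio of a [zscore()] profile and
#' carries the per-segment mean Z alongside.
#'
#' @param zp a [zscore()] result.
#' @param bins the bin frame.
#' @param params a [segmentation_params()].
#' @param by segmentation unit, see [cbs_segment()]; the pipeline default
#'   is per-arm.
#' @return A `segment_set`.
#' @export
segment_profile <- function(zp, bins, params = segmentation_params(),
                            by = "arm") {
  cbs_segment(zp$ratio, bins, params, z = zp$z, sample_id = zp$sample_id,
              by = by)
}

#' Write segments in SEG format (1-based inclusive coordinates)
#'
#' @param segments a `segment_set`.
#' @param path output path.
#' @param sample_id overrides the segment set's own id.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample_id = NULL) {
  id <- if (is.null(sample_id)) attr(segments, "sample_id") else sample_id
  utils::write.table(
    data.frame(sample = id, chrom = segments$chrom,
               start = format(segments$start_bp + 1, scientific = FALSE,
                              trim = TRUE),
               end = format(segments$end_bp, scientific = FALSE, trim = TRUE),
               n_bins = segments$n_bins, mean = segments$mean_ratio),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
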