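# Synthetic low-pass WGS cohort generator.
#
# The data-generating model: each bin b of a sample with tumor fraction f and
# per-bin integer copy state c_b has expected read count
#     lambda_b = depth * bias_b * (f * c_b + 2 * (1 - f)) / 2
# and the observed count is negative-binomial with mean lambda_b and size
# (inverse-dispersion) `dispersion`. The bias vector is lognormal, drawn once
# per cohort and shared by all samples, mimicking bin-level systematic bias
# that the control baseline removes.

local_seed <- function(seed) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() assign(".Random.seed", old, envir = globalenv())
}

#' Construct a CNA event table
#'
#' @param chrom,start,end event coordinates (bp, 0-based half-open); `end`
#'   may exceed the chromosome length and is clipped at binning time.
#' @param copy non-negative integer copy state (diploid background is 2).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `copy`.
#' @export
cna_events <- function(chrom = character(), start = numeric(),
                       end = numeric(), copy = integer()) {
  ev <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), copy = as.numeric(copy),
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    if (any(ev$start >= ev$end)) stop("event start must be < end")
    if (any(ev$copy < 0)) stop("copy states must be non-negative")
  }
  ev
}

# chromosomes absent from the karyotype yield empty event lists, so the
# hg19-named presets degrade gracefully on reduced frames
arm_event <- function(kt, chrom, arm, copy) {
  i <- match(chrom, kt$chrom)
  if (is.na(i)) return(cna_events())
  if (arm == "p") cna_events(chrom, 0, kt$centromere_mid[i], copy)
  else cna_events(chrom, kt$centromere_mid[i], kt$length[i], copy)
}

whole_chrom_event <- function(kt, chrom, copy) {
  i <- match(chrom, kt$chrom)
  if (is.na(i)) return(cna_events())
  cna_events(chrom, 0, kt$length[i], copy)
}

#' Neuroblastoma-typical copy-number event presets
#'
#' Fixed event lists emulating recurrent aberration patterns in peripheral
#' neuroblastic tumors:
#' \describe{
#'   \item{flat}{no events (healthy / copy-neutral profile).}
#'   \item{gn_like}{ganglioneuroma-like: copy-neutral (empty list); these
#'     benign tumors shed near-undetectable aberrant ctDNA.}
#'   \item{nb_17q_1p}{segmental neuroblastoma: chr17q gain (c=3) and chr1p
#'     loss (c=1).}
#'   \item{nb_11q}{11q-deleted segmental subtype: chr11q loss, chr17q gain,
#'     chr3p loss.}
#'   \item{nb_mycn_amp}{MYCN-amplified: focal ~1-Mb chr2p amplification
#'     (c=15, around the MYCN locus) on top of chr2p gain, chr17q gain and
#'     chr1p loss.}
#'   \item{hyperdiploid}{numerical-CNA subtype: whole-chromosome c=3 gains
#'     of chr7, chr12, chr13 and chr17.}
#' }
#'
#' @param name preset id, one of `flat`, `gn_like`, `nb_17q_1p`, `nb_11q`,
#'   `nb_mycn_amp`, `hyperdiploid`.
#' @param karyotype karyotype used to resolve arm boundaries (default the
#'   bundled hg19-like autosomes).
#' @return A [cna_events()] table.
#' @export
preset_events <- function(name, karyotype = hg19_karyotype()) {
  kt <- karyotype
  switch(name,
    flat = cna_events(),
    gn_like = cna_events(),
    nb_17q_1p = rbind(
      arm_event(kt, "chr17", "q", 3),
      arm_event(kt, "chr1", "p", 1)),
    nb_11q = rbind(
      arm_event(kt, "chr11", "q", 1),
      arm_event(kt, "chr17", "q", 3),
      arm_event(kt, "chr3", "p", 1)),
    nb_mycn_amp = rbind(
      arm_event(kt, "chr2", "p", 3),
      cna_events("chr2", 15.5e6, 16.5e6, 15),
      arm_event(kt, "chr17", "q", 3),
      arm_event(kt, "chr1", "p", 1)),
    hyperdiploid = rbind(
      whole_chrom_event(kt, "chr7", 3),
      whole_chrom_event(kt, "chr12", 3),
      whole_chrom_event(kt, "chr13", 3),
      whole_chrom_event(kt, "chr17", 3)),
    stop("unknown preset: ", name)
  )
}

#' Specification of one simulated sample
#'
#' @param sample_id character id.
#' @param tumor_fraction true tumor DNA fraction f in \[0, 1\].
#' @param events a [cna_events()] table or a [preset_events()] name.
#' @param depth expected mean read count per bin in an unbiased diploid bin.
#' @param dispersion negative-binomial size parameter; the default
#'   `2 * depth` gives variance = 1.5 x mean at the mean depth.
#' @param seed integer seed for this sample's count noise.
#' @param labels named list of clinicopathologic metadata (histology, risk,
#'   inrg_stage, inss_stage, mycn, timepoint, pair_id).
#' @return An object of class `sim_sample_spec`.
#' @export
sim_sample_spec <- function(sample_id, tumor_fraction = 0, events = "flat",
                            depth = 60, dispersion = 2 * depth,
                            seed = 1L, labels = list()) {
  f <- as.numeric(tumor_fraction)
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  structure(list(sample_id = as.character(sample_id), tumor_fraction = f,
                 events = events, depth = depth, dispersion = dispersion,
                 seed = as.integer(seed), labels = labels),
            class = "sim_sample_spec")
}

# resolve events (preset name or table), clip to chromosomes present in
# `bins`, drop events on absent chromosomes, and apply last-writer-wins for
# overlaps (later rows overwrite earlier ones on the bin copy vector).
resolve_events <- function(events, bins) {
  if (is.character(events)) {
    kt <- attr(bins, "karyotype")
    events <- preset_events(events, karyotype = kt)
  }
  events[events$chrom %in% unique(bins$chrom), , drop = FALSE]
}

# per-bin integer copy state implied by an event list (background 2)
events_to_copy <- function(events, bins) {
  cb <- rep(2, nrow(bins))
  if (nrow(events) == 0L) return(cb)
  for (i in seq_len(nrow(events))) {
    mid <- (bins$start + bins$end) / 2
    hit <- bins$chrom == events$chrom[i] & mid >= events$start[i] &
      mid < events$end[i]
    cb[hit] <- events$copy[i]
  }
  cb
}

# truth segment table + LGA count implied by a copy-state vector, using the
# same arm-bounded >=10 Mb flank rule as lga_count()
truth_segments <- function(copy, bins) {
  key <- arm_key(bins)
  runs <- rle(paste(key, copy))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  data.frame(chrom = bins$chrom[idx_start], arm = bins$arm[idx_start],
             start_bp = bins$start[idx_start], end_bp = bins$end[idx_end],
             copy = copy[idx_start], stringsAsFactors = FALSE)
}

truth_lga <- function(copy, bins, min_size = 10e6) {
  seg <- truth_segments(copy, bins)
  n <- 0L
  if (nrow(seg) < 2) return(n)
  for (i in seq_len(nrow(seg) - 1L)) {
    a <- seg[i, ]; b <- seg[i + 1L, ]
    if (a$chrom == b$chrom && a$arm == b$arm && a$copy != b$copy &&
        (a$end_bp - a$start_bp) >= min_size &&
        (b$end_bp - b$start_bp) >= min_size) n <- n + 1L
  }
  n
}

#' Simulate one LP-WGS bin-count profile
#'
#' @param spec a [sim_sample_spec()].
#' @param bins a [make_bins()] frame.
#' @param bias per-bin multiplicative bias factors (length `nrow(bins)`),
#'   typically drawn once per cohort; default all 1.
#' @return A list with `profile` (a `coverage_profile`) and `truth` (per-bin
#'   copy state, true f, truth segment boundaries, truth LGA count).
#' @export
simulate_sample <- function(spec, bins, bias = rep(1, nrow(bins))) {
  stopifnot(inherits(spec, "sim_sample_spec"))
  if (length(bias) != nrow(bins))
    stop("bias vector length (", length(bias), ") != bin count (",
         nrow(bins), ")")
  ev <- resolve_events(spec$events, bins)
  cb <- events_to_copy(ev, bins)
  f <- spec$tumor_fraction
  lambda <- spec$depth * bias * (f * cb + 2 * (1 - f)) / 2
  restore <- local_seed(spec$seed)
  on.exit(restore())
  raw <- stats::rnbinom(length(lambda), mu = lambda, size = spec$dispersion)
  profile <- coverage_profile(spec$sample_id, raw)
  boundaries <- which(diff(cb) != 0)  # break after bin_index boundaries-1
  truth <- list(copy = cb, tumor_fraction = f, boundaries = boundaries,
                lga = truth_lga(cb, bins), events = ev, labels = spec$labels)
  list(profile = profile, truth = truth)
}

#' Simulate a labeled cohort of control and tumor profiles
#'
#' Controls are simulated copy-neutral (f = 0, no events). One shared
#' lognormal per-bin bias vector is drawn for the whole cohort, so the bias
#' is removable by the control baseline just as systematic bin bias is in
#' real data.
#'
#' @param specs list of [sim_sample_spec()] for the non-control samples.
#' @param n_controls number of healthy-control profiles (>= 2; the baseline
#'   SD needs at least two samples).
#' @param bins a [make_bins()] frame.
#' @param seed cohort-level seed; drives the bias vector, control seeds and
#'   any spec whose own seed is NA.
#' @param bias_sd SD of the per-bin lognormal bias (default 0.1).
#' @param depth,dispersion control-profile depth and dispersion (defaults
#'   match [sim_sample_spec()]).
#' @return A list: `profiles` (named list of `coverage_profile`),
#'   `sample_sheet` (one row per sample with labels and true f), `truths`
#'   (named list), `bias`, `bins`.
#' @export
simulate_cohort <- function(specs, n_controls, bins, seed = 1L,
                            bias_sd = 0.1, depth = 60,
                            dispersion = 2 * depth) {
  if (n_controls < 2) stop("n_controls must be >= 2")
  restore <- local_seed(seed)
  bias <- exp(stats::rnorm(nrow(bins), mean = -bias_sd^2 / 2, sd = bias_sd))
  sub_seeds <- sample.int(2^31 - 2, n_controls + length(specs))
  restore()

  ctrl_specs <- lapply(seq_len(n_controls), function(i) {
    sim_sample_spec(sprintf("control_%02d", i), 0, "flat", depth = depth,
                    dispersion = dispersion, seed = sub_seeds[i],
                    labels = list(histology = "HC", timepoint = "control"))
  })
  specs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (is.na(s$seed)) s$seed <- sub_seeds[n_controls + i]
    s
  })
  all_specs <- c(ctrl_specs, specs)
  sims <- lapply(all_specs, simulate_sample, bins = bins, bias = bias)
  ids <- vapply(all_specs, `[[`, character(1), "sample_id")
  names(sims) <- ids

  lab_field <- function(s, field, default = NA_character_) {
    v <- s$labels[[field]]
    if (is.null(v)) default else as.character(v)
  }
  sheet <- data.frame(
    sample_id = ids,
    is_control = vapply(all_specs, function(s)
      identical(lab_field(s, "timepoint"), "control"), logical(1)),
    true_tfx = vapply(all_specs, `[[`, numeric(1), "tumor_fraction"),
    histology = vapply(all_specs, lab_field, character(1), field = "histology"),
    risk = vapply(all_specs, lab_field, character(1), field = "risk"),
    inrg_stage = vapply(all_specs, lab_field, character(1), field = "inrg_stage"),
    inss_stage = vapply(all_specs, lab_field, character(1), field = "inss_stage"),
    mycn = vapply(all_specs, lab_field, character(1), field = "mycn"),
    timepoint = vapply(all_specs, lab_field, character(1), field = "timepoint"),
    pair_id = vapply(all_specs, lab_field, character(1), field = "pair_id"),
    stringsAsFactors = FALSE
  )
  list(profiles = lapply(sims, `[[`, "profile"),
       sample_sheet = sheet,
       truths = lapply(sims, `[[`, "truth"),
       bias = bias, bins = bins)
}

#' Specs for the demo cohort (11 controls + mixed tumor presets)
#'
#' A small cohort mirroring the structure of a neuroblastic-tumor plasma
#' study: benign ganglioneuroma-like samples at trace fractions, segmental
#' and MYCN-amplified neuroblastoma at fractions 5--40%, and a hyperdiploid
#' sample. Control count (11) matches the healthy-control panel size used
#' throughout.
#'
#' @param f_nb tumor fractions for the four segmental-NB samples.
#' @param depth,dispersion expected reads per bin and negative-binomial
#'   size for every tumor sample (must match the control panel's).
#' @return list of [sim_sample_spec()].
#' @export
demo_cohort_specs <- function(f_nb = c(0.05, 0.1, 0.2, 0.4), depth = 60,
                              dispersion = 2 * depth) {
  specs <- list()
  for (i in seq_along(f_nb)) {
    specs[[length(specs) + 1L]] <- sim_sample_spec(
      sprintf("nb_%02d", i), f_nb[i],
      if (i %% 2 == 0) "nb_11q" else "nb_17q_1p",
      depth = depth, dispersion = dispersion,
      seed = NA, labels = list(histology = "NB", risk = "high",
                               timepoint = "pre"))
  }
  specs[[length(specs) + 1L]] <- sim_sample_spec(
    "nb_mycn", 0.25, "nb_mycn_amp", depth = depth,
    dispersion = dispersion, seed = NA,
    labels = list(histology = "NB", risk = "high", mycn = "amp",
                  timepoint = "pre"))
  specs[[length(specs) + 1L]] <- sim_sample_spec(
    "nb_hyperdiploid", 0.15, "hyperdiploid", depth = depth,
    dispersion = dispersion, seed = NA,
    labels = list(histology = "NB", risk = "intermediate",
                  timepoint = "pre"))
  for (i in 1:2) {
    specs[[length(specs) + 1L]] <- sim_sample_spec(
      sprintf("gn_%02d", i), 0, "gn_like", depth = depth,
      dispersion = dispersion, seed = NA,
      labels = list(histology = "GN", risk = "low", timepoint = "pre"))
  }
  specs
}

#' Specs for a paired pre/post-chemotherapy design
#'
#' Each pair shares one event preset and seedless spec pair: the
#' post-chemotherapy sample reuses the pre-chemotherapy event list at
#' `fold_reduction` times lower tumor fraction, emulating treatment
#' response.
#'
#' @param n_pairs number of patients (default 16).
#' @param f_pre pre-chemotherapy fractions; default log-uniform in
#'   \[0.05, 0.5\] (requires a seed via `seed`).
#' @param fold_reduction fraction divisor applied post-chemotherapy
#'   (default 50).
#' @param seed seed used to draw `f_pre` when not supplied.
#' @param depth,dispersion simulator depth settings for every sample.
#' @return list of 2 * n_pairs [sim_sample_spec()].
#' @export
paired_cohort_specs <- function(n_pairs = 16, f_pre = NULL,
                                fold_reduction = 50, seed = 1L,
                                depth = 60, dispersion = 2 * depth) {
  if (is.null(f_pre)) {
    restore <- local_seed(seed)
    f_pre <- exp(stats::runif(n_pairs, log(0.05), log(0.5)))
    restore()
  }
  stopifnot(length(f_pre) == n_pairs)
  presets <- rep(c("nb_17q_1p", "nb_11q", "nb_mycn_amp"), length.out = n_pairs)
  specs <- list()
  for (i in seq_len(n_pairs)) {
    pid <- sprintf("pt_%02d", i)
    specs[[2 * i - 1]] <- sim_sample_spec(
      paste0(pid, "_pre"), f_pre[i], presets[i], depth = depth,
      dispersion = dispersion, seed = NA,
      labels = list(histology = "NB", timepoint = "pre", pair_id = pid))
    specs[[2 * i]] <- sim_sample_spec(
      paste0(pid, "_post"), f_pre[i] / fold_reduction, presets[i],
      depth = depth, dispersion = dispersion, seed = NA,
      labels = list(histology = "NB", timepoint = "post", pair_id = pid))
  }
  specs
}
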