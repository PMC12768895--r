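# Pipeline orchestration: simulate -> normalize -> segment -> TFx -> HRD ->
# classify, as one reproducible, seeded run writing plain-text artifacts
# plus a machine-readable manifest.

#' Analyze one sample against a control baseline
#'
#' The per-sample core of the pipeline: depth-normalize, Z-score against
#' the baseline, segment the log2 ratio, estimate TFx, count LGAs, call
#' arm-level aberrations, and evaluate the follow-up decision rule.
#'
#' @param profile a [coverage_profile()].
#' @param baseline a [build_baseline()] result.
#' @param bins the bin frame.
#' @param seg_params a [segmentation_params()].
#' @param tfx_par a [tfx_params()].
#' @param z_threshold arm-call threshold (default 3).
#' @return list of class `sample_result`: `sample_id`, `z` (z_profile),
#'   `segments`, `tfx` (tfx_estimate), `scar`, `arms`, `flags`.
#' @export
analyze_sample <- function(profile, baseline, bins,
                           seg_params = segmentation_params(),
                           tfx_par = tfx_params(), z_threshold = 3) {
  zp <- zscore(profile, baseline)
  seg <- segment_profile(zp, bins, seg_params)
  est <- estimate_tfx(seg, tfx_par)
  scar <- lga_count(seg)
  arms <- arm_calls(zp, bins, z_threshold = z_threshold)
  flags <- decision_flags(est$tfx, arms,
                          tfx_threshold = tfx_par$detect_threshold,
                          z_threshold = z_threshold)
  structure(list(sample_id = profile$sample_id, z = zp, segments = seg,
                 tfx = est, scar = scar, arms = arms, flags = flags),
            class = "sample_result")
}

#' Follow-up decision flags
#'
#' A sample is flagged for further clinical evaluation when TFx is at or
#' above the reporting threshold (0.2%) AND at least one chromosome arm has
#' `|aggregate Z| >= z_threshold` (conjunction). The discontinue-style
#' negative flag is the joint converse: TFx below threshold AND every arm
#' below the Z threshold.
#'
#' @param tfx estimated tumor fraction.
#' @param arms an [arm_calls()] table.
#' @param tfx_threshold TFx threshold as a fraction (default 0.002).
#' @param z_threshold arm aggregate-Z threshold (default 3).
#' @param rule `"and"` (default) or `"or"` for the follow-up combination.
#' @return list: `follow_up`, `negative`, `tfx_high`, `any_arm_aberrant`.
#' @export
decision_flags <- function(tfx, arms, tfx_threshold = 0.002,
                           z_threshold = 3, rule = c("and", "or")) {
  rule <- match.arg(rule)
  tfx_high <- tfx >= tfx_threshold
  usable <- !arms$low_bins & !is.na(arms$aggregate_z)
  any_arm <- any(abs(arms$aggregate_z[usable]) >= z_threshold)
  follow <- if (rule == "and") tfx_high && any_arm else tfx_high || any_arm
  list(follow_up = follow,
       negative = !tfx_high && !any_arm,
       tfx_high = tfx_high, any_arm_aberrant = any_arm)
}

#' Build a run configuration
#'
#' All thresholds of the pipeline are surfaced here rather than hard-coded:
#' the 0.2% TFx reporting threshold, the |Z| >= 3 arm rule, the 10-Mb LGA
#' size and the segmentation alpha of 0.05. The configuration round-trips
#' through JSON unchanged and every stage seed is derived deterministically
#' from the global seed.
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param bin_size bin width in bp.
#' @param n_controls simulated controls (simulation mode).
#' @param depth,dispersion,bias_sd simulator settings.
#' @param alpha,n_perm,min_width,undo_sd segmentation settings.
#' @param z_threshold,tfx_threshold,lga_min_size decision thresholds.
#' @param control_paths,sample_paths optional bin-count TSVs; when given,
#'   they replace simulation.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, bin_size = 2e6,
                       n_controls = 11, depth = 600,
                       dispersion = 2 * depth, bias_sd = 0.1,
                       alpha = 0.05, n_perm = 400, min_width = 2,
                       undo_sd = 1.0, z_threshold = 3,
                       tfx_threshold = 0.002, lga_min_size = 10e6,
                       control_paths = NULL, sample_paths = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              bin_size = bin_size, n_controls = n_controls, depth = depth,
              dispersion = dispersion, bias_sd = bias_sd, alpha = alpha,
              n_perm = n_perm, min_width = min_width, undo_sd = undo_sd,
              z_threshold = z_threshold, tfx_threshold = tfx_threshold,
              lga_min_size = lga_min_size,
              control_paths = control_paths, sample_paths = sample_paths)
  if (cfg$seed < 0) stop("seed must be a non-negative integer")
  if (!is.null(control_paths) && length(control_paths) < 2)
    stop("need at least 2 control count files")
  if (!is.null(control_paths)) {
    missing <- c(control_paths, sample_paths)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("input files not found: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' In simulation mode (no input paths) the demo cohort is generated at the
#' configured bin size and depth; otherwise control and sample bin-count
#' TSVs are loaded. Every sample is analyzed with [analyze_sample()];
#' per-sample SEG files, a cohort TFx table and a JSON manifest are written
#' under `config$out_dir`. Reruns with the same config are identical.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  kt <- hg19_karyotype()
  bins <- make_bins(kt, config$bin_size)
  restore <- local_seed(config$seed)
  stage_seeds <- sample.int(2^31 - 2, 4)
  restore()

  if (is.null(config$control_paths)) {
    specs <- demo_cohort_specs(depth = config$depth,
                               dispersion = config$dispersion)
    cohort <- simulate_cohort(specs, config$n_controls, bins,
                              seed = stage_seeds[1],
                              bias_sd = config$bias_sd,
                              depth = config$depth,
                              dispersion = config$dispersion)
    profiles <- cohort$profiles
    sheet <- cohort$sample_sheet
  } else {
    ctrl <- lapply(config$control_paths, read_bin_counts, bins = bins)
    samp <- lapply(config$sample_paths, read_bin_counts, bins = bins)
    profiles <- c(ctrl, samp)
    names(profiles) <- vapply(profiles, `[[`, character(1), "sample_id")
    sheet <- data.frame(sample_id = names(profiles),
                        is_control = c(rep(TRUE, length(ctrl)),
                                       rep(FALSE, length(samp))),
                        stringsAsFactors = FALSE)
  }

  controls <- profiles[sheet$is_control]
  baseline <- build_baseline(controls)
  seg_params <- segmentation_params(alpha = config$alpha,
                                    n_perm = config$n_perm,
                                    min_width = config$min_width,
                                    undo_sd = config$undo_sd)
  tfx_par <- tfx_params(detect_threshold = config$tfx_threshold)

  results <- list()
  set.seed(stage_seeds[2])  # one stream for all permutation tests
  for (id in sheet$sample_id[!sheet$is_control]) {
    res <- analyze_sample(profiles[[id]], baseline, bins,
                          seg_params = seg_params, tfx_par = tfx_par,
                          z_threshold = config$z_threshold)
    write_seg(res$segments, file.path(config$out_dir,
                                      paste0(id, ".seg.tsv")), id)
    results[[id]] <- res
  }

  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, tfx = r$tfx$tfx,
               tfx_percent = 100 * r$tfx$tfx,
               detectable = r$tfx$detectable,
               lga_count = r$scar$lga_count,
               n_segments = nrow(r$segments),
               follow_up = r$flags$follow_up,
               negative_flag = r$flags$negative,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab_path <- file.path(config$out_dir, "tfx_table.tsv")
  utils::write.table(tab, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sheet, file.path(config$out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("plasmacna")),
    seed = config$seed, stage_seeds = stage_seeds,
    n_bins = nrow(bins), n_samples = nrow(sheet),
    config = unclass(config),
    outputs = list(tfx_table = "tfx_table.tsv",
                   sample_sheet = "sample_sheet.tsv"),
    digests = as.list(tools::md5sum(tab_path)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, table = tab, results = results,
                 baseline = baseline, bins = bins, sample_sheet = sheet))
}
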