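# End-to-end orchestration: ingestion -> fixed-bin masking -> variable-width
# re-binning -> GC correction -> HMM fit with baseline anchoring -> segment
# filtering -> chromosome calls -> sample classification.

#' Pipeline configuration
#'
#' All tunable parameters of the nanopore calling pipeline, with the
#' workflow defaults: MAPQ >= 5, 100-kb fixed bins with the 0.9985/0.1
#' quantile mask, 1-Mb nominal variable bins, 3-chromatid expected
#' baseline, 10-Mb minimal segment size, EM at relative tolerance 1e-4 with
#' up to 500 iterations and 3 restarts. `downsample_n` optionally reduces
#' the sample to a fixed read number (e.g. 300,000 for a shortened
#' sequencing run) before binning. The config is embedded verbatim in every
#' report.
#'
#' @param min_mapq minimum mapping quality.
#' @param fixed_bin fixed bin width in bp.
#' @param variable_bin nominal variable bin width in bp.
#' @param quantile_hi,quantile_lo masking quantiles.
#' @param expected_baseline euploid chromatid count.
#' @param min_segment minimal segment size in bp.
#' @param em_tol,em_max_iter,em_restarts EM settings.
#' @param downsample_n optional downsampling target.
#' @param seed integer seed for every stochastic step.
#' @param scale genome scale divisor: on a 1:`scale` down-scaled genome
#'   (see [toy_layout()]) the three length parameters (`fixed_bin`,
#'   `variable_bin`, `min_segment`) are divided by `scale`, preserving the
#'   bins-per-chromosome geometry of the full-size workflow.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_mapq = 5L, fixed_bin = 100000L,
                            variable_bin = 1000000L, quantile_hi = 0.9985,
                            quantile_lo = 0.1, expected_baseline = 3L,
                            min_segment = 10000000, em_tol = 1e-4,
                            em_max_iter = 500L, em_restarts = 3L,
                            downsample_n = NULL, seed = 1L, scale = 1) {
  if (scale != 1) {
    fixed_bin <- round(fixed_bin / scale)
    variable_bin <- round(variable_bin / scale)
    min_segment <- round(min_segment / scale)
  }
  cfg <- list(
    min_mapq = min_mapq, fixed_bin = fixed_bin, variable_bin = variable_bin,
    quantile_hi = quantile_hi, quantile_lo = quantile_lo,
    expected_baseline = expected_baseline, min_segment = min_segment,
    em_tol = em_tol, em_max_iter = em_max_iter, em_restarts = em_restarts,
    downsample_n = downsample_n, seed = seed
  )
  stopifnot(min_mapq >= 0, fixed_bin > 0, variable_bin >= fixed_bin,
            quantile_hi > quantile_lo, quantile_lo >= 0, quantile_hi <= 1,
            expected_baseline >= 1, min_segment > 0, em_tol > 0,
            em_max_iter >= 1, em_restarts >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the nanopore copy-number pipeline on one sample
#'
#' The full calling workflow against a merged euploid reference:
#' \enumerate{
#'   \item optional downsampling of the sample to `downsample_n` reads;
#'   \item read counting in fixed 100-kb bins for sample and reference;
#'     the quantile mask is computed on each and their intersection (the
#'     reference side acting as a blacklist) removes artifact territory —
#'     a bin must be extreme in both the sample and the euploid reference
#'     to be excluded, so real copy-number signal is not masked;
#'   \item variable-width 1-Mb binning from the masked reference
#'     (mappability correction) and sample counting in those bins;
#'   \item GC correction of the variable-bin counts;
#'   \item zero-inflated NB HMM fit with restarts, anchored at the
#'     3-somy baseline;
#'   \item Viterbi decoding, segment construction, 10-Mb segment
#'     filtering, per-chromosome calls and the sample verdict.
#' }
#' Identical inputs, config and seed give an identical report.
#'
#' @param sample_reads a `read_set` (or path ingested via
#'   [ingest_alignments()] by the caller).
#' @param reference_reads a merged euploid `read_set`.
#' @param layout a `genome_layout`.
#' @param config a `pipeline_config`.
#' @return An `ont_report`: list with `bins` (corrected variable-bin
#'   counts), `model`, `path`, `segments`, `calls`, `classification`,
#'   `qc`, and `config`.
#' @export
run_ont_pipeline <- function(sample_reads, reference_reads, layout,
                             config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(config$downsample_n) && config$downsample_n < nrow(sample_reads)) {
    sample_reads <- stage("downsample",
                          downsample_reads(sample_reads, config$downsample_n,
                                           seed = config$seed))
  }
  fixed <- stage("fixed-bins", make_fixed_bins(layout, config$fixed_bin))
  samp_fixed <- stage("mask", {
    sc <- quantile_mask(count_reads(sample_reads, fixed),
                        hi = config$quantile_hi, lo = config$quantile_lo)
    rc <- quantile_mask(count_reads(reference_reads, fixed),
                        hi = config$quantile_hi, lo = config$quantile_lo)
    # blacklist = reference quantile mask intersected with the sample mask,
    # so genuinely low bins of a loss chromosome are not masked away
    sc$masked <- sc$masked & rc$masked
    sc
  })
  sample_m <- stage("mask", mask_reads(sample_reads, samp_fixed))
  reference_m <- stage("mask", mask_reads(reference_reads, samp_fixed))
  vbins <- stage("variable-bins",
                 make_variable_bins(reference_m, layout, config$variable_bin))
  bins <- stage("count", count_reads(sample_m, vbins, layout))
  bins <- stage("gc-correct", {
    if (all(is.na(bins$gc))) {
      warning("layout carries no GC track; GC correction skipped")
      bins$corrected <- as.numeric(bins$raw)
      bins
    } else {
      gc_correct(bins)
    }
  })
  model <- stage("hmm", fit_cnv_hmm(
    bins, expected_baseline = config$expected_baseline, tol = config$em_tol,
    max_iter = config$em_max_iter, restarts = config$em_restarts,
    seed = config$seed
  ))
  path <- stage("decode", viterbi(model, bins))
  segments <- stage("segments", {
    s <- segments_from_path(path)
    suppressWarnings(filter_segments(s, min_length = config$min_segment))
  })
  calls <- stage("calls", call_chromosomes(segments, layout,
                                           config$expected_baseline))
  classification <- stage("classify", {
    if (nrow(calls) == 23) classify_sample(calls, model$baseline_flag) else {
      cls <- classify_sample_partial(calls, model$baseline_flag)
      cls
    }
  })
  qc <- tibble::tibble(
    n_reads = nrow(sample_reads),
    n_bins = nrow(bins),
    n_masked_fixed_bins = sum(samp_fixed$masked),
    median_bin_count = stats::median(bins$raw),
    baseline_flag = model$baseline_flag
  )
  structure(
    list(bins = bins, model = model, path = path, segments = segments,
         calls = calls, classification = classification, qc = qc,
         config = unclass(config),
         provenance = list(
           sample = read_provenance(sample_reads),
           reference = read_provenance(reference_reads),
           sample_checksum = read_checksum(sample_reads),
           reference_checksum = read_checksum(reference_reads)
         )),
    class = "ont_report"
  )
}

# order-invariant content fingerprint of a read set (no digest dependency)
read_checksum <- function(reads) {
  sprintf("%.0f-%d-%.0f", sum(reads$start) %% 1e15, nrow(reads),
          sum(as.numeric(reads$mapq)))
}

# sample verdict for toy layouts carrying fewer than 23 chromosomes
classify_sample_partial <- function(calls, baseline_flag = FALSE) {
  n_aneu <- sum(calls$classification %in% c("gain", "loss"))
  tibble::tibble(
    verdict = if (n_aneu >= 1) "aneuploid" else "euploid",
    highly_complex = n_aneu > nrow(calls) / 2,
    n_aneuploid_chromosomes = n_aneu,
    n_no_call = sum(calls$classification == "no-call"),
    baseline_flag = baseline_flag
  )
}

#' @export
print.ont_report <- function(x, ...) {
  cat("Pooled polar-body copy-number report\n")
  cat(sprintf("  %d reads, %d variable bins (median count %.0f)\n",
              x$qc$n_reads, x$qc$n_bins, x$qc$median_bin_count))
  print(x$model)
  cat(sprintf("  verdict: %s (%d aneuploid chromosomes%s)\n",
              x$classification$verdict,
              x$classification$n_aneuploid_chromosomes,
              if (x$classification$highly_complex) ", highly complex" else ""))
  if (x$model$baseline_flag) {
    cat("  WARNING: baseline anchoring failed; calls need review\n")
  }
  invisible(x)
}

#' Run the trisomic-baseline aCGH classifier
#'
#' Per-chromosome means, threshold classification against the given
#' baseline, and DLRS QC for both channels.
#'
#' @param profile an `acgh_profile` (or path to a probe TSV).
#' @param baseline euploid chromatid count (default 3).
#' @return An `acgh_report`: list with `means`, `calls`, `classification`,
#'   `thresholds`, `qc` (per-channel DLRS).
#' @export
run_acgh_classifier <- function(profile, baseline = 3L) {
  if (is.character(profile)) profile <- read_acgh_tsv(profile)
  thr <- acgh_thresholds(baseline)
  means <- chromosome_means(profile)
  res <- classify_acgh(means, thr)
  qc <- tibble::tibble(
    dlrs_female = dlr_spread(profile, "female"),
    dlrs_male = dlr_spread(profile, "male"),
    n_probes = nrow(profile)
  )
  structure(
    list(means = means, calls = res$calls, classification = res$classification,
         thresholds = thr, qc = qc),
    class = "acgh_report"
  )
}

#' @export
print.acgh_report <- function(x, ...) {
  print(x$thresholds)
  cat(sprintf("  %d probes, DLRS %.2f (female) / %.2f (male)\n",
              x$qc$n_probes, x$qc$dlrs_female, x$qc$dlrs_male))
  if (!is.null(x$classification)) {
    cat(sprintf("  verdict: %s (%d aneuploid chromosomes)\n",
                x$classification$verdict,
                x$classification$n_aneuploid_chromosomes))
  }
  invisible(x)
}

#' Cross-method concordance between two sets of reports
#'
#' Builds sample- and chromosome-level cross tables from per-sample call
#' tibbles of two methods (method A conventionally aCGH), with optional
#' exclusion of highly complex samples, and computes the concordance
#' statistics.
#'
#' @param calls_a,calls_b long tibbles with columns `sample`, `chrom`,
#'   `classification` (chromosome level) or `sample`, `verdict` (sample
#'   level).
#' @param level `"sample"` or `"chromosome"`.
#' @param exclude sample ids to exclude.
#' @return A list: `table` (`concordance_table`) and `stats`.
#' @export
run_concordance <- function(calls_a, calls_b, level = "chromosome",
                            exclude = character(0)) {
  tab <- cross_table(calls_a, calls_b, level = level, exclude = exclude)
  list(table = tab, stats = concordance_stats(tab))
}

#' Write a pipeline report to JSON
#'
#' Serialises bins, segments, calls, classification, QC, the fitted model
#' and the full configuration.
#'
#' @param report an `ont_report` or `acgh_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- lapply(unclass(report), function(x) {
    if (inherits(x, "cnv_hmm") || inherits(x, "acgh_thresholds")) unclass(x) else x
  })
  obj$version <- as.character(utils::packageVersion("polarploidy"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
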