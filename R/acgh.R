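# Trisomic-baseline aCGH classification. Conventional aCGH software assumes
# a diploid genome; for pooled polar bodies the euploid state is three
# chromatids, so the expected log2 ratios and the gain/loss thresholds must
# be recomputed against a baseline of 3. Profiles carry two control
# channels (sample vs male control and vs female control); autosomes must
# exceed a threshold in BOTH channels, the X chromosome is judged on the
# female channel only.

#' Expected log2 ratio of a copy-number state
#'
#' `log2(copies / baseline)`: e.g. a single-chromatid gain against a diploid
#' baseline is `log2(3/2) = 0.58`, against the pooled polar-body baseline of
#' three chromatids `log2(4/3) = 0.42`, and a chromatid loss
#' `log2(2/3) = -0.58`. Values are exact; round only for display.
#'
#' @param copies copy (chromatid) count, positive.
#' @param baseline baseline chromatid count, positive.
#' @return The log2 ratio (numeric).
#' @export
state_log2 <- function(copies, baseline) {
  if (any(copies <= 0) || any(baseline <= 0)) {
    stop("copies and baseline must be positive")
  }
  log2(copies / baseline)
}

#' Gain/loss log2 thresholds for a given baseline
#'
#' The threshold is placed halfway (in copy number) between euploid and the
#' adjacent aneuploid state: gain at `log2((baseline + 0.5) / baseline)`,
#' loss at `log2((baseline - 0.5) / baseline)`. For the 3-chromatid
#' polar-body baseline these are 0.22 and -0.26 (2-decimal display).
#'
#' @param baseline baseline chromatid count (>= 1).
#' @return A list with `baseline`, `gain` and `loss` (log2 units).
#' @export
acgh_thresholds <- function(baseline = 3L) {
  if (baseline < 1) stop("baseline must be at least 1")
  structure(
    list(
      baseline = as.integer(baseline),
      gain = log2((baseline + 0.5) / baseline),
      loss = log2((baseline - 0.5) / baseline)
    ),
    class = "acgh_thresholds"
  )
}

#' @export
print.acgh_thresholds <- function(x, ...) {
  cat(sprintf("aCGH thresholds (baseline %d chromatids): gain > %.2f, loss < %.2f\n",
              x$baseline, x$gain, x$loss))
  invisible(x)
}

#' Read an aCGH probe profile
#'
#' Probe TSV dialect: `chrom position log2_vs_male log2_vs_female`,
#' tab-separated, sorted or sortable by (chromosome, position).
#'
#' @param path probe TSV path.
#' @return An `acgh_profile` tibble.
#' @export
read_acgh_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "position", "log2_vs_male", "log2_vs_female")
  if (!all(need %in% names(df))) {
    stop("probe TSV must have columns ", paste(need, collapse = ", "))
  }
  as_acgh_profile(df[, need])
}

#' Coerce a probe table to an aCGH profile
#'
#' Sorts by (chromosome, position), normalises chromosome names and checks
#' that log2 values are finite.
#'
#' @param df a data frame with columns `chrom`, `position`,
#'   `log2_vs_male`, `log2_vs_female`.
#' @return An `acgh_profile` tibble.
#' @export
as_acgh_profile <- function(df) {
  out <- tibble::as_tibble(df)
  out$chrom <- normalise_chrom(out$chrom)
  out <- dplyr::arrange(out, factor(chrom, levels = unique(chrom)), position)
  stopifnot(all(is.finite(out$log2_vs_male)), all(is.finite(out$log2_vs_female)))
  class(out) <- unique(c("acgh_profile", class(out)))
  out
}

#' Per-chromosome mean log2 ratios
#'
#' Arithmetic mean of the probe log2 ratios per chromosome and control
#' channel. Chromosomes without probes are omitted with a warning.
#'
#' @param profile an `acgh_profile`.
#' @return A tibble: `chrom`, `mean_vs_male`, `mean_vs_female`, `n_probes`.
#' @export
chromosome_means <- function(profile) {
  if (nrow(profile) == 0) stop("empty probe profile")
  out <- profile |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      mean_vs_male = mean(.data$log2_vs_male),
      mean_vs_female = mean(.data$log2_vs_female),
      n_probes = dplyr::n(),
      .groups = "drop"
    )
  out <- out[order(match(out$chrom, .ANALYSIS_CHROMS)), ]
  missing <- setdiff(.ANALYSIS_CHROMS, out$chrom)
  if (length(missing) > 0) {
    warning("no probes on: ", paste(missing, collapse = ", "), "; omitted")
  }
  out
}

#' Classify chromosomes from aCGH means against trisomic-baseline thresholds
#'
#' An autosome is a gain if its mean log2 ratio exceeds the gain threshold
#' in both control channels, a loss if below the loss threshold in both;
#' otherwise euploid (a single-channel excursion is treated as a
#' control-specific artifact). Chromosome X is judged on the female-control
#' channel only, since a male control carries one X against the sample's
#' maternal chromatids. Comparisons are strict: values exactly at a
#' threshold remain euploid (borderline results are for review, not silent
#' classification).
#'
#' @param means per-chromosome means from [chromosome_means()].
#' @param thresholds an `acgh_thresholds` (default baseline 3).
#' @return A list with `calls` (tibble: `chrom`, `classification`,
#'   `mean_vs_male`, `mean_vs_female`) and `classification` (one-row sample
#'   verdict tibble, as in [classify_sample()]).
#' @export
classify_acgh <- function(means, thresholds = acgh_thresholds(3L)) {
  if (!"chrX" %in% means$chrom || anyNA(means$mean_vs_female[means$chrom == "chrX"])) {
    stop("female-control mean for chromosome X is required")
  }
  cls <- purrr::map_chr(seq_len(nrow(means)), function(i) {
    m <- means[i, ]
    if (m$chrom == "chrX") {
      if (m$mean_vs_female > thresholds$gain) return("gain")
      if (m$mean_vs_female < thresholds$loss) return("loss")
      return("euploid")
    }
    if (m$mean_vs_male > thresholds$gain && m$mean_vs_female > thresholds$gain) {
      return("gain")
    }
    if (m$mean_vs_male < thresholds$loss && m$mean_vs_female < thresholds$loss) {
      return("loss")
    }
    "euploid"
  })
  calls <- tibble::tibble(
    chrom = means$chrom,
    modal_somy = NA_integer_,
    classification = cls,
    mean_vs_male = means$mean_vs_male,
    mean_vs_female = means$mean_vs_female
  )
  sample_cls <- if (nrow(calls) == 23) classify_sample(calls) else NULL
  list(calls = calls, classification = sample_cls)
}

#' Derivative log ratio spread (DLRS)
#'
#' The spread of the differences between genomically adjacent probe log2
#' ratios, the standard aCGH noise/QC metric. Differences never span
#' chromosome boundaries; the spread is the robust IQR-based scale
#' `IQR(d) / (1.349 * sqrt(2))`, which equals the per-probe noise SD for
#' independent Gaussian probe noise. A DLRS below about 0.7 marks a usable
#' single-cell WGA profile.
#'
#' @param profile an `acgh_profile`.
#' @param channel `"male"` or `"female"` control channel.
#' @return The DLRS (non-negative scalar).
#' @export
dlr_spread <- function(profile, channel = c("female", "male")) {
  channel <- match.arg(channel)
  col <- paste0("log2_vs_", channel)
  d <- unlist(lapply(split(profile[[col]], profile$chrom), diff), use.names = FALSE)
  if (length(d) == 0) stop("need at least 2 probes on some chromosome")
  stats::IQR(d, type = 7) / (1.349 * sqrt(2))
}
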