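# From decoded state paths to filtered copy-number segments, per-chromosome
# ploidy calls and the sample-level verdict. The euploid expectation for
# pooled first+second polar bodies is 3 chromatids per chromosome, for the
# X chromosome exactly as for autosomes (all chromatids are maternal).

#' Merge a decoded path into copy-number segments
#'
#' Maximal runs of identical somy become segments. Zero-inflation bins carry
#' no copy-number evidence of their own and are merged into the flanking
#' segment with the greater bp extent (ties go left); a chromosome decoded
#' entirely as zero-inflation yields a single segment with `somy = NA`
#' (a no-call).
#'
#' @param path a `state_path` from [viterbi()].
#' @return A tibble of segments: `chrom`, `start`, `end`, `somy`, `n_bins`.
#' @export
segments_from_path <- function(path) {
  purrr::map_dfr(unique(path$chrom), function(ch) {
    p <- path[path$chrom == ch, ]
    segs <- run_length_segments(p)
    merge_zero_inflation(segs)
  })
}

run_length_segments <- function(p) {
  key <- ifelse(is.na(p$somy), -1L, p$somy)
  r <- rle(key)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  tibble::tibble(
    chrom = p$chrom[1],
    start = p$start[starts_idx],
    end = p$end[ends_idx],
    somy = ifelse(r$values < 0, NA_integer_, r$values),
    n_bins = r$lengths
  )
}

merge_zero_inflation <- function(segs) {
  while (any(is.na(segs$somy)) && nrow(segs) > 1) {
    i <- which(is.na(segs$somy))[1]
    left <- if (i > 1) segs$end[i - 1] - segs$start[i - 1] else -Inf
    right <- if (i < nrow(segs)) segs$end[i + 1] - segs$start[i + 1] else -Inf
    j <- if (left >= right) i - 1 else i + 1   # ties go left
    segs$start[j] <- min(segs$start[j], segs$start[i])
    segs$end[j] <- max(segs$end[j], segs$end[i])
    segs$n_bins[j] <- segs$n_bins[j] + segs$n_bins[i]
    segs <- segs[-i, , drop = FALSE]
    segs <- merge_adjacent(segs)
  }
  segs
}

merge_adjacent <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  keep <- rep(TRUE, nrow(segs))
  for (i in 2:nrow(segs)) {
    prev <- max(which(keep[1:(i - 1)]))
    same <- identical(segs$somy[prev], segs$somy[i]) ||
      (is.na(segs$somy[prev]) && is.na(segs$somy[i]))
    if (same) {
      segs$end[prev] <- segs$end[i]
      segs$n_bins[prev] <- segs$n_bins[prev] + segs$n_bins[i]
      keep[i] <- FALSE
    }
  }
  segs[keep, , drop = FALSE]
}

#' Filter short segments against the minimal-segment-size rule
#'
#' Segments shorter than `min_length` (10 Mb default) are reassigned the
#' somy of the flanking segment with greater bp (terminal short segments
#' take their only neighbour), adjacent same-somy segments are re-merged,
#' and the process iterates until stable — so the result still tiles the
#' decoded territory. Chromosomes shorter than `min_length` are kept as-is
#' with a warning.
#'
#' @param segments a segment tibble from [segments_from_path()].
#' @param min_length minimum segment size in bp (default 10 Mb).
#' @return A filtered segment tibble.
#' @export
filter_segments <- function(segments, min_length = 10000000) {
  purrr::map_dfr(unique(segments$chrom), function(ch) {
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    chrom_len <- max(segs$end) - min(segs$start)
    if (chrom_len < min_length) {
      warning("chromosome ", ch, " is shorter than the minimum segment size; ",
              "segments kept as-is")
      return(segs)
    }
    repeat {
      if (nrow(segs) < 2) break
      widths <- segs$end - segs$start
      short <- which(widths < min_length)
      if (length(short) == 0) break
      i <- short[which.min(widths[short])]
      left <- if (i > 1) segs$end[i - 1] - segs$start[i - 1] else -Inf
      right <- if (i < nrow(segs)) segs$end[i + 1] - segs$start[i + 1] else -Inf
      j <- if (left >= right) i - 1 else i + 1
      segs$somy[i] <- segs$somy[j]
      segs <- merge_adjacent(segs)
    }
    segs
  })
}

#' Per-chromosome ploidy calls from filtered segments
#'
#' The modal somy of a chromosome is the somy holding the greatest total bp;
#' ties break towards the state nearest the expected baseline, then to the
#' lower somy. Classification compares the modal somy with the baseline:
#' equal is euploid, above is a gain, below a loss. Chromosomes with no
#' decoded bins yield a `no-call` (propagated as missing, never as
#' euploid).
#'
#' @param segments a filtered segment tibble.
#' @param layout a `genome_layout` (defines the chromosomes to report).
#' @param expected_baseline euploid chromatid count (default 3).
#' @return A tibble: `chrom`, `modal_somy`, `classification`
#'   (`euploid`/`gain`/`loss`/`no-call`), `fraction_modal`.
#' @export
call_chromosomes <- function(segments, layout, expected_baseline = 3L) {
  purrr::map_dfr(layout$chrom, function(ch) {
    segs <- segments[segments$chrom == ch & !is.na(segments$somy), , drop = FALSE]
    if (nrow(segs) == 0) {
      return(tibble::tibble(chrom = ch, modal_somy = NA_integer_,
                            classification = "no-call", fraction_modal = NA_real_))
    }
    bp <- tapply(segs$end - segs$start, segs$somy, sum)
    somies <- as.integer(names(bp))
    best <- which(bp == max(bp))
    if (length(best) > 1) {
      cand <- somies[best]
      d <- abs(cand - expected_baseline)
      cand <- cand[d == min(d)]
      modal <- min(cand)
    } else {
      modal <- somies[best]
    }
    cls <- if (modal == expected_baseline) "euploid" else if (modal > expected_baseline) "gain" else "loss"
    tibble::tibble(
      chrom = ch, modal_somy = modal, classification = cls,
      fraction_modal = as.numeric(bp[as.character(modal)] / sum(bp))
    )
  })
}

#' Sample-level ploidy classification
#'
#' A sample is aneuploid if at least one chromosome is called gain or loss,
#' and highly complex if more than half of the 23 analysed chromosomes
#' (i.e. 12 or more) are aneuploid — such samples typically reflect a
#' shifted baseline and are excluded from per-chromosome concordance.
#' No-call chromosomes are reported but never counted as euploid.
#'
#' @param calls exactly 23 per-chromosome calls from [call_chromosomes()]
#'   (or the aCGH classifier).
#' @param baseline_flag propagated anchoring flag, if any.
#' @return A one-row tibble: `verdict`, `highly_complex`,
#'   `n_aneuploid_chromosomes`, `n_no_call`, `baseline_flag`.
#' @export
classify_sample <- function(calls, baseline_flag = FALSE) {
  if (nrow(calls) != 23) {
    stop("expected 23 chromosome calls, got ", nrow(calls))
  }
  n_aneu <- sum(calls$classification %in% c("gain", "loss"))
  tibble::tibble(
    verdict = if (n_aneu >= 1) "aneuploid" else "euploid",
    highly_complex = n_aneu > 23 / 2,
    n_aneuploid_chromosomes = n_aneu,
    n_no_call = sum(calls$classification == "no-call"),
    baseline_flag = baseline_flag
  )
}

#' Write segments as BED
#'
#' BED5 with `name` = somy and `score` = `fraction_modal * 1000` style
#' confidence (here the bin count), 0-based half-open as BED requires.
#'
#' @param segments a segment tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- tibble::tibble(
    chrom = segments$chrom,
    start = as.integer(segments$start),
    end = as.integer(segments$end),
    name = paste0(segments$somy, "-somy"),
    score = pmin(as.integer(segments$n_bins), 1000L)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
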