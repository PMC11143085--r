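# Bin construction and read counting. Coordinates are 0-based half-open
# everywhere internally; BED on output.

new_bin_set <- function(df, scheme, nominal_width) {
  out <- tibble::as_tibble(df)
  attr(out, "scheme") <- scheme
  attr(out, "nominal_width") <- nominal_width
  class(out) <- unique(c("bin_set", class(out)))
  out
}

#' Fixed-width genomic bins
#'
#' Tiles each chromosome with `ceiling(length / width)` bins of the given
#' width; the last bin is truncated at the chromosome end.
#'
#' @param layout a `genome_layout`.
#' @param width bin width in bp (default 100 kb).
#' @return A `bin_set` tibble (`chrom`, `start`, `end`).
#' @export
make_fixed_bins <- function(layout, width = 100000L) {
  if (width <= 0) stop("bin width must be positive")
  if (width > min(layout$length)) {
    stop("bin width ", width, " exceeds the shortest chromosome (",
         min(layout$length), " bp)")
  }
  bins <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + width, len))
  })
  new_bin_set(bins, scheme = "fixed", nominal_width = width)
}

#' Count reads per bin
#'
#' Assigns each read to the unique bin whose half-open interval
#' `[start, end)` contains the read start. Reads past the last bin end of a
#' chromosome (only possible with user-supplied bin sets) are dropped and
#' tallied. GC per bin is attached as the length-weighted mean of the
#' layout's GC windows overlapping the bin, when a GC track is present.
#'
#' @param reads a `read_set`.
#' @param binset a `bin_set`.
#' @param layout the shared `genome_layout` (for GC annotation); optional.
#' @return A `binned_counts` tibble: `chrom`, `start`, `end`, `raw`,
#'   `gc`, `masked` (all `FALSE` initially), `corrected` (`NA` until
#'   [gc_correct()]).
#' @export
count_reads <- function(reads, binset, layout = NULL) {
  counts <- integer(nrow(binset))
  dropped <- 0L
  pos_by_chrom <- split(reads$start, reads$chrom)
  for (ch in unique(binset$chrom)) {
    bi <- which(binset$chrom == ch)
    starts <- binset$start[bi]
    last_end <- binset$end[bi[length(bi)]]
    pos <- pos_by_chrom[[ch]]
    if (is.null(pos)) pos <- numeric(0)
    pos_in <- pos[pos >= starts[1] & pos < last_end]
    dropped <- dropped + (length(pos) - length(pos_in))
    if (length(pos_in)) {
      idx <- findInterval(pos_in, starts)
      counts[bi] <- counts[bi] + tabulate(idx, nbins = length(bi))
    }
  }
  out <- tibble::as_tibble(binset)
  out$raw <- counts
  out$gc <- if (!is.null(layout) && !is.null(layout_gc(layout))) {
    bin_gc(binset, layout_gc(layout))
  } else {
    NA_real_
  }
  out$masked <- FALSE
  out$corrected <- NA_real_
  attr(out, "scheme") <- attr(binset, "scheme")
  attr(out, "nominal_width") <- attr(binset, "nominal_width")
  attr(out, "n_dropped_reads") <- dropped
  class(out) <- unique(c("binned_counts", class(out)))
  out
}

# Length-weighted mean GC of the gc-track windows overlapping each bin.
# Windows are sorted and non-overlapping, so the weighted integral of GC up
# to any coordinate is piecewise linear and one cumulative sum serves every
# bin boundary.
bin_gc <- function(binset, gc_track) {
  out <- rep(NA_real_, nrow(binset))
  for (ch in unique(binset$chrom)) {
    bi <- which(binset$chrom == ch)
    g <- gc_track[gc_track$chrom == ch, ]
    if (nrow(g) == 0) next
    gcv <- ifelse(is.na(g$gc), 0, g$gc)
    wv <- ifelse(is.na(g$gc), 0, 1)          # NA-gc windows carry no weight
    cum_gc <- c(0, cumsum(gcv * (g$end - g$start)))
    cum_w <- c(0, cumsum(wv * (g$end - g$start)))
    integral <- function(x, cum, val) {
      i <- findInterval(x, g$start)
      i <- pmax(pmin(i, nrow(g)), 1)
      cum[i] + val[i] * pmin(pmax(x - g$start[i], 0), g$end[i] - g$start[i])
    }
    num <- integral(binset$end[bi], cum_gc, gcv) -
      integral(binset$start[bi], cum_gc, gcv)
    den <- integral(binset$end[bi], cum_w, wv) -
      integral(binset$start[bi], cum_w, wv)
    out[bi] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Quantile-based outlier masking
#'
#' Masks bins whose raw count lies strictly above the `hi` quantile or
#' strictly below the `lo` quantile of the genome-wide raw-count
#' distribution of this sample (defaults 0.9985 and 0.1). Quantiles use the
#' linear-interpolation empirical definition (type 7). Masking removes
#' WGA/mappability artifact bins before model fitting.
#'
#' @param counts a `binned_counts` tibble from fixed bins, genome-wide.
#' @param hi,lo upper and lower mask quantiles, `hi > lo`.
#' @return The input with `masked` updated (existing masks are retained).
#' @export
quantile_mask <- function(counts, hi = 0.9985, lo = 0.1) {
  if (hi <= lo) stop("hi quantile must exceed lo quantile")
  q <- stats::quantile(counts$raw, c(lo, hi), type = 7, names = FALSE)
  counts$masked <- counts$masked | counts$raw > q[2] | counts$raw < q[1]
  counts
}

#' Drop reads falling in masked bins
#'
#' Used to build variable-width bins from unmasked territory only: the
#' quantile mask is computed on fixed bins, then sample and reference reads
#' inside masked bins are removed before re-binning.
#'
#' @param reads a `read_set`.
#' @param masked_counts a `binned_counts` with the `masked` column set.
#' @return A filtered `read_set`.
#' @export
mask_reads <- function(reads, masked_counts) {
  bad <- masked_counts[masked_counts$masked, c("chrom", "start", "end")]
  if (nrow(bad) == 0) return(reads)
  keep <- rep(TRUE, nrow(reads))
  for (ch in unique(bad$chrom)) {
    b <- bad[bad$chrom == ch, ]
    ri <- which(reads$chrom == ch)
    if (!length(ri)) next
    # masked bins are sorted, non-overlapping intervals: one findInterval
    b <- b[order(b$start), ]
    pos <- reads$start[ri]
    j <- findInterval(pos, b$start)
    inbad <- j >= 1 & pos < b$end[pmax(j, 1)]
    keep[ri[inbad]] <- FALSE
  }
  prov <- c(read_provenance(reads), list(n_masked_out = sum(!keep)))
  new_read_set(reads[keep, , drop = FALSE], provenance = prov)
}

#' Variable-width bins from a euploid reference
#'
#' Mappability correction by re-binning: each bin holds (approximately) the
#' same number of reads from a merged euploid reference, so regions of low
#' mappability become genomically wider bins. The per-bin read target T is
#' the median fixed-bin reference count at the nominal width (1 Mb default);
#' boundaries are placed at midpoints between the T-th and (T+1)-th
#' reference read; a terminal bin holding fewer than T/2 reference reads is
#' merged into its neighbour.
#'
#' @param reference a merged euploid `read_set`.
#' @param layout a `genome_layout`.
#' @param nominal_width nominal bin width in bp (default 1 Mb).
#' @return A `bin_set` with attribute `target_reads` = T.
#' @export
make_variable_bins <- function(reference, layout, nominal_width = 1000000L) {
  fixed <- make_fixed_bins(layout, width = nominal_width)
  ref_counts <- count_reads(reference, fixed)
  target <- max(1L, round(stats::median(ref_counts$raw)))
  ref_by_chrom <- split(reference$start, reference$chrom)
  bins <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    pos <- sort(ref_by_chrom[[ch]])
    if (length(pos) == 0) stop("reference has zero reads on ", ch)
    cut_idx <- if (length(pos) - 1 >= target) {
      seq(target, length(pos) - 1, by = target)
    } else {
      integer(0)
    }
    boundaries <- if (length(cut_idx)) {
      floor((pos[cut_idx] + pos[cut_idx + 1]) / 2)
    } else {
      numeric(0)
    }
    boundaries <- unique(pmin(pmax(boundaries, 1), len - 1))
    starts <- c(0, boundaries)
    ends <- c(boundaries, len)
    # merge a sparse terminal bin (< target/2 reference reads) leftwards
    if (length(starts) > 1) {
      n_last <- sum(pos >= starts[length(starts)])
      if (n_last < target / 2) {
        starts <- starts[-length(starts)]
        ends <- ends[-(length(ends) - 1)]
      }
    }
    tibble::tibble(chrom = ch, start = starts, end = ends)
  })
  out <- new_bin_set(bins, scheme = "variable", nominal_width = nominal_width)
  attr(out, "target_reads") <- target
  out
}

#' GC-bias correction of binned counts
#'
#' Fits a second-degree polynomial of raw count on GC fraction over unmasked
#' bins and rescales each bin by `mean(fitted) / fitted(gc)`, so the
#' corrected counts are flat in GC while preserving the unmasked mean
#' exactly. Fitted values that are non-positive are clamped to the 1st
#' percentile of the positive fitted values (with a warning) so corrected
#' counts stay non-negative and finite.
#'
#' @param counts a `binned_counts` with per-bin `gc`; at least 50 unmasked
#'   bins are required for a stable fit.
#' @return The input with `corrected` filled for unmasked bins.
#' @export
gc_correct <- function(counts) {
  un <- !counts$masked
  if (sum(un) < 50) stop("need at least 50 unmasked bins for GC correction (have ",
                         sum(un), ")")
  if (anyNA(counts$gc[un])) stop("GC fraction missing for some unmasked bins")
  gc <- counts$gc[un]
  raw <- counts$raw[un]
  if (stats::sd(gc) < 1e-9) {
    counts$corrected[un] <- raw
    return(counts)
  }
  fit <- stats::lm(raw ~ stats::poly(gc, 2, raw = TRUE))
  fitted <- as.numeric(stats::predict(fit))
  if (any(fitted <= 0)) {
    clamp <- stats::quantile(fitted[fitted > 0], 0.01, names = FALSE)
    warning("non-positive GC fit values clamped for ", sum(fitted <= 0), " bins")
    fitted[fitted <= 0] <- clamp
  }
  corrected <- raw * mean(fitted) / fitted
  # enforce exact mean preservation over unmasked bins
  corrected <- corrected * mean(raw) / mean(corrected)
  counts$corrected[un] <- corrected
  counts
}

#' Round-trip binned counts to a BED-like TSV
#'
#' Columns `chrom start end raw corrected masked gc`, 0-based half-open.
#'
#' @param counts a `binned_counts`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins_tsv <- function(counts, path) {
  readr::write_tsv(
    tibble::as_tibble(counts)[, c("chrom", "start", "end", "raw", "corrected",
                                  "masked", "gc")],
    path
  )
  invisible(path)
}

#' @rdname write_bins_tsv
#' @param scheme bin scheme recorded on the restored object.
#' @export
read_bins_tsv <- function(path, scheme = "variable") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "scheme") <- scheme
  class(out) <- unique(c("binned_counts", class(out)))
  out
}
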