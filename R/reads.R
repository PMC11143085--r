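# Aligned-read ingestion with MAPQ filtering, and seeded downsampling.
# A read set is a tibble (chrom, start, mapq), one row per primary aligned
# read, start being the 0-based leftmost mapped position. Read length is
# irrelevant at 1-Mb bins (nanopore low-pass reads average ~0.5 kb), so a
# read is represented by its start only. Duplicates are deliberately not
# removed.

new_read_set <- function(df, provenance = list(), seed = NULL) {
  out <- tibble::as_tibble(df[, c("chrom", "start", "mapq")])
  attr(out, "provenance") <- provenance
  attr(out, "seed") <- seed
  class(out) <- unique(c("read_set", class(out)))
  out
}

read_provenance <- function(reads) attr(reads, "provenance")

#' Ingest aligned reads with mapping-quality filtering
#'
#' Reads a BAM/SAM file (via Rsamtools) or the plain-text read TSV dialect
#' (`chrom  start  mapq`, tab-separated, 0-based starts) and applies the
#' ingestion filters: unmapped, secondary and supplementary records are
#' excluded, records with MAPQ below `min_mapq` (default 5) are excluded, and
#' reads on chromosomes outside the layout (chrY, decoys, alt contigs) are
#' dropped and tallied in the provenance. BAM/SAM positions are converted to
#' 0-based starts.
#'
#' @param path alignment file (`.bam`/`.sam`) or read TSV.
#' @param layout a `genome_layout`.
#' @param min_mapq minimum mapping quality retained (default 5).
#' @return A `read_set` tibble (`chrom`, `start`, `mapq`) with a
#'   `provenance` attribute recording the source and per-filter tallies.
#' @export
ingest_alignments <- function(path, layout, min_mapq = 5L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.(bam|sam)$", path, ignore.case = TRUE)) {
    df <- read_sam_records(path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chrom", "start", "mapq")
    if (!all(need %in% names(df))) {
      stop("read TSV must have columns chrom, start, mapq: ", path)
    }
    df <- df[, need]
  }
  n_input <- nrow(df)
  df$chrom <- normalise_chrom(df$chrom)
  keep_mapq <- !is.na(df$mapq) & df$mapq >= min_mapq
  df <- df[keep_mapq, , drop = FALSE]
  n_lowq <- n_input - nrow(df)
  on_layout <- df$chrom %in% layout$chrom
  n_off <- sum(!on_layout)
  df <- df[on_layout, , drop = FALSE]
  len <- layout$length[match(df$chrom, layout$chrom)]
  df <- df[df$start >= 0 & df$start < len, , drop = FALSE]
  if (nrow(df) == 0) stop("zero surviving reads after filtering: ", path)
  new_read_set(
    df,
    provenance = list(
      source = path, min_mapq = min_mapq, n_input = n_input,
      n_low_mapq = n_lowq, n_off_layout = n_off, n_kept = nrow(df)
    )
  )
}

# Primary mapped records from SAM/BAM: flag-filters out unmapped (0x4),
# secondary (0x100) and supplementary (0x800) alignments.
read_sam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM input")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".bam")
    on.exit(unlink(paste0(tmp, c("", ".bai"))), add = TRUE)
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", tmp),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  ok <- !is.na(rec$pos)
  tibble::tibble(
    chrom = as.character(rec$rname)[ok],
    start = rec$pos[ok] - 1,        # SAM is 1-based; internal coords 0-based
    mapq = as.integer(rec$mapq)[ok]
  )
}

#' Downsample a read set without replacement
#'
#' Uniform seeded subsampling, emulating downsampling of a sequencing run to
#' a target read number (e.g. 300,000 reads for a shortened run). The same
#' seed always yields the same subset; the RNG state of the session is left
#' untouched.
#'
#' @param reads a `read_set`.
#' @param n target number of reads; must not exceed `nrow(reads)`.
#' @param seed integer seed.
#' @return A `read_set` of exactly `n` rows (a subset of the input).
#' @export
downsample_reads <- function(reads, n, seed) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(reads)) {
    stop("cannot downsample to ", n, " reads: only ", nrow(reads), " available")
  }
  idx <- withr::with_seed(as.integer(seed), sample.int(nrow(reads), n))
  prov <- c(read_provenance(reads), list(downsampled_to = n, downsample_seed = seed))
  new_read_set(reads[sort(idx), , drop = FALSE], provenance = prov, seed = seed)
}

#' Write / read the plain-text read TSV dialect
#'
#' Columns `chrom`, `start` (0-based), `mapq`, tab-separated — a fixture
#' format so tests and small exchanges never need a BAM encoder.
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_tsv <- function(reads, path) {
  readr::write_tsv(tibble::as_tibble(reads)[, c("chrom", "start", "mapq")], path)
  invisible(path)
}
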