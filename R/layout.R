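# Genome layouts: the 23 analysed chromosomes (22 autosomes + X), their
# lengths, and an optional per-window GC track. Y is excluded throughout:
# polar bodies are maternal.

.ANALYSIS_CHROMS <- c(paste0("chr", 1:22), "chrX")

# GRCh38 primary-assembly chromosome lengths (bp)
.GRCH38_LENGTHS <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895
)

new_genome_layout <- function(chrom, length, gc = NULL, gc_window = NA_integer_) {
  out <- tibble::tibble(chrom = as.character(chrom), length = as.numeric(length))
  stopifnot(!anyDuplicated(out$chrom), all(out$length > 0))
  attr(out, "gc") <- gc
  attr(out, "gc_window") <- gc_window
  class(out) <- c("genome_layout", class(out))
  out
}

#' Genome layout constructors
#'
#' A genome layout is a tibble with one row per analysed chromosome
#' (`chrom`, `length`) and, optionally, a per-window GC track stored in
#' `attr(, "gc")` as a tibble (`chrom`, `start`, `end`, `gc`). The analysis
#' set is fixed at the 22 autosomes plus X; chromosome Y is never analysed
#' because pooled polar bodies carry only maternal chromatids.
#'
#' `grch38_layout()` returns the GRCh38 primary-assembly lengths.
#' `toy_layout()` returns the same 23 chromosomes scaled down (default 1:30,
#' about 100 Mb total) so million-read simulations run in seconds; both attach
#' a deterministic smooth synthetic GC track (around 0.41 mean GC, labelled
#' synthetic) so GC correction is exercised end to end.
#'
#' @param scale divisor applied to GRCh38 lengths for the toy genome.
#' @param gc_window window size in bp for the synthetic GC track.
#' @return A `genome_layout` tibble.
#' @examples
#' toy_layout()
#' @export
grch38_layout <- function(gc_window = 100000L) {
  lay <- new_genome_layout(names(.GRCH38_LENGTHS), unname(.GRCH38_LENGTHS))
  attach_synthetic_gc(lay, gc_window)
}

#' @rdname grch38_layout
#' @export
toy_layout <- function(scale = 30, gc_window = round(100000 / scale)) {
  len <- pmax(round(.GRCH38_LENGTHS / scale), 10 * gc_window)
  lay <- new_genome_layout(names(.GRCH38_LENGTHS), unname(len))
  attach_synthetic_gc(lay, gc_window)
}

#' Attach a synthetic GC track to a layout
#'
#' Builds a deterministic, smoothly varying GC fraction per window
#' (superposed long- and short-period waves around 0.41), emulating the
#' isochore-scale GC structure of a real genome without requiring sequence.
#' The track is synthetic: it carries no real GRCh38 composition.
#'
#' @param layout a `genome_layout`.
#' @param gc_window window size in bp.
#' @return The layout with a `gc` attribute tibble.
#' @export
attach_synthetic_gc <- function(layout, gc_window = 100000L) {
  gc <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    starts <- seq(0, len - 1, by = gc_window)
    ends <- pmin(starts + gc_window, len)
    mid <- (starts + ends) / 2
    # chromosome-specific phase so chromosomes differ but remain deterministic
    ph <- sum(utf8ToInt(ch))
    gcv <- 0.41 + 0.06 * sin(2 * pi * mid / (37 * gc_window) + ph) +
      0.03 * sin(2 * pi * mid / (7.3 * gc_window) + 2 * ph)
    # shared mappability landscape: mostly ~1, with recurrent low-mappability
    # troughs (emulating repeat-rich territory) common to every sample
    mapp <- 0.75 + 0.25 * sin(2 * pi * mid / (23 * gc_window) + 3 * ph)
    mapp <- pmax(mapp, 0.02)^2
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   gc = pmin(pmax(gcv, 0.2), 0.65), mappability = mapp)
  })
  attr(layout, "gc") <- gc
  attr(layout, "gc_window") <- as.integer(gc_window)
  layout
}

#' Load a genome layout from FASTA or a length table
#'
#' From FASTA, the per-window GC fraction is computed as (G+C)/(A+C+G+T)
#' within each window, so N bases are excluded from the denominator. From a
#' two-column TSV (`chrom`, `length`) no GC track is available (attach one
#' with [attach_synthetic_gc()] or supply per-bin GC later). The layout is
#' restricted to chr1..chr22 and chrX; bare names ("1", "X") are accepted and
#' normalised to the "chr" prefix. All 23 analysis chromosomes must be
#' present.
#'
#' @param source path to a FASTA file or a tab-separated length table.
#' @param gc_window GC window size in bp (FASTA input).
#' @return A `genome_layout` tibble.
#' @export
load_genome_layout <- function(source, gc_window = 100000L) {
  if (!file.exists(source)) stop("layout source not found: ", source)
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", source, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("Biostrings is required to read FASTA layouts")
    }
    stopifnot(gc_window > 0)
    seqs <- Biostrings::readDNAStringSet(source)
    if (length(seqs) == 0) stop("empty FASTA: ", source)
    names(seqs) <- normalise_chrom(sub("\\s.*$", "", names(seqs)))
    seqs <- seqs[names(seqs) %in% .ANALYSIS_CHROMS]
    present <- intersect(.ANALYSIS_CHROMS, names(seqs))
    check_analysis_set(present)
    seqs <- seqs[present]
    gc <- purrr::map_dfr(present, function(ch) {
      s <- seqs[[ch]]
      len <- length(s)
      starts <- seq(0, len - 1, by = gc_window)
      ends <- pmin(starts + gc_window, len)
      v <- Biostrings::Views(s, start = starts + 1, end = ends)
      freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
      denom <- rowSums(freq)
      tibble::tibble(
        chrom = ch, start = starts, end = ends,
        gc = ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
      )
    })
    lay <- new_genome_layout(present, Biostrings::width(seqs), gc, as.integer(gc_window))
    return(lay)
  }
  tab <- readr::read_tsv(source, show_col_types = FALSE)
  names(tab)[1:2] <- c("chrom", "length")
  tab$chrom <- normalise_chrom(tab$chrom)
  tab <- tab[tab$chrom %in% .ANALYSIS_CHROMS, ]
  check_analysis_set(tab$chrom)
  ord <- match(.ANALYSIS_CHROMS, tab$chrom)
  new_genome_layout(tab$chrom[ord], tab$length[ord])
}

normalise_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# X must always be present (its trisomic-baseline call is part of the assay);
# toy layouts may carry a subset of autosomes.
check_analysis_set <- function(present) {
  if (length(present) == 0) stop("no analysis chromosomes (chr1..chr22, chrX) found")
  if (!"chrX" %in% present) stop("chromosome X absent from layout")
  invisible(TRUE)
}

layout_gc <- function(layout) attr(layout, "gc", exact = TRUE)

chrom_order <- function(layout) layout$chrom
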