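# Shared fixtures, built in code. Expensive simulated objects are memoised
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_toy_layout <- function() memo("toy_layout", toy_layout())

# merged euploid reference on the toy genome, shared across pipeline tests
fixture_toy_reference <- function() {
  memo("toy_ref", simulate_reference(fixture_toy_layout(), n_samples = 6,
                                     reads_each = 1000000L, seed = 99))
}

# layout with a flat mappability landscape, for tests whose expectation
# assumes uniform coverage
flat_layout <- function(...) {
  lay <- toy_layout(...)
  gc <- attr(lay, "gc")
  gc$mappability <- 1
  attr(lay, "gc") <- gc
  lay
}

# two-chromosome mini layout (X is always required)
mini_layout <- function(len1 = 10e6, lenX = 10e6, gc_window = 100000L) {
  lay <- polarploidy:::new_genome_layout(c("chr1", "chrX"), c(len1, lenX))
  attach_synthetic_gc(lay, gc_window)
}

# hand-rolled SAM writer for ingestion tests
write_toy_sam <- function(path, records,
                          chroms = c(chr1 = 10000000, chrX = 10000000,
                                     chrY = 1000000)) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), as.integer(chroms))
  )
  body <- vapply(records, function(r) {
    flag <- if (!is.null(r$flag)) r$flag else 0L
    rname <- if (!is.null(r$chrom)) r$chrom else "*"
    pos <- if (!is.null(r$pos)) r$pos else 0L   # SAM 1-based
    cigar <- if (flag == 4L) "*" else "10M"
    paste(r$name, flag, rname, pos, r$mapq, cigar, "*", 0, 0,
          "ACGTACGTAC", "~~~~~~~~~~", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# exhaustive-path Viterbi oracle: argmax over all K^T state paths
brute_force_viterbi <- function(logE, logA, logPi) {
  T_ <- nrow(logE)
  K <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- logPi[paths[, 1]] + logE[cbind(1, paths[, 1])]
  for (t in 2:T_) {
    lp <- lp + logA[cbind(paths[, t - 1], paths[, t])] +
      logE[cbind(t, paths[, t])]
  }
  as.integer(paths[which.max(lp), ])
}

# log-probability of one path under the model (for random-path comparisons)
path_logprob <- function(path, logE, logA, logPi) {
  lp <- logPi[path[1]] + logE[1, path[1]]
  for (t in seq_along(path)[-1]) {
    lp <- lp + logA[path[t - 1], path[t]] + logE[t, path[t]]
  }
  lp
}

# binned_counts built directly from a count vector (one chromosome unless
# chrom given), for HMM unit tests that bypass read counting
counts_fixture <- function(x, width = 1000000, chrom = "chr1", gc = NULL) {
  n <- length(x)
  out <- tibble::tibble(
    chrom = rep(chrom, length.out = n),
    start = (seq_len(n) - 1) * width,
    end = seq_len(n) * width,
    raw = as.numeric(x),
    gc = if (is.null(gc)) rep(0.4, n) else gc,
    masked = FALSE,
    corrected = as.numeric(x)
  )
  class(out) <- unique(c("binned_counts", class(out)))
  out
}

# state_path built from a somy vector (NA = zero-inflation bin)
path_fixture <- function(somy, width = 1000000, chrom = "chr1") {
  n <- length(somy)
  tibble::tibble(
    chrom = rep(chrom, length.out = n),
    start = (seq_len(n) - 1) * width,
    end = seq_len(n) * width,
    state = ifelse(is.na(somy), "zero-inflation", paste0(somy, "-somy")),
    somy = as.integer(somy)
  )
}

seg_fixture <- function(chrom, start, end, somy) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 somy = as.integer(somy),
                 n_bins = as.integer((end - start) / 1e6))
}
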