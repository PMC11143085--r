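# Cross-method concordance: cross tables of two call sets at sample or
# chromosome level, concordance fractions, and gain/loss tallies.

new_concordance_table <- function(counts, level, excluded = character(0)) {
  structure(
    list(counts = counts, level = level, excluded_samples = excluded),
    class = "concordance_table"
  )
}

#' Cross-tabulate two methods' ploidy calls
#'
#' Inner-joins the two call sets on their shared units (sample ids at the
#' sample level; sample id x chromosome at the chromosome level) and counts
#' every class pair. Sample-level classes are `euploid`/`aneuploid`;
#' chromosome-level classes are `euploid`/`gain`/`loss`, where every somy
#' below the baseline (at least one chromatid lost) maps to `loss`. Units
#' missing from either set, `no-call` entries, and ids on `exclude` are left
#' out and listed.
#'
#' @param calls_a,calls_b tibbles of calls. Sample level: columns `sample`,
#'   `verdict`. Chromosome level: `sample`, `chrom`, `classification`.
#'   Method A is conventionally the aCGH side (rows).
#' @param level `"sample"` or `"chromosome"`.
#' @param exclude sample ids to drop (e.g. highly complex samples).
#' @return A `concordance_table`: counts matrix (A rows x B columns), level,
#'   excluded units.
#' @export
cross_table <- function(calls_a, calls_b, level = c("sample", "chromosome"),
                        exclude = character(0)) {
  level <- match.arg(level)
  if (level == "sample") {
    classes <- c("euploid", "aneuploid")
    a <- calls_a[, c("sample", "verdict")]
    b <- calls_b[, c("sample", "verdict")]
    names(a)[2] <- "class_a"
    names(b)[2] <- "class_b"
    keys <- "sample"
  } else {
    classes <- c("euploid", "gain", "loss")
    a <- calls_a[, c("sample", "chrom", "classification")]
    b <- calls_b[, c("sample", "chrom", "classification")]
    names(a)[3] <- "class_a"
    names(b)[3] <- "class_b"
    keys <- c("sample", "chrom")
  }
  a <- a[!a$sample %in% exclude, ]
  b <- b[!b$sample %in% exclude, ]
  joined <- dplyr::inner_join(a, b, by = keys)
  joined <- joined[joined$class_a != "no-call" & joined$class_b != "no-call", ]
  if (nrow(joined) == 0) stop("no shared units between the two call sets")
  counts <- table(
    factor(joined$class_a, levels = classes),
    factor(joined$class_b, levels = classes)
  )
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(method_a = classes, method_b = classes))
  dropped <- union(setdiff(unique(a$sample), unique(joined$sample)),
                   setdiff(unique(b$sample), unique(joined$sample)))
  new_concordance_table(counts, level, excluded = union(exclude, dropped))
}

#' Build a concordance table from a counts matrix
#'
#' For cross tables given directly as counts (e.g. published tables), with
#' identically ordered row (method A) and column (method B) classes.
#'
#' @param counts a square integer matrix with dimnames.
#' @param level `"sample"` or `"chromosome"`.
#' @return A `concordance_table`.
#' @export
as_concordance_table <- function(counts, level = "chromosome") {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            identical(rownames(counts), colnames(counts)))
  new_concordance_table(counts, level)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance cross table (", x$level, " level, method A rows)\n", sep = "")
  print(x$counts)
  s <- concordance_stats(x)
  cat(sprintf("overall concordance: %.1f%% (%d/%d)\n", 100 * s$overall,
              sum(diag(x$counts)), sum(x$counts)))
  invisible(x)
}

#' Concordance statistics of a cross table
#'
#' Overall concordance is the diagonal share of all compared units;
#' per-class concordance conditions on the method-A row (the share of
#' method-A calls of that class that method B agrees with). Classes with an
#' empty method-A row are reported as `NA`.
#'
#' @param table a `concordance_table`.
#' @return A list: `overall` fraction, `per_class` named numeric, `n` units.
#' @export
concordance_stats <- function(table) {
  m <- table$counts
  total <- sum(m)
  if (total == 0) stop("empty concordance table")
  row_tot <- rowSums(m)
  per_class <- ifelse(row_tot > 0, diag(m) / row_tot, NA_real_)
  names(per_class) <- rownames(m)
  list(overall = sum(diag(m)) / total, per_class = per_class, n = total)
}

#' Tally gains and losses across a cohort
#'
#' Absolute numbers of per-chromosome gain and loss calls, overall and per
#' chromosome.
#'
#' @param calls a tibble with columns `chrom` and `classification`
#'   (optionally spanning many samples).
#' @return A list: `gains`, `losses`, `per_chromosome` tibble.
#' @export
gain_loss_tally <- function(calls) {
  per <- calls |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      gains = sum(.data$classification == "gain"),
      losses = sum(.data$classification == "loss"),
      .groups = "drop"
    )
  per <- per[order(match(per$chrom, .ANALYSIS_CHROMS)), ]
  list(gains = sum(per$gains), losses = sum(per$losses), per_chromosome = per)
}

#' Tidy a concordance table
#'
#' One row per cell of the cross table, with a concordant flag.
#'
#' @param x a `concordance_table`.
#' @param ... unused.
#' @return A tibble: `method_a`, `method_b`, `n`, `concordant`.
#' @export
tidy.concordance_table <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n", stringsAsFactors = FALSE)
  tibble::tibble(
    method_a = df$method_a, method_b = df$method_b, n = as.integer(df$n),
    concordant = df$method_a == df$method_b
  )
}

#' @rdname tidy.concordance_table
#' @export
glance.concordance_table <- function(x, ...) {
  s <- concordance_stats(x)
  tibble::tibble(
    level = x$level, n = s$n, overall = s$overall,
    n_excluded = length(x$excluded_samples)
  )
}

#' Published validation-cohort cross tables
#'
#' The cross tables reported for the 102-sample pooled polar-body validation
#' cohort that compared this trisomic-baseline nanopore caller with the
#' established aCGH classification (method A = aCGH rows, method B =
#' nanopore columns):
#' \describe{
#'   \item{`sample`}{102 samples, euploid/aneuploid verdicts: 36 + 62
#'     concordant, 4 samples euploid by aCGH but aneuploid by nanopore.}
#'   \item{`chromosome`}{2346 chromosomes (102 x 23), euploid/gain/loss.}
#'   \item{`chromosome_filtered`}{2162 chromosomes after excluding the 8
#'     highly complex samples (more than half of chromosomes aneuploid by
#'     nanopore).}
#' }
#' The diagonals, totals, row totals and the dominant off-diagonal cells are
#' as published; in the two chromosome-level tables the few remaining cells
#' not printed individually are solved from the published marginals (this
#' affects no reported concordance statistic).
#'
#' @return A named list of three `concordance_table` objects.
#' @export
cohort_cross_tables <- function() {
  classes2 <- c("euploid", "aneuploid")
  sample_tab <- matrix(c(36L, 0L, 4L, 62L), 2, 2,
                       dimnames = list(method_a = classes2, method_b = classes2))
  classes3 <- c("euploid", "gain", "loss")
  chrom_tab <- matrix(
    c(
      2032L, 123L, 13L,  # aCGH euploid row: nanopore euploid / gain / loss
      3L, 47L, 0L,       # aCGH gain row
      38L, 0L, 90L       # aCGH loss row
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(method_a = classes3, method_b = classes3)
  )
  chrom_filt <- matrix(
    c(
      1997L, 21L, 13L,
      3L, 45L, 0L,
      12L, 0L, 71L
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(method_a = classes3, method_b = classes3)
  )
  list(
    sample = new_concordance_table(sample_tab, "sample"),
    chromosome = new_concordance_table(chrom_tab, "chromosome"),
    chromosome_filtered = new_concordance_table(chrom_filt, "chromosome")
  )
}
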