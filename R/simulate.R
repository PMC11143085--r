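# Seeded generators for karyotypes, WGA-like read coverage and aCGH probe
# profiles, with exact ground-truth bookkeeping. The simulator emulates the
# data regime of low-pass nanopore sequencing of WGA-amplified pooled polar
# bodies: ~1 M reads per sample, strongly over-dispersed and zero-inflated
# bin counts with GC bias and bin-scale amplification unevenness, and aCGH
# profiles at a derivative-log-ratio spread around 0.57.

#' Specify a karyotype in chromatid counts
#'
#' A karyotype is the per-chromosome chromatid count (baseline 3 for pooled
#' first+second polar bodies; 0-4 allowed) plus optional segmental events
#' that add or remove chromatids over an interval. The resulting copy
#' number must stay within 0-4 at every position.
#'
#' @param layout a `genome_layout`.
#' @param baseline euploid chromatid count (default 3).
#' @param somy named integer vector of whole-chromosome chromatid counts;
#'   unnamed chromosomes default to `baseline`.
#' @param events tibble/data frame of segmental events: `chrom`, `start`,
#'   `end`, `delta` (chromatid change).
#' @return A `karyotype_spec`.
#' @export
karyotype_spec <- function(layout, baseline = 3L, somy = integer(0),
                           events = NULL) {
  full <- stats::setNames(rep(as.integer(baseline), nrow(layout)), layout$chrom)
  if (length(somy)) {
    bad <- setdiff(names(somy), layout$chrom)
    if (length(bad)) stop("unknown chromosome in somy: ", bad[1])
    full[names(somy)] <- as.integer(somy)
  }
  if (any(full < 0 | full > 4)) stop("chromatid counts must be within 0-4")
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("chrom", "start", "end", "delta") %in% names(events)))
    for (i in seq_len(nrow(events))) {
      ch <- events$chrom[i]
      len <- layout$length[match(ch, layout$chrom)]
      if (is.na(len) || events$start[i] < 0 || events$end[i] > len ||
          events$end[i] <= events$start[i]) {
        stop("event ", i, " outside chromosome bounds")
      }
      cn <- full[ch] + events$delta[i]
      if (cn < 0 || cn > 4) stop("event ", i, " pushes copy number outside 0-4")
    }
  } else {
    events <- tibble::tibble(chrom = character(0), start = numeric(0),
                             end = numeric(0), delta = integer(0))
  }
  structure(
    list(layout = layout, baseline = as.integer(baseline), somy = full,
         events = events),
    class = "karyotype_spec"
  )
}

# copy number of a karyotype at given positions of one chromosome
karyotype_copy <- function(spec, chrom, pos) {
  cn <- rep(spec$somy[[chrom]], length(pos))
  ev <- spec$events[spec$events$chrom == chrom, ]
  for (i in seq_len(nrow(ev))) {
    hit <- pos >= ev$start[i] & pos < ev$end[i]
    cn[hit] <- cn[hit] + ev$delta[i]
  }
  cn
}

#' Ground-truth per-chromosome calls of a karyotype
#'
#' The modal chromatid count by bp (whole-chromosome somy unless segmental
#' events cover more than half the chromosome) classified against the
#' baseline — the truth a caller is scored against.
#'
#' @param spec a `karyotype_spec`.
#' @return A tibble: `chrom`, `modal_somy`, `classification`.
#' @export
karyotype_truth <- function(spec) {
  purrr::map_dfr(spec$layout$chrom, function(ch) {
    len <- spec$layout$length[match(ch, spec$layout$chrom)]
    ev <- spec$events[spec$events$chrom == ch, ]
    base <- spec$somy[[ch]]
    bp <- stats::setNames(len, as.character(base))
    for (i in seq_len(nrow(ev))) {
      w <- ev$end[i] - ev$start[i]
      cn <- as.character(base + ev$delta[i])
      bp[as.character(base)] <- bp[as.character(base)] - w
      bp[cn] <- sum(bp[cn], w, na.rm = TRUE)
    }
    modal <- as.integer(names(bp)[which.max(bp)])
    cls <- if (modal == spec$baseline) "euploid" else if (modal > spec$baseline) "gain" else "loss"
    tibble::tibble(chrom = ch, modal_somy = modal, classification = cls)
  })
}

#' WGA noise model for simulated coverage
#'
#' Multiplicative coverage distortions of single-cell whole-genome
#' amplification, applied per GC window of the layout: a linear GC bias
#' (`1 + gc_slope * (gc - 0.4)`), a lognormal amplification factor with
#' log-SD `wga_sigma` (bin-scale amplification unevenness — the source of
#' the undulating patterns and baseline ambiguity seen in real single-cell
#' data), and a dropout probability `zero_inflation_p` per window. Window
#' weights are drawn once per sample, making counts over-dispersed relative
#' to Poisson at roughly `nb_dispersion` variance/mean in 1-Mb bins under
#' the defaults.
#'
#' @param gc_slope multiplicative GC bias per unit GC deviation (default 0.8).
#' @param wga_sigma lognormal log-SD of the per-window amplification factor
#'   (default 0.3 at 100-kb windows).
#' @param zero_inflation_p per-window dropout probability (default 0.01).
#' @param nb_dispersion nominal variance/mean target, recorded for
#'   reference (default 2).
#' @return A `noise_model` list.
#' @export
noise_model <- function(gc_slope = 0.8, wga_sigma = 0.3, zero_inflation_p = 0.01,
                        nb_dispersion = 2) {
  stopifnot(gc_slope >= 0, wga_sigma >= 0,
            zero_inflation_p >= 0, zero_inflation_p < 1, nb_dispersion >= 0)
  structure(
    list(gc_slope = gc_slope, wga_sigma = wga_sigma,
         zero_inflation_p = zero_inflation_p, nb_dispersion = nb_dispersion),
    class = "noise_model"
  )
}

#' Simulate a low-pass read set from a karyotype
#'
#' Read starts are drawn window-by-window with probability proportional to
#' local copy number x GC bias x lognormal WGA factor; dropout windows emit
#' nothing; positions are uniform within a window. MAPQ is set to values
#' >= 5 (mostly 60), since the simulator models post-alignment reads. The
#' same seed yields an identical read set.
#'
#' @param spec a `karyotype_spec`.
#' @param n_reads number of reads to draw.
#' @param noise a `noise_model`.
#' @param seed integer seed.
#' @return A list: `reads` (a `read_set`), `truth` (per-chromosome calls
#'   from [karyotype_truth()]), `events` (segmental ground truth).
#' @export
simulate_reads <- function(spec, n_reads, noise = noise_model(), seed = 1L) {
  stopifnot(n_reads > 0)
  layout <- spec$layout
  gc <- layout_gc(layout)
  if (is.null(gc)) stop("layout needs a GC track for simulation")
  withr::with_seed(as.integer(seed), {
    mid <- (gc$start + gc$end) / 2
    cn <- numeric(nrow(gc))
    for (ch in unique(gc$chrom)) {
      i <- gc$chrom == ch
      cn[i] <- karyotype_copy(spec, ch, mid[i])
    }
    if (all(cn == 0)) stop("karyotype has zero copies everywhere")
    mapp <- if ("mappability" %in% names(gc)) gc$mappability else 1
    w <- cn * mapp * pmax(1 + noise$gc_slope * (gc$gc - 0.4), 0.05) *
      stats::rlnorm(nrow(gc), 0, noise$wga_sigma) *
      (gc$end - gc$start) / mean(gc$end - gc$start)
    w[stats::runif(nrow(gc)) < noise$zero_inflation_p] <- 0
    counts <- as.integer(stats::rmultinom(1, n_reads, w / sum(w)))
    idx <- rep.int(seq_len(nrow(gc)), counts)
    pos <- floor(gc$start[idx] +
                   stats::runif(length(idx)) * (gc$end[idx] - gc$start[idx]))
    mapq <- ifelse(stats::runif(length(idx)) < 0.9, 60L,
                   as.integer(5 + floor(stats::runif(length(idx)) * 55)))
    ord <- order(match(gc$chrom[idx], layout$chrom), pos)
    reads <- new_read_set(
      tibble::tibble(chrom = gc$chrom[idx][ord], start = pos[ord],
                     mapq = mapq[ord]),
      provenance = list(source = "simulate_reads", seed = seed,
                        n_reads = n_reads),
      seed = seed
    )
    list(reads = reads, truth = karyotype_truth(spec), events = spec$events)
  })
}

#' Simulate an aCGH probe profile from a karyotype
#'
#' Probes are spread over chromosomes proportionally to length (at least
#' two per chromosome) at uniform sorted positions. Each probe's log2 ratio
#' is the expected `log2(copies / baseline)` plus independent Gaussian
#' noise with SD `target_dlrs` in both control channels, so the realised
#' derivative-log-ratio spread estimates `target_dlrs`. For chromosome X
#' the male-control channel is offset by +1 (log2 of the 2:1 X dosage of a
#' female vs male control).
#'
#' @param spec a `karyotype_spec`.
#' @param n_probes total probe count (>= 2 per chromosome).
#' @param target_dlrs target derivative-log-ratio spread (default 0.57, the
#'   cohort mean for single-cell WGA material).
#' @param seed integer seed.
#' @return An `acgh_profile` tibble with a `truth` attribute.
#' @export
simulate_acgh <- function(spec, n_probes = 20000L, target_dlrs = 0.57, seed = 1L) {
  layout <- spec$layout
  if (n_probes < 2 * nrow(layout)) stop("need at least 2 probes per chromosome")
  stopifnot(target_dlrs >= 0)
  withr::with_seed(as.integer(seed), {
    share <- pmax(2L, round(n_probes * layout$length / sum(layout$length)))
    prof <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      ch <- layout$chrom[i]
      pos <- sort(floor(stats::runif(share[i], 0, layout$length[i])))
      cn <- karyotype_copy(spec, ch, pos)
      expected <- ifelse(cn > 0, log2(cn / spec$baseline), -3) # floor for 0 copies
      male_off <- if (ch == "chrX") 1 else 0
      tibble::tibble(
        chrom = ch, position = pos,
        log2_vs_male = expected + male_off + stats::rnorm(share[i], 0, target_dlrs),
        log2_vs_female = expected + stats::rnorm(share[i], 0, target_dlrs)
      )
    })
    out <- as_acgh_profile(prof)
    attr(out, "truth") <- karyotype_truth(spec)
    out
  })
}

#' Simulate a merged euploid reference read set
#'
#' The calling pipeline corrects mappability against a reference built by
#' merging aligned reads of several euploid samples (six in the validating
#' workflow, selected by aCGH DLRS < 0.7). Merging averages each sample's
#' private WGA amplification noise while preserving the shared mappability
#' landscape, which is exactly what variable-width binning needs.
#'
#' @param layout a `genome_layout`.
#' @param n_samples euploid samples to merge (default 6).
#' @param reads_each reads per merged sample.
#' @param noise a `noise_model`.
#' @param seed integer seed.
#' @return A merged `read_set`.
#' @export
simulate_reference <- function(layout, n_samples = 6L, reads_each = 1000000L,
                               noise = noise_model(), seed = 1L) {
  spec <- karyotype_spec(layout)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1, n_samples))
  parts <- lapply(seeds, function(s) {
    tibble::as_tibble(simulate_reads(spec, reads_each, noise, seed = s)$reads)
  })
  merged <- dplyr::bind_rows(parts)
  merged <- merged[order(match(merged$chrom, layout$chrom), merged$start), ]
  new_read_set(merged,
               provenance = list(source = "simulate_reference", seed = seed,
                                 n_samples = n_samples, reads_each = reads_each),
               seed = seed)
}

#' Simulate a paired nanopore + aCGH cohort with ground truth
#'
#' Draws per-sample karyotypes from independent per-chromosome gain/loss
#' probabilities (whole-chromosome events: gain = 4 chromatids, loss = 2),
#' then generates a read set and an aCGH profile per sample. The default
#' event probabilities are enriched on chromosomes 15, 16, 19, 21 and 22,
#' the chromosomes with the highest aneuploidy rates in oocytes.
#'
#' @param layout a `genome_layout`.
#' @param n_samples cohort size.
#' @param gain_prob,loss_prob per-chromosome event probabilities; either a
#'   single number or a vector named by chromosome.
#' @param n_reads reads per sample.
#' @param n_probes probes per aCGH profile.
#' @param target_dlrs aCGH noise level.
#' @param noise a `noise_model` for the read simulation.
#' @param seed integer seed.
#' @return A list: `samples` (named list with `reads`, `profile`, `truth`
#'   per sample) and `truth` (long tibble `sample`, `chrom`, `modal_somy`,
#'   `classification`).
#' @export
simulate_cohort <- function(layout, n_samples, gain_prob = 0.03,
                            loss_prob = 0.05, n_reads = 1000000L,
                            n_probes = 20000L, target_dlrs = 0.57,
                            noise = noise_model(), seed = 1L) {
  expand_prob <- function(p) {
    if (length(p) == 1 && is.null(names(p))) {
      return(stats::setNames(rep(p, nrow(layout)), layout$chrom))
    }
    stopifnot(all(names(p) %in% layout$chrom))
    full <- stats::setNames(rep(0, nrow(layout)), layout$chrom)
    full[names(p)] <- p
    full
  }
  gp <- expand_prob(gain_prob)
  lp <- expand_prob(loss_prob)
  stopifnot(all(gp >= 0 & gp <= 1), all(lp >= 0 & lp <= 1), all(gp + lp <= 1))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1, 2 * n_samples))
  samples <- lapply(seq_len(n_samples), function(i) {
    somy <- withr::with_seed(seeds[i], {
      u <- stats::runif(nrow(layout))
      s <- rep(3L, nrow(layout))
      s[u < gp] <- 4L
      s[u >= gp & u < gp + lp] <- 2L
      stats::setNames(s, layout$chrom)
    })
    spec <- karyotype_spec(layout, baseline = 3L, somy = somy)
    sim <- simulate_reads(spec, n_reads, noise, seed = seeds[i])
    prof <- simulate_acgh(spec, n_probes, target_dlrs, seed = seeds[n_samples + i])
    list(reads = sim$reads, profile = prof, truth = sim$truth, spec = spec)
  })
  ids <- sprintf("S%03d", seq_len(n_samples))
  names(samples) <- ids
  truth <- purrr::map2_dfr(samples, ids, function(s, id) {
    dplyr::mutate(s$truth, sample = id, .before = 1)
  })
  list(samples = samples, truth = truth)
}
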