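test_that("karyotype specs validate chromatid counts and events", {
  lay <- fixture_toy_layout()
  spec <- karyotype_spec(lay, somy = c(chr21 = 2L))
  expect_equal(spec$somy[["chr21"]], 2L)
  expect_equal(spec$somy[["chr1"]], 3L)
  expect_error(karyotype_spec(lay, somy = c(chr1 = 5L)), "0-4")
  expect_error(karyotype_spec(lay, somy = c(chr99 = 3L)), "unknown")
  expect_error(
    karyotype_spec(lay, events = tibble::tibble(
      chrom = "chr1", start = 0, end = 1e12, delta = 1L)),
    "bounds")
  expect_error(
    karyotype_spec(lay, somy = c(chr1 = 4L),
                   events = tibble::tibble(chrom = "chr1", start = 0,
                                           end = 1e6, delta = 1L)),
    "outside 0-4")
  # truth bookkeeping covers segmental events
  ev <- tibble::tibble(chrom = "chr1", start = 0,
                       end = lay$length[1] * 0.6, delta = 1L)
  spec2 <- karyotype_spec(lay, events = ev)
  truth <- karyotype_truth(spec2)
  expect_equal(truth$classification[truth$chrom == "chr1"], "gain")
  expect_identical(spec2$events, ev)
})

test_that("noise-free euploid coverage is near-uniform", {
  lay <- flat_layout()
  sim <- simulate_reads(karyotype_spec(lay), 1000000,
                        noise_model(0, 0, 0), seed = 2)
  bins <- make_fixed_bins(lay, 1000000L)  # ~10,000 reads per bin
  bc <- count_reads(sim$reads, bins)
  full <- bc[bc$end - bc$start == 1000000, ]  # drop truncated terminal bins
  cv <- sd(full$raw) / mean(full$raw)
  expect_lt(cv, 0.05)
})

test_that("a 4-chromatid chromosome draws reads at the 4/3 rate", {
  lay <- flat_layout()
  sim <- simulate_reads(karyotype_spec(lay, somy = c(chr2 = 4L)), 1000000,
                        noise_model(0, 0, 0), seed = 3)
  bins <- make_fixed_bins(lay, 1000000L)
  bc <- count_reads(sim$reads, bins)
  bc <- bc[bc$end - bc$start == 1000000, ]
  ratio <- mean(bc$raw[bc$chrom == "chr2"]) /
    mean(bc$raw[bc$chrom != "chr2"])
  expect_gt(ratio, 1.28)
  expect_lt(ratio, 1.39)
})

test_that("read simulation is deterministic under a fixed seed", {
  lay <- fixture_toy_layout()
  spec <- karyotype_spec(lay, somy = c(chr16 = 2L))
  a <- simulate_reads(spec, 20000, seed = 11)$reads
  b <- simulate_reads(spec, 20000, seed = 11)$reads
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_reads(spec, 20000, seed = 12)$reads
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  expect_true(all(a$mapq >= 5))
})

test_that("noiseless aCGH probes sit exactly at the expected log2 levels", {
  lay <- fixture_toy_layout()
  spec <- karyotype_spec(lay, somy = c(chr5 = 4L, chr9 = 2L))
  prof <- simulate_acgh(spec, n_probes = 2300, target_dlrs = 0, seed = 4)
  f <- prof$log2_vs_female
  expect_true(all(abs(f[prof$chrom == "chr5"] - state_log2(4, 3)) < 1e-12))
  expect_true(all(abs(f[prof$chrom == "chr9"] - state_log2(2, 3)) < 1e-12))
  expect_true(all(abs(f[prof$chrom == "chr1"]) < 1e-12))
  # X male channel carries the female-vs-male control offset
  x <- prof[prof$chrom == "chrX", ]
  expect_true(all(abs(x$log2_vs_male - 1) < 1e-12))
})

test_that("the DLRS round-trips through simulation", {
  lay <- grch38_layout()
  prof <- simulate_acgh(karyotype_spec(lay), n_probes = 20000,
                        target_dlrs = 0.57, seed = 5)
  est <- dlr_spread(prof, "female")
  expect_gte(est, 0.52)
  expect_lte(est, 0.62)
})

test_that("cohort simulation matches its binomial event model", {
  lay <- fixture_toy_layout()
  co <- simulate_cohort(lay, n_samples = 1000, gain_prob = 0,
                        loss_prob = c(chr21 = 0.05), n_reads = 1000,
                        n_probes = 60, seed = 6)
  losses <- sum(co$truth$classification == "loss")
  expect_equal(sum(co$truth$classification == "gain"), 0L)
  # all losses on chr21, count within 3 binomial SDs of 50
  expect_true(all(co$truth$chrom[co$truth$classification == "loss"] == "chr21"))
  se <- sqrt(1000 * 0.05 * 0.95)
  expect_lt(abs(losses - 50), 3 * se)
  # zero probabilities: everyone euploid
  eu <- simulate_cohort(lay, n_samples = 5, gain_prob = 0, loss_prob = 0,
                        n_reads = 1000, n_probes = 60, seed = 7)
  expect_true(all(eu$truth$classification == "euploid"))
  # determinism
  co2 <- simulate_cohort(lay, n_samples = 3, gain_prob = 0.1, loss_prob = 0.1,
                         n_reads = 1000, n_probes = 60, seed = 8)
  co3 <- simulate_cohort(lay, n_samples = 3, gain_prob = 0.1, loss_prob = 0.1,
                         n_reads = 1000, n_probes = 60, seed = 8)
  expect_identical(co2$truth, co3$truth)
  expect_identical(tibble::as_tibble(co2$samples[[1]]$reads),
                   tibble::as_tibble(co3$samples[[1]]$reads))
})
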