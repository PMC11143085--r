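test_that("expected state log2 ratios match the closed form", {
  expect_equal(round(state_log2(3, 2), 2), 0.58)
  expect_equal(round(state_log2(1, 2), 2), -1)
  expect_equal(round(state_log2(4, 3), 2), 0.42)
  expect_equal(round(state_log2(2, 3), 2), -0.58)
  expect_equal(state_log2(3, 3), 0)
  expect_error(state_log2(0, 3), "positive")
  expect_error(state_log2(3, -1), "positive")
})

test_that("gain/loss thresholds sit halfway between adjacent states", {
  t3 <- acgh_thresholds(3)
  expect_equal(round(t3$gain, 2), 0.22)
  expect_equal(round(t3$loss, 2), -0.26)
  t1 <- acgh_thresholds(1)
  expect_equal(t1$gain, log2(1.5))
  expect_equal(t1$loss, -1)
  t2 <- acgh_thresholds(2)
  expect_equal(round(t2$gain, 3), 0.322)
  expect_equal(round(t2$loss, 3), -0.415)
  expect_error(acgh_thresholds(0), "baseline")
  # each threshold lies strictly between the adjacent expected states
  for (b in 2:3) {
    tt <- acgh_thresholds(b)
    expect_gt(tt$gain, 0)
    expect_lt(tt$gain, state_log2(b + 1, b))
    expect_lt(tt$loss, 0)
    expect_gt(tt$loss, state_log2(b - 1, b))
  }
})

make_profile <- function(means_by_chrom, n = 50, sd = 0, seed = 1,
                         chroms = c(paste0("chr", 1:22), "chrX")) {
  withr::with_seed(seed, as_acgh_profile(purrr::map_dfr(chroms, function(ch) {
    mu <- if (ch %in% names(means_by_chrom)) means_by_chrom[[ch]] else 0
    tibble::tibble(
      chrom = ch, position = sort(sample.int(1e8, n)),
      log2_vs_male = mu + rnorm(n, 0, sd),
      log2_vs_female = mu + rnorm(n, 0, sd)
    )
  })))
}

test_that("chromosome means are plain arithmetic means per channel", {
  prof <- make_profile(list(), n = 10, sd = 0)
  prof$log2_vs_male[] <- 0.3
  prof$log2_vs_female[] <- 0.3
  m <- chromosome_means(prof)
  expect_true(all(abs(m$mean_vs_male - 0.3) < 1e-12))
  expect_true(all(abs(m$mean_vs_female - 0.3) < 1e-12))
  two <- as_acgh_profile(tibble::tibble(
    chrom = "chrX", position = c(1, 2),
    log2_vs_male = c(0.1, 0.5), log2_vs_female = c(0.1, 0.5)
  ))
  expect_warning(m2 <- chromosome_means(two), "omitted")
  expect_equal(m2$mean_vs_male, 0.3)
})

test_that("euploid trisomic profiles have chromosome means near zero", {
  lay <- grch38_layout()
  ok <- 0
  total <- 0
  for (s in 1:100) {
    prof <- simulate_acgh(karyotype_spec(lay), n_probes = 46000,
                          target_dlrs = 0.57, seed = s)
    m <- chromosome_means(prof)
    ok <- ok + sum(abs(m$mean_vs_female) < 0.05)
    total <- total + nrow(m)
  }
  expect_gte(ok / total, 0.95)
})

test_that("classification needs both channels for autosomes, female only for X", {
  thr <- acgh_thresholds(3)
  base <- chromosome_means(make_profile(list(), n = 5, sd = 0))
  set_chr <- function(m, ch, male, female) {
    m$mean_vs_male[m$chrom == ch] <- male
    m$mean_vs_female[m$chrom == ch] <- female
    m
  }
  both <- classify_acgh(set_chr(base, "chr7", 0.30, 0.28), thr)
  expect_equal(both$calls$classification[both$calls$chrom == "chr7"], "gain")
  disagree <- classify_acgh(set_chr(base, "chr7", 0.30, 0.10), thr)
  expect_equal(disagree$calls$classification[disagree$calls$chrom == "chr7"],
               "euploid")
  xloss <- classify_acgh(set_chr(base, "chrX", 0.50, -0.40), thr)
  expect_equal(xloss$calls$classification[xloss$calls$chrom == "chrX"], "loss")
  # exact threshold values stay euploid (strict comparisons)
  border <- classify_acgh(set_chr(base, "chr7", thr$gain, thr$gain), thr)
  expect_equal(border$calls$classification[border$calls$chrom == "chr7"],
               "euploid")
  expect_error(classify_acgh(base[base$chrom != "chrX", ], thr), "X")
})

test_that("DLRS estimates the per-probe noise SD", {
  # constant profile: zero spread
  flat <- make_profile(list(), n = 20, sd = 0)
  expect_equal(dlr_spread(flat, "female"), 0)
  # iid Normal(c, sigma): DLRS -> sigma
  prof <- make_profile(list(), n = 500, sd = 0.35, seed = 2)  # 11500 probes
  expect_lt(abs(dlr_spread(prof, "female") - 0.35) / 0.35, 0.05)
  expect_error(
    dlr_spread(as_acgh_profile(tibble::tibble(
      chrom = c("chr1", "chr2"), position = c(1, 1),
      log2_vs_male = 0, log2_vs_female = 0))),
    "2 probes")
})

test_that("aCGH classification recovers simulated whole-chromosome events", {
  lay <- grch38_layout()
  correct <- 0
  total <- 0
  for (s in 1:100) {
    somy <- withr::with_seed(1000 + s, {
      v <- sample(c(2L, 3L, 4L), 23, replace = TRUE, prob = c(0.1, 0.8, 0.1))
      stats::setNames(v, lay$chrom)
    })
    spec <- karyotype_spec(lay, somy = somy)
    prof <- simulate_acgh(spec, n_probes = 23 * 500, target_dlrs = 0.57,
                          seed = 2000 + s)
    res <- classify_acgh(chromosome_means(prof), acgh_thresholds(3))
    truth <- karyotype_truth(spec)
    correct <- correct + sum(res$calls$classification == truth$classification)
    total <- total + 23
  }
  expect_gte(correct / total, 0.95)
})
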