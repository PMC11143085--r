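# Simulate counts from the model family itself: per-bin somy states with
# sticky transitions, NB emissions with mean s*mu and variance s*sigma2.
simulate_hmm_counts <- function(n, mu, sigma2, somy, seed = 1) {
  withr::with_seed(seed, {
    m <- somy * mu
    v <- pmax(somy * sigma2, m * 1.001 + 1e-9)
    size <- m^2 / (v - m)
    x <- rnbinom(n, size = size, mu = m)
    counts_fixture(x)
  })
}

test_that("moment initialisation recovers per-chromatid mean and variance", {
  set.seed(5)
  n <- 2500
  x <- rnbinom(n, size = 300^2 / (600 - 300), mu = 300)  # mean 300, var 600
  bc <- counts_fixture(x)
  m <- init_model(bc, expected_baseline = 3L)
  expect_lt(abs(m$mu - 100) / 100, 0.05)
  expect_lt(abs(m$sigma2 - 200) / 200, 0.15)
  m1 <- init_model(bc, expected_baseline = 1L)
  expect_lt(abs(m1$mu - 300) / 300, 0.05)
  expect_error(init_model(counts_fixture(rep(0, 100))), "zero")
})

test_that("EM recovers tied emission parameters from model-family data", {
  somy <- rep(3L, 2500)
  somy[1200:1500] <- 4L   # one 4-somy block
  bc <- simulate_hmm_counts(2500, mu = 100, sigma2 = 180, somy = somy, seed = 2)
  m <- fit_em(init_model(bc), bc, tol = 1e-5, max_iter = 100)
  expect_lt(abs(m$mu - 100) / 100, 0.10)
  path <- viterbi(m, bc)
  expect_equal(polarploidy:::modal_state_bp(path), "3-somy")
})

test_that("the log-likelihood trace is non-decreasing and converges", {
  bc <- simulate_hmm_counts(500, 100, 180, rep(3L, 500), seed = 3)
  m <- fit_em(init_model(bc), bc)
  expect_true(all(diff(m$loglik_trace) >= -1e-8))
  expect_lt(length(m$loglik_trace), 50)
  # infinite tolerance: exactly one EM iteration
  m1 <- fit_em(init_model(bc), bc, tol = Inf)
  expect_equal(length(m1$loglik_trace), 2)
  expect_true(all(abs(rowSums(m1$transition) - 1) < 1e-9))
})

test_that("EM stays monotone across random starts", {
  for (s in 1:10) {
    somy <- withr::with_seed(s, sample(c(2L, 3L, 4L), 120, replace = TRUE,
                                       prob = c(0.15, 0.7, 0.15)))
    bc <- simulate_hmm_counts(120, 80, 150, somy, seed = 100 + s)
    m <- fit_em(init_model(bc), bc, max_iter = 30)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("Viterbi equals the exhaustive-path oracle on small instances", {
  for (s in 1:5) {
    n <- 6
    bc <- simulate_hmm_counts(n, 50, 100,
                              withr::with_seed(s, sample(1:4, n, TRUE)),
                              seed = 200 + s)
    m <- fit_em(init_model(bc), bc, max_iter = 5)
    logE <- polarploidy:::hmm_log_emissions(
      polarploidy:::hmm_observations(bc)$x, m$mu, m$sigma2)
    oracle <- brute_force_viterbi(logE, log(m$transition), log(m$initial))
    path <- viterbi(m, bc)
    got <- match(path$state, polarploidy:::.HMM_STATES)
    expect_equal(got, oracle)
  }
})

test_that("posteriors normalise and Viterbi beats random paths", {
  bc <- simulate_hmm_counts(60, 70, 140,
                            rep(c(3L, 4L, 3L), times = c(25, 10, 25)), seed = 9)
  m <- fit_em(init_model(bc), bc, max_iter = 20)
  path <- viterbi(m, bc)
  post <- as.matrix(path[, grep("^p_", names(path))])
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  logE <- polarploidy:::hmm_log_emissions(
    polarploidy:::hmm_observations(bc)$x, m$mu, m$sigma2)
  vit_lp <- path_logprob(match(path$state, polarploidy:::.HMM_STATES),
                         logE, log(m$transition), log(m$initial))
  rand <- withr::with_seed(1, replicate(1000, path_logprob(
    sample(1:6, nrow(bc), replace = TRUE),
    logE, log(m$transition), log(m$initial))))
  expect_true(all(vit_lp >= rand))
})

test_that("zero bins decode as zero-inflation, not 0-somy, when likelier", {
  # long 3-somy stretch with an embedded run of exact zeros; under the
  # residual-background NB (mean eps*mu) a zero is less likely than under
  # the point mass, so the zeros must decode as zero-inflation
  x <- c(rep(300, 20), rep(0, 5), rep(300, 20))
  bc <- counts_fixture(x)
  m <- init_model(bc)
  m$mu <- 100
  m$sigma2 <- 150
  path <- viterbi(m, bc)
  expect_true(all(path$state[21:25] == "zero-inflation"))
  expect_true(all(path$state[c(1:20, 26:45)] == "3-somy"))
})

test_that("baseline anchoring repairs a shifted fit and flags failures", {
  bc <- simulate_hmm_counts(600, 100, 180, rep(3L, 600), seed = 12)
  m <- fit_em(init_model(bc), bc, max_iter = 50)
  # force a misfit: mu under-estimated by 25% makes 4-somy modal
  bad <- m
  bad$mu <- m$mu * 0.75
  bad$sigma2 <- max(m$sigma2 * 0.75, 1.05 * bad$mu)
  bad <- fit_em(bad, bc, max_iter = 3)
  expect_equal(polarploidy:::modal_state_bp(viterbi(bad, bc)), "4-somy")
  fixed <- anchor_baseline(bad, bc)
  expect_equal(polarploidy:::modal_state_bp(viterbi(fixed, bc)), "3-somy")
  expect_false(fixed$baseline_flag)
  # an already anchored fit is returned unchanged
  again <- anchor_baseline(m, bc)
  expect_false(again$baseline_flag)
  expect_equal(again$mu, m$mu)
  # adversarial bimodal data with no 3-somy-modal fit: flag, not error
  x <- withr::with_seed(4, rnbinom(400, mu = rep(c(60, 240), each = 200),
                                   size = 50))
  bim <- counts_fixture(x)
  mb <- fit_em(init_model(bim), bim, max_iter = 40)
  anchored <- anchor_baseline(mb, bim, max_retries = 2)
  modal <- polarploidy:::modal_state_bp(viterbi(anchored, bim))
  expect_true(anchored$baseline_flag || modal == "3-somy")
})

test_that("tidy and glance summarise a fitted model", {
  bc <- simulate_hmm_counts(300, 90, 160, rep(3L, 300), seed = 30)
  m <- fit_em(init_model(bc), bc, max_iter = 30)
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_equal(td$emission_mean[td$state == "3-somy"], 3 * m$mu)
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_false(gl$baseline_flag)
  expect_equal(gl$loglik, utils::tail(m$loglik_trace, 1))
})
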