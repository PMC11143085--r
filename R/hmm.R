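# Zero-inflated negative-binomial HMM over somy states 0..4 with tied
# emissions: state s emits NB with mean s*mu and variance s*sigma2, so one
# (mu, sigma2) pair describes all copy-number levels — the
# mean-proportional-to-copy-number assumption that makes a 3-somy baseline
# identifiable at low coverage. A separate zero-inflation state (point mass
# at zero) absorbs WGA dropout bins; the 0-somy state instead uses a small
# residual-background mean eps*mu (eps = 0.1) for misalignment reads, which
# keeps the two zero-heavy states distinguishable.

.HMM_STATES <- c("zero-inflation", "0-somy", "1-somy", "2-somy", "3-somy", "4-somy")
.HMM_EPS <- 0.1
# effective per-state copy factor (NA = point mass)
.HMM_COPY <- c(NA, .HMM_EPS, 1, 2, 3, 4)

new_cnv_hmm <- function(mu, sigma2, transition, initial, expected_baseline,
                        loglik_trace = numeric(0), baseline_flag = FALSE) {
  structure(
    list(
      states = .HMM_STATES, mu = mu, sigma2 = max(sigma2, 1.05 * mu),
      eps = .HMM_EPS, transition = transition, initial = initial,
      expected_baseline = as.integer(expected_baseline),
      loglik_trace = loglik_trace, baseline_flag = baseline_flag
    ),
    class = "cnv_hmm"
  )
}

#' @export
print.cnv_hmm <- function(x, ...) {
  cat("Zero-inflated NB copy-number HMM (states: zero-inflation, 0-4 somy)\n")
  cat(sprintf("  per-chromatid mean mu = %.3f, variance sigma2 = %.3f\n", x$mu, x$sigma2))
  cat(sprintf("  expected baseline: %d chromatids; baseline flag: %s\n",
              x$expected_baseline, x$baseline_flag))
  if (length(x$loglik_trace)) {
    cat(sprintf("  EM: %d iterations, log-likelihood %.2f\n",
                length(x$loglik_trace) - 1L, utils::tail(x$loglik_trace, 1)))
  }
  invisible(x)
}

# Observation vector used by the HMM: unmasked bins, corrected counts when
# available (rounded — NB emissions are discrete), raw otherwise.
hmm_observations <- function(counts) {
  un <- which(!counts$masked)
  if (length(un) == 0) stop("no unmasked bins")
  x <- counts$corrected[un]
  if (all(is.na(x))) x <- counts$raw[un]
  list(
    x = as.integer(round(pmax(x, 0))),
    bin_index = un,
    chrom = counts$chrom[un]
  )
}

# T x 6 log emission matrix
hmm_log_emissions <- function(x, mu, sigma2, eps = .HMM_EPS) {
  K <- length(.HMM_COPY)
  out <- matrix(-Inf, nrow = length(x), ncol = K)
  out[, 1] <- ifelse(x == 0, 0, -Inf)
  for (k in 2:K) {
    s <- .HMM_COPY[k]
    m <- s * mu
    v <- max(s * sigma2, m * 1.001 + 1e-9)
    size <- m^2 / (v - m)
    out[, k] <- stats::dnbinom(x, size = size, mu = m, log = TRUE)
  }
  out
}

#' Initialise the copy-number HMM from binned counts
#'
#' Moment initialisation: the per-chromatid mean `mu` is the 10%-trimmed
#' mean of the positive corrected counts divided by the expected baseline
#' (3 chromatids for pooled polar bodies), and the per-chromatid variance is
#' the sample variance of those counts divided by the baseline, floored at
#' `1.05 * mu` (a valid negative binomial needs variance above the mean).
#' Transitions start sticky (self-probability 0.99) and the initial
#' distribution uniform.
#'
#' @param counts a `binned_counts` (at least 100 unmasked bins for a fit
#'   that is later trusted; initialisation itself only needs positives).
#' @param expected_baseline euploid chromatid count (default 3).
#' @return A `cnv_hmm` model.
#' @export
init_model <- function(counts, expected_baseline = 3L) {
  obs <- hmm_observations(counts)
  pos <- obs$x[obs$x > 0]
  if (length(pos) == 0) stop("all bin counts are zero; sample unanalysable")
  mu0 <- mean(pos, trim = 0.1) / expected_baseline
  s20 <- max(stats::var(pos) / expected_baseline, 1.05 * mu0)
  K <- length(.HMM_STATES)
  A <- matrix(0.01 / (K - 1), K, K)
  diag(A) <- 0.99
  new_cnv_hmm(mu0, s20, A, rep(1 / K, K), expected_baseline)
}

# One Baum-Welch E-step over all chromosomes (independent chains).
hmm_estep <- function(model, obs) {
  logA <- log(model$transition)
  logPi <- log(model$initial)
  logE_all <- hmm_log_emissions(obs$x, model$mu, model$sigma2)
  chroms <- unique(obs$chrom)
  K <- length(.HMM_STATES)
  gamma <- matrix(0, nrow = length(obs$x), ncol = K)
  xi_sum <- matrix(0, K, K)
  first_gamma <- matrix(0, length(chroms), K)
  ll <- 0
  for (i in seq_along(chroms)) {
    idx <- which(obs$chrom == chroms[i])
    r <- .fb_chrom(logE_all[idx, , drop = FALSE], logA, logPi)
    if (!is.finite(r$loglik)) stop("non-finite likelihood on ", chroms[i])
    ll <- ll + r$loglik
    gamma[idx, ] <- r$gamma
    xi_sum <- xi_sum + r$xi_sum
    first_gamma[i, ] <- r$gamma[1, ]
  }
  list(loglik = ll, gamma = gamma, xi_sum = xi_sum, first_gamma = first_gamma)
}

# Expected complete-data log-likelihood terms that depend on (mu, sigma2);
# maximised numerically in the M-step (generalised EM: the update is only
# accepted when it improves Q, so the log-likelihood never decreases).
hmm_q_emission <- function(gamma, x, mu, sigma2) {
  q <- 0
  for (k in 2:length(.HMM_COPY)) {
    w <- gamma[, k]
    if (sum(w) < 1e-12) next
    s <- .HMM_COPY[k]
    m <- s * mu
    v <- max(s * sigma2, m * 1.001 + 1e-9)
    size <- m^2 / (v - m)
    q <- q + sum(w * stats::dnbinom(x, size = size, mu = m, log = TRUE))
  }
  q
}

hmm_mstep_emission <- function(gamma, x, mu, sigma2) {
  q0 <- hmm_q_emission(gamma, x, mu, sigma2)
  par0 <- c(log(mu), log(max(sigma2 / mu - 1.05, 1e-6)))
  negq <- function(p) {
    m <- exp(p[1])
    s2 <- m * (1.05 + exp(p[2]))
    -hmm_q_emission(gamma, x, m, s2)
  }
  opt <- tryCatch(
    stats::optim(par0, negq, method = "Nelder-Mead", control = list(maxit = 200)),
    error = function(e) NULL
  )
  if (!is.null(opt) && -opt$value > q0) {
    mu_new <- exp(opt$par[1])
    list(mu = mu_new, sigma2 = mu_new * (1.05 + exp(opt$par[2])))
  } else {
    list(mu = mu, sigma2 = sigma2)
  }
}

#' Fit the copy-number HMM by Baum-Welch EM
#'
#' Expectation-maximisation with tied emissions. Forward-backward runs in
#' log space per chromosome (chromosomes are independent chains); the
#' transition matrix and initial distribution have closed-form updates, and
#' the tied `(mu, sigma2)` pair is updated by numerical maximisation of the
#' expected complete-data log-likelihood, accepted only when it improves it,
#' so the log-likelihood trace is non-decreasing. Iteration stops when the
#' relative log-likelihood gain falls below `tol` or after `max_iter`
#' iterations.
#'
#' @param model a `cnv_hmm` initialised on these counts.
#' @param counts the `binned_counts` used for initialisation.
#' @param tol relative log-likelihood tolerance (default 1e-4).
#' @param max_iter maximum EM iterations (default 500).
#' @return The fitted `cnv_hmm` with `loglik_trace` filled.
#' @export
fit_em <- function(model, counts, tol = 1e-4, max_iter = 500L) {
  obs <- hmm_observations(counts)
  trace <- numeric(0)
  ll_prev <- -Inf
  K <- length(.HMM_STATES)
  for (iter in seq_len(max_iter)) {
    e <- hmm_estep(model, obs)
    trace <- c(trace, e$loglik)
    if (iter > 1) {
      rel <- (e$loglik - ll_prev) / max(abs(ll_prev), 1)
      if (rel < tol) break
    }
    ll_prev <- e$loglik
    # closed-form updates
    A <- e$xi_sum + 1e-10
    model$transition <- A / rowSums(A)
    pi_new <- colMeans(e$first_gamma) + 1e-12
    model$initial <- pi_new / sum(pi_new)
    em <- hmm_mstep_emission(e$gamma, obs$x, model$mu, model$sigma2)
    model$mu <- em$mu
    model$sigma2 <- em$sigma2
  }
  model$loglik_trace <- trace
  model
}

#' Decode the maximum a posteriori state path
#'
#' Viterbi decoding per chromosome (no transitions across chromosome
#' boundaries) plus forward-backward posterior state probabilities per bin.
#'
#' @param model a fitted `cnv_hmm`.
#' @param counts the `binned_counts` the model was fitted on.
#' @return A `state_path` tibble over unmasked bins: `chrom`, `start`,
#'   `end`, `state` (state label), `somy` (integer, `NA` for the
#'   zero-inflation state) and posterior columns `p_zero_inflation`,
#'   `p_somy0` .. `p_somy4`.
#' @export
viterbi <- function(model, counts) {
  obs <- hmm_observations(counts)
  logA <- log(model$transition)
  logPi <- log(model$initial)
  logE_all <- hmm_log_emissions(obs$x, model$mu, model$sigma2)
  path <- integer(length(obs$x))
  K <- length(.HMM_STATES)
  post <- matrix(0, nrow = length(obs$x), ncol = K)
  for (ch in unique(obs$chrom)) {
    idx <- which(obs$chrom == ch)
    logE <- logE_all[idx, , drop = FALSE]
    path[idx] <- .viterbi_chrom(logE, logA, logPi)
    post[idx, ] <- .fb_chrom(logE, logA, logPi)$gamma
  }
  out <- tibble::tibble(
    chrom = counts$chrom[obs$bin_index],
    start = counts$start[obs$bin_index],
    end = counts$end[obs$bin_index],
    state = .HMM_STATES[path],
    somy = c(NA_integer_, 0L, 1L, 2L, 3L, 4L)[path]
  )
  colnames(post) <- c("p_zero_inflation", paste0("p_somy", 0:4))
  out <- dplyr::bind_cols(out, tibble::as_tibble(post))
  class(out) <- unique(c("state_path", class(out)))
  out
}

# Modal decoded state by total bp, used for baseline anchoring.
modal_state_bp <- function(path) {
  bp <- tapply((path$end - path$start), path$state, sum)
  names(bp)[which.max(bp)]
}

#' Anchor the fitted baseline at the expected modal somy
#'
#' Aneuploid calling against a 3-chromatid baseline assumes EM converged
#' with 3-somy as the modal state. When the decoded modal state (by total
#' bp) differs — the "baseline shift" failure mode of low-pass single-cell
#' fits — `mu` is rescaled by `modal / expected_baseline` and the model
#' refitted, up to `max_retries` times. If no retry lands on the expected
#' modal state, the best-likelihood fit is kept and `baseline_flag` is set
#' so the verdict can be reviewed.
#'
#' @param model a fitted `cnv_hmm`.
#' @param counts the `binned_counts` used for the fit.
#' @param max_retries re-anchoring attempts (default 3).
#' @param tol,max_iter EM settings for refits.
#' @return A `cnv_hmm` with `baseline_flag` set appropriately.
#' @export
anchor_baseline <- function(model, counts, max_retries = 3L, tol = 1e-4,
                            max_iter = 500L) {
  target <- paste0(model$expected_baseline, "-somy")
  best <- model
  best_ll <- utils::tail(model$loglik_trace, 1)
  for (try in seq_len(max_retries + 1L)) {
    path <- viterbi(model, counts)
    modal <- modal_state_bp(path)
    if (modal == "zero-inflation") {
      stop("modal decoded state is zero-inflation; sample unanalysable")
    }
    if (modal == target) {
      model$baseline_flag <- FALSE
      return(model)
    }
    if (try > max_retries) break
    modal_somy <- as.numeric(sub("-somy", "", modal))
    scale <- max(modal_somy, .HMM_EPS) / model$expected_baseline
    model$mu <- model$mu * scale
    model$sigma2 <- max(model$sigma2 * scale, 1.05 * model$mu)
    model <- fit_em(model, counts, tol = tol, max_iter = max_iter)
    ll <- utils::tail(model$loglik_trace, 1)
    if (ll > best_ll) {
      best <- model
      best_ll <- ll
    }
  }
  best$baseline_flag <- TRUE
  best
}

#' Fit, restart, and anchor the copy-number HMM
#'
#' Convenience wrapper used by the pipeline: initialises the model, runs EM
#' from `restarts` jittered transition matrices (seeded), keeps the
#' best-likelihood fit, then anchors the baseline at the expected modal
#' somy.
#'
#' @inheritParams init_model
#' @inheritParams fit_em
#' @param restarts number of EM restarts with jittered transitions.
#' @param seed integer seed for the jitter.
#' @param max_retries anchoring retries.
#' @return A fitted, anchored `cnv_hmm`.
#' @export
fit_cnv_hmm <- function(counts, expected_baseline = 3L, tol = 1e-4,
                        max_iter = 500L, restarts = 3L, seed = 1L,
                        max_retries = 3L) {
  model0 <- init_model(counts, expected_baseline)
  K <- length(.HMM_STATES)
  fits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(restarts), function(r) {
      m <- model0
      if (r > 1) {
        jitter <- matrix(stats::runif(K * K, 0, 0.02), K, K)
        A <- m$transition + jitter
        m$transition <- A / rowSums(A)
      }
      fit_em(m, counts, tol = tol, max_iter = max_iter)
    })
  })
  lls <- vapply(fits, function(m) utils::tail(m$loglik_trace, 1), numeric(1))
  best <- fits[[which.max(lls)]]
  anchor_baseline(best, counts, max_retries = max_retries, tol = tol,
                  max_iter = max_iter)
}

#' Serialise a fitted model to JSON
#'
#' All parameters, the likelihood trace and the baseline flag, for
#' reproducibility of a call.
#'
#' @param model a `cnv_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Tidy methods for the copy-number HMM
#'
#' `tidy()` returns one row per HMM state with its emission parameters;
#' `glance()` returns a one-row model summary.
#'
#' @param x a `cnv_hmm`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cnv_hmm <- function(x, ...) {
  tibble::tibble(
    state = x$states,
    copy_factor = .HMM_COPY,
    emission_mean = ifelse(is.na(.HMM_COPY), 0, .HMM_COPY * x$mu),
    emission_var = ifelse(is.na(.HMM_COPY), 0, .HMM_COPY * x$sigma2),
    self_transition = diag(x$transition),
    initial_prob = x$initial
  )
}

#' @rdname tidy.cnv_hmm
#' @export
glance.cnv_hmm <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma2 = x$sigma2,
    expected_baseline = x$expected_baseline,
    n_iter = max(length(x$loglik_trace) - 1L, 0L),
    loglik = if (length(x$loglik_trace)) utils::tail(x$loglik_trace, 1) else NA_real_,
    baseline_flag = x$baseline_flag
  )
}
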