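#' Construct a univariate Gaussian hidden Markov model
#'
#' A K-state HMM with Gaussian emissions, the model family used to segment
#' dynamic body acceleration into activity regimes. States are identified only
#' up to permutation; downstream code orders them by emission standard
#' deviation.
#'
#' @param pi Initial state distribution (length `K`, sums to 1).
#' @param A Transition matrix (`K` x `K`, rows sum to 1).
#' @param mu Per-state emission means (g).
#' @param sigma Per-state emission standard deviations (g), all above
#'   `sigma_floor`.
#' @param sigma_floor Lower bound enforced on `sigma` (default `1e-4` g),
#'   preventing degenerate collapse of a state onto a single observation.
#' @return An object of class `gaussian_hmm` with elements `K`, `pi`, `A`,
#'   `mu`, `sigma`, `sigma_floor`.
#' @export
gaussian_hmm <- function(pi, A, mu, sigma, sigma_floor = 1e-4) {
  K <- length(mu)
  A <- matrix(as.numeric(A), nrow = K)
  stopifnot(K >= 1, K <= 16, length(pi) == K, length(sigma) == K,
            nrow(A) == K, ncol(A) == K)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("rows of A must sum to 1")
  if (any(sigma < sigma_floor)) stop("all sigma must be >= sigma_floor")
  structure(list(K = K, pi = as.numeric(pi), A = A, mu = as.numeric(mu),
                 sigma = as.numeric(sigma), sigma_floor = sigma_floor),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM with %d states\n", x$K))
  cat("  mu    :", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat("  sigma :", paste(signif(x$sigma, 4), collapse = " "), "\n")
  cat("  pi    :", paste(signif(x$pi, 4), collapse = " "), "\n")
  invisible(x)
}

check_obs <- function(obs) {
  obs <- as.numeric(obs)
  if (length(obs) == 0) stop("observation sequence is empty")
  if (!all(is.finite(obs))) stop("observations must be finite")
  obs
}

#' Seeded random initialization of a Gaussian HMM
#'
#' Draws a starting model for EM. Emission scales are seeded from evenly
#' spaced quantiles of the absolute observations (low quantiles for quiet
#' states, high for active ones) with multiplicative jitter; means are small
#' jittered offsets around zero, since dynamic acceleration is near zero-mean
#' in every regime and states separate chiefly by variance. `pi` is uniform
#' and transition rows are diagonal-dominant random draws, reflecting the
#' persistence of behavior at 25 Hz.
#'
#' @param K Number of states (>= 1).
#' @param obs Numeric observation sequence, length >= `K`.
#' @param seed Integer seed; the initialization is deterministic given
#'   `(K, obs, seed)`.
#' @param sigma_floor Passed to [gaussian_hmm()].
#' @return A `gaussian_hmm`.
#' @export
random_init <- function(K, obs, seed, sigma_floor = 1e-4) {
  stopifnot(K >= 1)
  obs <- check_obs(obs)
  if (length(obs) < K) stop("need at least K observations to initialize")
  rng <- local_rng(seed)
  on.exit(rng())

  if (K == 1) {
    return(gaussian_hmm(pi = 1, A = matrix(1, 1, 1),
                        mu = mean(obs) * runif(1, 0.9, 1.1),
                        sigma = max(sd_pop(obs) * runif(1, 0.8, 1.2), sigma_floor * 2),
                        sigma_floor = sigma_floor))
  }

  s_all <- sd_pop(obs)
  # sd seeds log-spaced between the median and an extreme quantile of |obs|
  # (rescaled by the half-normal median 0.6745), so quiet and burst regimes
  # both attract a state even when quiet samples dominate the record
  q_lo <- quantile(abs(obs), 0.5, names = FALSE) / 0.6745
  q_hi <- quantile(abs(obs), 0.9995, names = FALSE) / 0.6745
  q_lo <- max(q_lo, s_all * 0.02, sigma_floor * 2)
  q_hi <- max(q_hi, q_lo * 1.01)
  sigma0 <- exp(seq(log(q_lo), log(q_hi), length.out = K)) * runif(K, 0.7, 1.4)
  sigma0 <- pmax(sigma0, sigma_floor * 2)
  mu0 <- rnorm(K, 0, 0.05 * s_all)
  pi0 <- rep(1 / K, K)
  A0 <- matrix(runif(K * K, 0.1, 1), K, K)
  diag(A0) <- diag(A0) + K * 2
  A0 <- A0 / rowSums(A0)
  gaussian_hmm(pi0, A0, mu0, sigma0, sigma_floor = sigma_floor)
}

#' Forward log-likelihood of an observation sequence
#'
#' Scaled forward recursion; returns `log p(obs | model)` in nats.
#'
#' @param model A `gaussian_hmm`.
#' @param obs Numeric observation sequence.
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(model, obs) {
  stopifnot(inherits(model, "gaussian_hmm"))
  obs <- check_obs(obs)
  .hmm_forward_cpp(obs, model$pi, model$A, model$mu, model$sigma)
}

#' Fit a Gaussian HMM by Baum-Welch expectation maximization
#'
#' Iterates scaled forward-backward E-steps and closed-form M-steps from a
#' given starting model. The log-likelihood trace is non-decreasing; iteration
#' stops at `max_iter` (default 10,000) or when the relative improvement drops
#' below `tol` (set `tol = 0` to always run the full `max_iter`). Emission
#' standard deviations are clamped at the model's `sigma_floor`. A state whose
#' total posterior mass starves (< 1e-12) is re-seeded from a residual
#' quantile of the observations with a warning.
#'
#' @param init Starting `gaussian_hmm`.
#' @param obs Numeric observation sequence.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @param seed Recorded in the result for provenance (not used for randomness
#'   unless a starved state must be re-seeded).
#' @return An object of class `hmm_fit`: list with `model`, `loglik`
#'   (final), `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
em_fit <- function(init, obs, max_iter = 10000, tol = 1e-6, seed = NA_integer_) {
  stopifnot(inherits(init, "gaussian_hmm"), max_iter >= 1)
  obs <- check_obs(obs)
  model <- init
  K <- model$K
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    e <- .hmm_forward_backward_cpp(obs, model$pi, model$A, model$mu, model$sigma)
    trace <- c(trace, e$loglik)

    g <- e$gamma
    mass <- colSums(g)
    starved <- which(mass < 1e-12)
    if (length(starved) > 0) {
      warning(sprintf("re-seeding starved state(s) %s from residual quantiles",
                      paste(starved, collapse = ", ")))
      for (k in starved) {
        model$mu[k] <- quantile(obs, runif(1), names = FALSE)
        model$sigma[k] <- max(sd_pop(obs), model$sigma_floor)
        mass[k] <- 1  # avoid 0/0 below; parameters for k were just reset
        g[, k] <- 0
      }
    }

    pi_new <- g[1, ]
    pi_new <- pi_new / sum(pi_new)
    A_new <- e$xi_sum
    rs <- rowSums(A_new)
    rs[rs == 0] <- 1
    A_new <- A_new / rs
    mu_new <- as.numeric(crossprod(g, obs)) / mass
    mu_new[!is.finite(mu_new)] <- model$mu[!is.finite(mu_new)]
    sig2 <- vapply(seq_len(K), function(k) sum(g[, k] * (obs - mu_new[k])^2), 0) / mass
    sigma_new <- pmax(sqrt(pmax(sig2, 0)), model$sigma_floor)
    if (length(starved) > 0) {
      mu_new[starved] <- model$mu[starved]
      sigma_new[starved] <- model$sigma[starved]
    }

    model$pi <- pi_new
    model$A <- A_new
    model$mu <- mu_new
    model$sigma <- sigma_new

    n <- length(trace)
    if (n >= 2) {
      rel <- (trace[n] - trace[n - 1]) / max(abs(trace[n - 1]), 1)
      if (rel < tol) { converged <- TRUE; break }
    }
  }

  structure(list(model = model, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = iter,
                 converged = converged, seed = seed),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian HMM fit: K = %d, loglik = %.4f, %d iteration(s)%s\n",
              x$model$K, x$loglik, x$n_iter,
              if (isTRUE(x$converged)) " (converged)" else ""))
  print(x$model)
  invisible(x)
}

#' Viterbi decoding
#'
#' Most probable state path given the model, computed in log space. Ties are
#' broken toward the lower state index.
#'
#' @param model A `gaussian_hmm`.
#' @param obs Numeric observation sequence.
#' @return Integer vector of state indices in `1..K`, one per observation.
#' @export
viterbi <- function(model, obs) {
  stopifnot(inherits(model, "gaussian_hmm"))
  obs <- check_obs(obs)
  .hmm_viterbi_cpp(obs, model$pi, model$A, model$mu, model$sigma)
}

#' Fit with multiple random restarts
#'
#' Runs [em_fit()] from `n_restarts` seeded random initializations and keeps
#' the fit with the highest final log-likelihood. Deterministic given `seeds`.
#'
#' @param K Number of states.
#' @param obs Numeric observation sequence.
#' @param n_restarts Number of restarts (default 10).
#' @param seeds Integer vector of length `n_restarts`; defaults to
#'   `seed_base + 1:n_restarts`.
#' @param seed_base Base for default seeds.
#' @param max_iter,tol Passed to [em_fit()].
#' @param sigma_floor Passed to [random_init()].
#' @return The best `hmm_fit`; all restart log-likelihoods are attached as
#'   attribute `restart_logliks`.
#' @export
fit_with_restarts <- function(K, obs, n_restarts = 10, seeds = NULL,
                              seed_base = 0L, max_iter = 10000, tol = 1e-6,
                              sigma_floor = 1e-4) {
  stopifnot(n_restarts >= 1)
  obs <- check_obs(obs)
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_restarts)
  stopifnot(length(seeds) == n_restarts)
  fits <- lapply(seeds, function(s) {
    em_fit(random_init(K, obs, seed = s, sigma_floor = sigma_floor), obs,
           max_iter = max_iter, tol = tol, seed = s)
  })
  lls <- vapply(fits, function(f) f$loglik, 0)
  best <- fits[[which.max(lls)]]
  attr(best, "restart_logliks") <- lls
  best
}

#' Compare state counts by BIC
#'
#' Fits models over a range of state counts and tabulates log-likelihood,
#' parameter count and BIC. The free-parameter count for a K-state univariate
#' Gaussian HMM is `(K - 1) + K(K - 1) + 2K` (initial distribution, transition
#' matrix, emission means and sds). The chosen K minimizes BIC unless
#' `K_pinned` overrides the choice; the full table is returned either way.
#'
#' @param obs Numeric observation sequence.
#' @param K_range Integer vector of state counts to fit (default `4:7`).
#' @param K_pinned Optional state count to select regardless of BIC.
#' @param n_restarts,seed_base,max_iter,tol Passed to [fit_with_restarts()].
#' @return List with `table` (data.frame: K, loglik, n_params, BIC), `chosen_K`,
#'   and `fits` (named list of `hmm_fit` per K).
#' @export
select_model <- function(obs, K_range = 4:7, K_pinned = NULL, n_restarts = 10,
                         seed_base = 0L, max_iter = 10000, tol = 1e-6) {
  obs <- check_obs(obs)
  stopifnot(length(obs) >= max(K_range))
  fits <- lapply(seq_along(K_range), function(i) {
    fit_with_restarts(K_range[i], obs, n_restarts = n_restarts,
                      seed_base = seed_base + 1000L * i,
                      max_iter = max_iter, tol = tol)
  })
  names(fits) <- paste0("K", K_range)
  n_params <- (K_range - 1) + K_range * (K_range - 1) + 2 * K_range
  loglik <- vapply(fits, function(f) f$loglik, 0)
  bic <- -2 * loglik + n_params * log(length(obs))
  tab <- data.frame(K = K_range, loglik = loglik, n_params = n_params,
                    BIC = bic, row.names = NULL)
  if (!is.null(K_pinned)) {
    if (!K_pinned %in% K_range) stop("K_pinned must lie in K_range")
    chosen <- K_pinned
  } else {
    chosen <- K_range[which.min(bic)]
  }
  list(table = tab, chosen_K = chosen, fits = fits)
}

# run code with a temporarily seeded RNG, restoring the caller's RNG state;
# returns the restore function for use with on.exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# population-form standard deviation (divisor n, the EM maximum-likelihood form)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
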