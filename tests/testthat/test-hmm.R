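test_that("random initialization is valid, deterministic and seed-sensitive", {
  set.seed(99)
  obs <- rnorm(500, sd = 0.05)

  m1 <- random_init(1, obs, seed = 1)
  expect_equal(m1$pi, 1)
  expect_equal(m1$A, matrix(1, 1, 1))

  a <- random_init(5, obs, seed = 42)
  b <- random_init(5, obs, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$pi), 1)
  expect_equal(rowSums(a$A), rep(1, 5))
  expect_true(all(a$sigma > 0))

  mus <- lapply(1:10, function(s) random_init(5, obs, seed = s)$mu)
  for (i in 1:9) for (j in (i + 1):10)
    expect_false(isTRUE(all.equal(mus[[i]], mus[[j]])))

  expect_error(random_init(5, obs[1:3], seed = 1), "at least K")
})

test_that("forward log-likelihood matches the closed form for one state", {
  m <- gaussian_hmm(1, matrix(1, 1, 1), mu = 0, sigma = 1)
  expect_equal(forward_loglik(m, 0), -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_error(forward_loglik(m, c(0, NA)), "finite")
})

test_that("forward log-likelihood matches exhaustive path summation", {
  set.seed(123)
  for (K in 2:3) {
    for (rep in 1:5) {
      m <- random_small_hmm(K)
      T_ <- if (K == 2) 8 else 6
      obs <- rnorm(T_, sd = 1.5)
      expect_equal(forward_loglik(m, obs), forward_loglik_bruteforce(m, obs),
                   tolerance = 1e-10)
    }
  }
})

test_that("Viterbi decoding matches exhaustive argmax over all paths", {
  set.seed(321)
  for (rep in 1:200) {
    m <- random_small_hmm(2)
    obs <- rnorm(10, sd = 1.5)
    expect_identical(viterbi(m, obs), viterbi_bruteforce(m, obs))
  }
  m1 <- gaussian_hmm(1, matrix(1, 1, 1), 0, 1)
  expect_identical(viterbi(m1, rnorm(20)), rep(1L, 20))
})

test_that("permuting state labels permutes the decoded sequence", {
  set.seed(5)
  m <- random_small_hmm(3)
  obs <- rnorm(50)
  perm <- c(3, 1, 2)  # new index of old state k is match(k, perm)
  mp <- gaussian_hmm(m$pi[perm], m$A[perm, perm], m$mu[perm], m$sigma[perm])
  v <- viterbi(m, obs)
  vp <- viterbi(mp, obs)
  expect_identical(match(v, perm), vp)
})

test_that("one-state EM equals the closed-form Gaussian fit", {
  set.seed(8)
  obs <- rnorm(400, mean = 0.3, sd = 0.7)
  init <- gaussian_hmm(1, matrix(1, 1, 1), mu = 5, sigma = 3)
  fit <- em_fit(init, obs, max_iter = 5)
  sd_p <- sqrt(mean((obs - mean(obs))^2))
  expect_equal(fit$model$mu, mean(obs), tolerance = 1e-12)
  expect_equal(fit$model$sigma, sd_p, tolerance = 1e-12)
  expect_equal(forward_loglik(fit$model, obs),
               sum(dnorm(obs, mean(obs), sd_p, log = TRUE)), tolerance = 1e-10)
})

test_that("EM never decreases the log-likelihood and conserves probabilities", {
  set.seed(77)
  true <- gaussian_hmm(c(0.5, 0.5), matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE),
                       mu = c(-1, 1), sigma = c(0.4, 0.6))
  obs <- simulate_obs(true, 800)
  for (s in 1:5) {
    fit <- em_fit(random_init(2, obs, seed = s), obs, max_iter = 200)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(sum(fit$model$pi), 1, tolerance = 1e-12)
    expect_equal(rowSums(fit$model$A), rep(1, 2), tolerance = 1e-12)
    expect_true(all(fit$model$sigma >= fit$model$sigma_floor))
    expect_lte(fit$n_iter, 200)
  }
})

test_that("EM recovers a well-separated two-state model", {
  set.seed(2024)
  true <- gaussian_hmm(c(0.5, 0.5), matrix(c(0.98, 0.02, 0.03, 0.97), 2, byrow = TRUE),
                       mu = c(0, 3), sigma = c(0.5, 0.5))
  obs <- simulate_obs(true, 5000)
  fit <- fit_with_restarts(2, obs, n_restarts = 5, seed_base = 10)
  ord <- order(fit$model$mu)
  expect_equal(fit$model$mu[ord], true$mu, tolerance = 0.05)
  expect_equal(fit$model$A[ord, ord], true$A, tolerance = 0.05)
})

test_that("restarts return the best fit and reduce to a single EM run", {
  set.seed(31)
  obs <- c(rnorm(300, sd = 0.3), rnorm(300, mean = 2, sd = 0.3))
  one <- fit_with_restarts(2, obs, n_restarts = 1, seeds = 7L)
  direct <- em_fit(random_init(2, obs, seed = 7L), obs, seed = 7L)
  expect_equal(one$model, direct$model)
  expect_equal(one$loglik, direct$loglik)

  best <- fit_with_restarts(2, obs, n_restarts = 6, seed_base = 0)
  lls <- attr(best, "restart_logliks")
  expect_length(lls, 6L)
  expect_equal(best$loglik, max(lls))
  expect_true(all(best$loglik >= lls))
})

test_that("BIC model comparison finds a two-state structure and reports all fits", {
  set.seed(55)
  true <- gaussian_hmm(c(0.5, 0.5), matrix(c(0.97, 0.03, 0.05, 0.95), 2, byrow = TRUE),
                       mu = c(0, 0), sigma = c(0.05, 0.5))
  obs <- simulate_obs(true, 10000)
  sel <- select_model(obs, K_range = 1:4, n_restarts = 3, seed_base = 2,
                      max_iter = 300)
  expect_equal(sel$chosen_K, 2L)
  expect_equal(nrow(sel$table), 4L)

  pinned <- select_model(obs[1:2000], K_range = 1:3, K_pinned = 3,
                         n_restarts = 2, seed_base = 5, max_iter = 100)
  expect_equal(pinned$chosen_K, 3L)
  expect_equal(nrow(pinned$table), 3L)  # all fits listed despite the pin

  # free-parameter count: (K-1) initial + K(K-1) transitions + 2K emissions
  expect_equal(sel$table$n_params, c(2, 7, 14, 23))
  expect_equal((5 - 1) + 5 * (5 - 1) + 2 * 5, 34)
})

test_that("model text serialization round-trips exactly", {
  set.seed(12)
  m <- random_small_hmm(4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path, seed = 9L, loglik = -123.456)
  m2 <- read_model(path)
  expect_equal(m2$pi, m$pi, tolerance = 0)
  expect_equal(m2$A, m$A, tolerance = 0)
  expect_equal(m2$mu, m$mu, tolerance = 0)
  expect_equal(m2$sigma, m$sigma, tolerance = 0)
  expect_identical(attr(m2, "seed"), 9L)
})
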