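# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# log p(obs | model) by explicit summation over all K^T state paths
forward_loglik_bruteforce <- function(model, obs) {
  K <- model$K
  T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(path) {
    lp <- log(model$pi[path[1]]) +
      dnorm(obs[1], model$mu[path[1]], model$sigma[path[1]], log = TRUE)
    if (T_ > 1) for (t in 2:T_) {
      lp <- lp + log(model$A[path[t - 1], path[t]]) +
        dnorm(obs[t], model$mu[path[t]], model$sigma[path[t]], log = TRUE)
    }
    lp
  })
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

# most probable path by exhaustive argmax; ties toward the lexicographically
# smallest path (matching the decoder's lower-index tie rule)
viterbi_bruteforce <- function(model, obs) {
  K <- model$K
  T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(path) {
    lp <- log(model$pi[path[1]]) +
      dnorm(obs[1], model$mu[path[1]], model$sigma[path[1]], log = TRUE)
    if (T_ > 1) for (t in 2:T_) {
      lp <- lp + log(model$A[path[t - 1], path[t]]) +
        dnorm(obs[t], model$mu[path[t]], model$sigma[path[t]], log = TRUE)
    }
    lp
  })
  best <- which(logp == max(logp))
  if (length(best) > 1) {
    ord <- do.call(order, as.data.frame(paths[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  as.integer(paths[best, ])
}

# sample an observation sequence from a Gaussian HMM (generative direction,
# independent of the package's fitting code)
simulate_obs <- function(model, T_) {
  s <- sample.int(model$K, 1, prob = model$pi)
  obs <- numeric(T_)
  for (t in seq_len(T_)) {
    if (t > 1) s <- sample.int(model$K, 1, prob = model$A[s, ])
    obs[t] <- rnorm(1, model$mu[s], model$sigma[s])
  }
  obs
}

random_small_hmm <- function(K) {
  pi <- runif(K); pi <- pi / sum(pi)
  A <- matrix(runif(K * K), K, K); A <- A / rowSums(A)
  gaussian_hmm(pi, A, mu = rnorm(K, 0, 2), sigma = runif(K, 0.3, 2))
}

# hand-built behavior script (list of behavior/duration at given sites)
make_script <- function(behavior, duration_s, location_id = NA,
                        from_id = NA, to_id = NA,
                        origin = as.numeric(as.POSIXct("2019-07-23 21:00:00",
                                                       tz = "GMT"))) {
  ends <- cumsum(duration_s)
  scr <- data.frame(behavior = behavior,
                    start_s = c(0, head(ends, -1)), end_s = ends,
                    location_id = rep_len(as.character(location_id), length(behavior)),
                    from_id = rep_len(as.character(from_id), length(behavior)),
                    to_id = rep_len(as.character(to_id), length(behavior)),
                    stringsAsFactors = FALSE)
  structure(scr, night_seconds = sum(duration_s), origin = origin,
            class = c("behavior_script", "data.frame"))
}

# minimal geometry: one post 5 m east of recorder R1, one post ~300 m away
tiny_geometry <- function(gps_error_sd = 20 / 1.96) {
  m_per_deg_lon <- 6371000 * pi / 180 * cos(51.35 * pi / 180)
  site_geometry(
    song_posts = data.frame(id = c("P1", "P2"),
                            lat = c(51.35, 51.35),
                            lon = c(4.49 + 5 / m_per_deg_lon, 4.494)),
    foraging_patches = data.frame(id = "F1", lat = 51.352, lon = 4.492),
    recorders = data.frame(id = "R1", lat = 51.35, lon = 4.49),
    gps_error_sd = gps_error_sd)
}

# short night (45 min, fast sessions) for end-to-end smoke tests
quick_night <- function(...) {
  night_config(night_start = "21:00:00", night_end = "21:45:00",
               session_min_s = 180, session_max_s = 420,
               rest_post_meanlog = log(40), rest_post_max_s = 300, ...)
}
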