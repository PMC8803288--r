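test_that("haversine distance behaves and agrees with an independent implementation", {
  expect_equal(haversine_m(51.35, 4.49, 51.35, 4.49), 0)

  # small eastward offset: ~ 111.195 km/deg * cos(lat)
  d <- haversine_m(51.35, 4.49, 51.35, 4.491)
  expect_equal(d, 111194.9 * 0.001 * cos(51.35 * pi / 180), tolerance = 0.01)

  set.seed(14)
  p <- cbind(runif(20, -180, 180), runif(20, -80, 80))
  q <- cbind(runif(20, -180, 180), runif(20, -80, 80))
  mine <- haversine_m(p[, 2], p[, 1], q[, 2], q[, 1])
  ref <- geosphere::distHaversine(p, q, r = 6371000)
  expect_equal(mine, ref, tolerance = 1e-9)
  expect_equal(mine, haversine_m(q[, 2], q[, 1], p[, 2], p[, 1]))  # symmetry

  expect_error(haversine_m(95, 0, 0, 0), "out of range")
})

test_that("bouts are classed near/far by the fix closest to their midpoint", {
  geom <- tiny_geometry()
  rec <- geom$recorders
  # fixes: at the near post (5 m) until t=1000, then at the far post
  p1 <- geom$song_posts[1, ]; p2 <- geom$song_posts[2, ]
  track <- data.frame(time_s = c(0, 500, 1000, 1500),
                      lat = c(p1$lat, p1$lat, p2$lat, p2$lat),
                      lon = c(p1$lon, p1$lon, p2$lon, p2$lon))
  bouts <- data.frame(start_s = c(400, 1400, 50000), end_s = c(450, 1450, 50040))
  got <- bout_distance_class(bouts, track, rec)
  expect_equal(got$distance_class, c("near", "far", NA))
  expect_lt(got$min_distance_m[1], 20)
  expect_gt(got$min_distance_m[2], 20)

  # raising the threshold never moves a bout from near to far
  wide <- bout_distance_class(bouts, track, rec, threshold_m = 1000)
  near_before <- which(got$distance_class == "near")
  expect_true(all(wide$distance_class[near_before] == "near"))
})

test_that("distance classes agree with the true geometry on a synthetic night", {
  geom <- default_site_geometry()
  cfg <- night_config()
  ok <- 0; n <- 0
  for (seed in 1:3) {
    scr <- simulate_behavior_script(cfg, geom, seed = seed)
    gps <- render_gps(scr, geom, seed = seed + 50)
    org <- attr(scr, "origin")
    sing <- scr[scr$behavior == "sing" & scr$end_s - scr$start_s >= 10, ]
    bouts <- data.frame(start_s = org + sing$start_s, end_s = org + sing$end_s)
    got <- bout_distance_class(bouts, gps, geom$recorders)
    cc <- nightsong:::site_coords(geom, sing$location_id)
    truth <- vapply(seq_len(nrow(sing)), function(i)
      min(haversine_m(cc$lat[i], cc$lon[i], geom$recorders$lat,
                      geom$recorders$lon)) < 20, TRUE)
    ok <- ok + sum((got$distance_class == "near") == truth, na.rm = TRUE)
    n <- n + sum(!is.na(got$distance_class))
  }
  expect_gte(ok / n, 0.95)
})

test_that("matching pairs identical and nested tables, leaving no singletons", {
  tab <- data.frame(start_s = c(100, 300, 500), end_s = c(150, 340, 560))
  m <- match_bouts(tab, tab)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$model_only_idx, 0L)
  expect_length(m$audio_only_idx, 0L)

  m2 <- match_bouts(data.frame(start_s = 100, end_s = 130),
                    data.frame(start_s = 101, end_s = 129))
  expect_equal(nrow(m2$pairs), 1L)
  expect_equal(m2$pairs$model_s, 30)
  expect_equal(m2$pairs$audio_s, 28)

  # disjoint beyond tolerance -> no match
  m3 <- match_bouts(data.frame(start_s = 100, end_s = 110),
                    data.frame(start_s = 113, end_s = 120), tol_s = 1)
  expect_equal(nrow(m3$pairs), 0L)
  expect_equal(m3$model_only_idx, 1L)
  expect_equal(m3$audio_only_idx, 1L)
})

test_that("greedy matching attains the optimal one-to-one match count", {
  # brute-force maximum bipartite matching on the same intersect predicate
  max_matching <- function(model, audio, tol_s = 1) {
    nm <- nrow(model); na <- nrow(audio)
    inter <- outer(seq_len(nm), seq_len(na), function(i, j)
      pmin(model$end_s[i], audio$end_s[j]) + 2 * tol_s >
        pmax(model$start_s[i], audio$start_s[j]))
    best <- 0
    rec <- function(i, used, count) {
      if (i > nm) { best <<- max(best, count); return() }
      rec(i + 1, used, count)
      for (j in which(inter[i, ] & !(seq_len(na) %in% used)))
        rec(i + 1, c(used, j), count + 1)
    }
    rec(1, integer(0), 0)
    best
  }
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    starts <- sort(runif(n, 0, 500))
    model <- data.frame(start_s = starts, end_s = starts + runif(n, 10, 40))
    keep <- runif(n) < 0.8
    audio <- data.frame(start_s = model$start_s[keep] + runif(sum(keep), -3, 3),
                        end_s = model$end_s[keep] + runif(sum(keep), -3, 3))
    if (nrow(audio) == 0) next
    got <- match_bouts(model, audio)
    expect_equal(nrow(got$pairs), max_matching(model, audio))
  }
})

test_that("classification accuracy reproduces the worked percentages", {
  expect_equal(round(classification_accuracy(12, 13)), 92)
  expect_equal(round(classification_accuracy(11, 13)), 85)
  expect_equal(classification_accuracy(7, 7), 100)
  expect_error(classification_accuracy(1, 0), "positive")
  expect_error(classification_accuracy(5, 4), "exceed")
})

test_that("the Spearman closed form matches direct rank computation", {
  expect_equal(round(spearman_from_S(21.7, 10), 2), 0.87)
  expect_equal(spearman_from_S(0, 10), 1)
  expect_error(spearman_from_S(1, 1), "at least 2")

  # perfect reversal: S = sum of squared rank differences, rho = -1
  n <- 7
  d2 <- sum((seq_len(n) - rev(seq_len(n)))^2)
  expect_equal(spearman_from_S(d2, n), -1)

  # untied data: closed form from S equals cor() on ranks to 1e-12
  set.seed(23)
  x <- rnorm(15); y <- rnorm(15)
  S <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman_from_S(S, 15), cor(rank(x), rank(y)),
               tolerance = 1e-12)
})

test_that("duration statistics handle exact equality and monotone shifts", {
  eq <- data.frame(model_s = c(12, 25, 40, 18, 33), audio_s = c(12, 25, 40, 18, 33))
  st <- duration_statistics(eq)
  expect_equal(st$wilcoxon$V, 0)
  expect_equal(st$mean_diff_s, 0)

  set.seed(2)
  audio <- sort(rlnorm(8, log(30), 0.5))
  sh <- duration_statistics(data.frame(model_s = audio + 5, audio_s = audio))
  expect_equal(sh$mean_diff_s, 5)
  expect_equal(sh$spearman$rho, 1)

  few <- duration_statistics(data.frame(model_s = c(20, 30), audio_s = c(21, 29)))
  expect_match(few$skipped[["all_pairs"]], "matched pair")
})

test_that("duration statistics agree with independent closed-form computation", {
  set.seed(91)
  audio <- rlnorm(12, log(28), 0.6)
  model <- audio + rnorm(12, 2, 4)
  pairs <- data.frame(model_s = model, audio_s = audio)
  st <- duration_statistics(pairs, min_recorded_s = 20)

  # Spearman rho and S by definition on ranks (no ties with continuous draws)
  rho <- cor(rank(model), rank(audio))
  S <- sum((rank(model) - rank(audio))^2)
  expect_equal(st$spearman$rho, rho, tolerance = 1e-8)
  expect_equal(st$spearman$S, S, tolerance = 1e-8)

  # Wilcoxon V: sum of ranks of |d| over positive differences
  d <- model - audio
  V <- sum(rank(abs(d))[d > 0])
  expect_equal(st$wilcoxon$V, V, tolerance = 1e-8)

  # paired t by closed form on the >= 20 s recorded subset
  sub <- d[audio >= 20]
  tstat <- mean(sub) / (sd(sub) / sqrt(length(sub)))
  expect_equal(st$paired_t$t, tstat, tolerance = 1e-8)
  expect_equal(st$paired_t$df, length(sub) - 1)
  expect_equal(st$paired_t$p,
               2 * pt(abs(tstat), length(sub) - 1, lower.tail = FALSE),
               tolerance = 1e-8)

  # Shapiro-Wilk W cross-checked against the stats routine on each sample
  expect_equal(st$shapiro$model$W, unname(shapiro.test(model)$statistic))
  expect_equal(st$shapiro$audio$W, unname(shapiro.test(audio)$statistic))
})

test_that("the confusion table sums its distance classes into the All row", {
  counts <- data.frame(class = c("near", "far"),
                       n_model = c(12, 56), n_audio = c(11, 4),
                       n_match = c(10, 4), n_model_only = c(2, 52),
                       n_audio_only = c(1, 0))
  tab <- build_table2(counts)
  expect_equal(tab$model, c(12, 56, 68))
  expect_equal(tab$audio, c(11, 4, 15))
  expect_equal(tab$match, c(10, 4, 14))
  expect_equal(tab$model_only, c(2, 52, 54))
  expect_equal(tab$audio_only, c(1, 0, 1))

  empty <- build_table2(data.frame(class = character(0), n_model = integer(0),
                                   n_audio = integer(0), n_match = integer(0),
                                   n_model_only = integer(0),
                                   n_audio_only = integer(0)))
  expect_true(all(as.matrix(empty[, -1]) == 0))

  set.seed(77)
  rnd <- data.frame(class = c("near", "far"),
                    n_model = sample(0:50, 2), n_audio = sample(0:50, 2),
                    n_match = sample(0:20, 2), n_model_only = sample(0:30, 2),
                    n_audio_only = sample(0:10, 2))
  rt <- build_table2(rnd)
  expect_equal(unlist(rt[3, -1]), unlist(rt[1, -1] + rt[2, -1]))
})

test_that("match counts conserve totals in every distance class", {
  set.seed(33)
  model <- data.frame(start_s = sort(runif(8, 0, 1000)))
  model$end_s <- model$start_s + runif(8, 10, 30)
  audio <- data.frame(start_s = model$start_s[c(1, 3, 5)] + 0.5,
                      end_s = model$end_s[c(1, 3, 5)] - 0.5)
  mc <- match_bouts(model, audio)
  model_cls <- rep(c("near", "far"), each = 4)
  audio_cls <- c("near", "near", "far")
  counts <- match_counts(mc, model_cls, audio_cls)
  # every model bout is either matched or model-only, within its own class
  for (r in 1:2) {
    expect_equal(counts$n_model[r], counts$n_match[r] + counts$n_model_only[r])
    expect_equal(counts$n_audio[r], counts$n_match[r] + counts$n_audio_only[r])
    expect_gte(counts$n_model_only[r], 0)
    expect_gte(counts$n_audio_only[r], 0)
  }
  expect_equal(sum(counts$n_model), 8)
  expect_equal(sum(counts$n_audio), 3)
  expect_equal(sum(counts$n_match), nrow(mc$pairs))
})
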