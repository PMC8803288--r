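#' Pipeline configuration
#'
#' All numeric constants of the analysis in one place: 25 Hz sampling, 2-s
#' smoothing window, 4-7 candidate states with the 5-state model pinned by
#' default, 10,000 EM iterations, 10 random restarts, a contiguous 50%
#' training fraction, the 10-s minimum song bout, 1-s subsampling, the 20-m
#' audibility threshold, +/- 1 s matching tolerance, the 20-s recorded-
#' duration cut for the paired t branch and the Shapiro-Wilk W = 0.9 gate.
#'
#' @param sample_rate Accelerometer sampling rate (Hz).
#' @param smooth_window_s Running-mean window (s).
#' @param K_range Candidate state counts.
#' @param K_pinned State count used for classification (`NULL` to choose by
#'   BIC over `K_range`).
#' @param fit_all_K Fit every K in `K_range` (reporting the full BIC table)
#'   even when `K_pinned` is set; default `FALSE` fits only the pinned K.
#' @param max_iter EM iteration cap.
#' @param tol Relative log-likelihood early-stopping tolerance (0 disables
#'   early stopping).
#' @param n_restarts Random restarts per fit.
#' @param train_fraction Fraction of the night used for fitting.
#' @param train_scheme `"contiguous"` (first block of the night, preserving
#'   dwell-time structure) or `"alternating"` (every other 10-min block).
#' @param fit_signal `"dynamic"` (movement-induced component; default) or
#'   `"smoothed"`.
#' @param min_sing_s Minimum retained song-bout duration (s).
#' @param filter_order `"after_subsample"` (1-s grid, default) or
#'   `"before_subsample"` (10-s rule applied to the 25 Hz label runs).
#' @param subsample_s Label grid spacing (s).
#' @param threshold_m Near/far distance threshold (m).
#' @param match_tol_s Bout-matching timing tolerance (s).
#' @param min_recorded_s Recorded-duration threshold of the t-test subset (s).
#' @param shapiro_cutoff Shapiro-Wilk W normality gate.
#' @param sigma_floor Emission sd floor (g).
#' @param master_seed Master seed; every stage draws a named sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_rate = 25, smooth_window_s = 2,
                            K_range = 4:7, K_pinned = 5, fit_all_K = FALSE,
                            max_iter = 10000, tol = 1e-6, n_restarts = 10,
                            train_fraction = 0.5, train_scheme = "contiguous",
                            fit_signal = "dynamic",
                            min_sing_s = 10, filter_order = "after_subsample",
                            subsample_s = 1, threshold_m = 20,
                            match_tol_s = 1, min_recorded_s = 20,
                            shapiro_cutoff = 0.9, sigma_floor = 1e-4,
                            master_seed = 1) {
  stopifnot(sample_rate > 0, smooth_window_s > 0, max_iter >= 1,
            n_restarts >= 1, train_fraction > 0, train_fraction <= 1,
            min_sing_s > 0, subsample_s > 0, threshold_m > 0,
            match_tol_s >= 0, min_recorded_s > 0)
  train_scheme <- match.arg(train_scheme, c("contiguous", "alternating"))
  fit_signal <- match.arg(fit_signal, c("dynamic", "smoothed"))
  filter_order <- match.arg(filter_order, c("after_subsample", "before_subsample"))
  if (!is.null(K_pinned) && !K_pinned %in% K_range)
    stop("K_pinned must lie in K_range")
  structure(as.list(environment()), class = "pipeline_config")
}

# named per-stage sub-seeds derived from the master seed (kept within the
# 32-bit integer range)
stage_seed <- function(master_seed, stage) {
  offs <- c(script = 11L, accel = 23L, gps = 37L, audio = 53L, fit = 71L)
  as.integer((as.numeric(master_seed) * 1009 + offs[[stage]]) %% 2147483647)
}

# training subset of the dynamic signal
training_obs <- function(obs, fraction, scheme, rate, block_s = 600) {
  n <- length(obs)
  if (fraction >= 1) return(obs)
  if (scheme == "contiguous") return(obs[seq_len(floor(n * fraction))])
  block <- max(1L, as.integer(block_s * rate))
  idx <- which(((seq_len(n) - 1) %/% block) %% round(1 / fraction) == 0)
  obs[idx]
}

#' Run the full synthetic-night pipeline
#'
#' simulate -> preprocess -> fit -> classify -> validate. Generates a seeded
#' synthetic night (behavior script, acceleration trace, GPS track, audio
#' ground truth), decomposes the acceleration, fits the Gaussian HMM on the
#' training fraction of the dynamic signal, Viterbi-decodes the whole night,
#' maps states to behaviors, extracts song bouts with the 10-s rule, and
#' validates them against the audio truth gated by GPS distance to the
#' recorders. Deterministic given `config$master_seed`.
#'
#' @param config A [pipeline_config()].
#' @param night A [night_config()].
#' @param emission An [emission_spec()].
#' @param geometry A [site_geometry()].
#' @param out_dir Optional directory to write artifacts into (labels, bouts,
#'   model, GPS, recorders, audio truth, confusion table, summary, log).
#' @param write_accel Also write the (large) accelerometer CSV when
#'   `out_dir` is set (default `FALSE`).
#' @return A `nightsong_run` list: `script`, `trace`, `gps`, `audio_truth`,
#'   `fit`, `model_table` (BIC table or `NULL`), `state_map`, `labels`,
#'   `bouts`, `song_bouts` (with distance columns), `matching`, `counts`,
#'   `table2`, `summary`, `duration_stats`, `truth` (per-second truth
#'   labels), `agreement` (per-second behavior agreement with the truth),
#'   `sing_jaccard` (overlap of retained song seconds with true song
#'   seconds), `seeds`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), night = night_config(),
                         emission = emission_spec(),
                         geometry = default_site_geometry(),
                         out_dir = NULL, write_accel = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- vapply(c("script", "accel", "gps", "audio", "fit"),
                  function(s) stage_seed(config$master_seed, s), 0L)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  say("simulate: master_seed=%d seeds=[%s]", config$master_seed,
      paste(names(seeds), seeds, sep = "=", collapse = " "))
  script <- simulate_behavior_script(night, geometry, seed = seeds[["script"]])
  trace <- render_acceleration(script, emission, seed = seeds[["accel"]])
  gps <- render_gps(script, geometry, seed = seeds[["gps"]])
  audio <- render_audio_truth(script, geometry, seed = seeds[["audio"]],
                              audible_m = config$threshold_m,
                              min_bout_s = config$min_sing_s,
                              miss_prob = night$audio_miss_prob)
  say("simulate: %d intervals, %d accel samples, %d fixes, %d audio bouts",
      nrow(script), nrow(trace), nrow(gps), nrow(audio))

  dyn <- dynamic_acceleration(trace, window_s = config$smooth_window_s)
  obs_full <- if (config$fit_signal == "dynamic") dyn$accel_g
              else running_mean(trace, config$smooth_window_s)$accel_g
  obs_train <- training_obs(obs_full, config$train_fraction,
                            config$train_scheme, config$sample_rate)
  say("preprocess: fit signal = %s, training on %d of %d samples (%s)",
      config$fit_signal, length(obs_train), length(obs_full),
      config$train_scheme)

  model_table <- NULL
  if (is.null(config$K_pinned) || config$fit_all_K) {
    sel <- select_model(obs_train, K_range = config$K_range,
                        K_pinned = config$K_pinned,
                        n_restarts = config$n_restarts,
                        seed_base = seeds[["fit"]],
                        max_iter = config$max_iter, tol = config$tol)
    model_table <- sel$table
    fit <- sel$fits[[paste0("K", sel$chosen_K)]]
    say("fit: chose K=%d (BIC over K in {%s})", sel$chosen_K,
        paste(config$K_range, collapse = ","))
  } else {
    fit <- fit_with_restarts(config$K_pinned, obs_train,
                             n_restarts = config$n_restarts,
                             seed_base = seeds[["fit"]],
                             max_iter = config$max_iter, tol = config$tol,
                             sigma_floor = config$sigma_floor)
    say("fit: K=%d pinned, %d restarts, best loglik %.2f (%d iterations)",
        config$K_pinned, config$n_restarts, fit$loglik, fit$n_iter)
  }

  states <- viterbi(fit$model, obs_full)
  map <- map_states_to_behaviors(fit$model, states)
  say("classify: state map [%s]", paste(names(map), map, sep = "->", collapse = " "))

  t0 <- trace$time_s[1]
  if (config$filter_order == "before_subsample") {
    beh25 <- map[as.character(states)]
    r <- rle(beh25)
    short <- r$values == "sing" & r$lengths < config$min_sing_s * config$sample_rate
    r$values[short] <- "rest"
    labels <- subsample_to_1s(inverse.rle(r), identity_map(),
                              t0 = t0, rate = config$sample_rate)
    bouts <- extract_bouts(labels)
  } else {
    labels <- subsample_to_1s(states, map, t0 = t0, rate = config$sample_rate)
    bouts <- extract_bouts(labels)
  }
  bouts <- filter_song_bouts(bouts, min_sing_s = config$min_sing_s)
  sng <- song_bouts(bouts)
  say("classify: %d bouts, %d song bouts of >= %g s", nrow(bouts), nrow(sng),
      config$min_sing_s)

  sng <- bout_distance_class(sng, gps, geometry$recorders,
                             threshold_m = config$threshold_m)
  audio_cls <- if (nrow(audio) > 0) {
    bout_distance_class(data.frame(start_s = audio$begin_s, end_s = audio$end_s),
                        gps, geometry$recorders,
                        threshold_m = config$threshold_m)$distance_class
  } else character(0)
  matching <- match_bouts(data.frame(start_s = sng$start_s, end_s = sng$end_s),
                          data.frame(start_s = audio$begin_s, end_s = audio$end_s),
                          tol_s = config$match_tol_s)
  counts <- match_counts(matching, sng$distance_class, audio_cls)
  table2 <- build_table2(counts, threshold_m = config$threshold_m)
  summ <- validation_summary(table2)
  dstats <- duration_statistics(matching$pairs,
                                min_recorded_s = config$min_recorded_s,
                                shapiro_cutoff = config$shapiro_cutoff)

  truth <- script_to_labels(script, step_s = config$subsample_s)
  m <- min(nrow(truth), nrow(labels))
  agreement <- mean(truth$behavior[seq_len(m)] == labels$behavior[seq_len(m)])
  jac <- sing_second_jaccard(sng, script)
  say("validate: agreement=%.3f jaccard=%.3f accuracy=%.1f%%",
      agreement, jac, summ$accuracy_pct)

  run <- structure(list(script = script, trace = trace, gps = gps,
                        audio_truth = audio, fit = fit,
                        model_table = model_table, state_map = map,
                        labels = labels, bouts = bouts, song_bouts = sng,
                        matching = matching, counts = counts, table2 = table2,
                        summary = summ, duration_stats = dstats,
                        truth = truth, agreement = agreement,
                        sing_jaccard = jac, seeds = seeds, log = log,
                        config = config),
                   class = "nightsong_run")
  if (!is.null(out_dir)) write_run(run, out_dir, geometry, write_accel)
  run
}

identity_map <- function() {
  structure(BEHAVIORS, names = BEHAVIORS)
}

# Jaccard index between retained model song seconds and true song intervals
sing_second_jaccard <- function(model_song_bouts, script) {
  origin <- attr(script, "origin")
  night <- attr(script, "night_seconds")
  secs <- seq(0, night - 1)
  truth <- script_behavior_at(script, secs + 0.5) == "sing"
  pred <- rep(FALSE, length(secs))
  for (i in seq_len(nrow(model_song_bouts))) {
    a <- floor(model_song_bouts$start_s[i] - origin)
    b <- ceiling(model_song_bouts$end_s[i] - origin) - 1
    idx <- seq(max(a, 0), min(b, night - 1)) + 1
    pred[idx] <- TRUE
  }
  un <- sum(truth | pred)
  if (un == 0) return(NA_real_)
  sum(truth & pred) / un
}

write_run <- function(run, out_dir, geometry, write_accel = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (write_accel) write_accel_csv(run$trace, p("accel.csv"))
  write_gps_csv(run$gps, p("gps.csv"))
  write_recorders_csv(geometry$recorders, p("recorders.csv"))
  write_bout_tsv(run$audio_truth, p("audio_bouts.tsv"))
  write_labels_csv(run$labels, p("labels.csv"))
  write_labels_csv(run$truth, p("truth_labels.csv"))
  sb <- run$song_bouts
  write_bout_tsv(data.frame(recorder_id = ifelse(is.na(sb$nearest_recorder),
                                                 "unlocated", sb$nearest_recorder),
                            begin_s = sb$start_s, end_s = sb$end_s),
                 p("model_song_bouts.tsv"))
  write_model(run$fit$model, p("model.txt"), seed = run$fit$seed,
              loglik = run$fit$loglik)
  write.table(run$table2, p("confusion_table.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  summ <- c(run$summary,
            list(agreement = run$agreement, sing_jaccard = run$sing_jaccard,
                 n_pairs = run$duration_stats$n,
                 mean_diff_s = run$duration_stats$mean_diff_s,
                 spearman_rho = run$duration_stats$spearman$rho %||% NA,
                 spearman_S = run$duration_stats$spearman$S %||% NA,
                 spearman_p = run$duration_stats$spearman$p %||% NA,
                 wilcoxon_V = run$duration_stats$wilcoxon$V %||% NA,
                 wilcoxon_p = run$duration_stats$wilcoxon$p %||% NA,
                 t_stat = run$duration_stats$paired_t$t %||% NA,
                 t_df = run$duration_stats$paired_t$df %||% NA,
                 t_p = run$duration_stats$paired_t$p %||% NA))
  writeLines(paste(names(summ), vapply(summ, function(v)
    sprintf("%.10g", as.numeric(v)), ""), sep = "\t"), p("summary.tsv"))
  writeLines(run$log, p("run.log"))
  invisible(out_dir)
}

#' @export
print.nightsong_run <- function(x, ...) {
  cat("Synthetic-night pipeline run\n")
  cat(sprintf("  %d script intervals, %d song bouts classified\n",
              nrow(x$script), nrow(song_bouts(x$bouts))))
  cat(sprintf("  per-second agreement with truth: %.1f%%; song Jaccard: %.2f\n",
              100 * x$agreement, x$sing_jaccard))
  print(x$table2)
  cat(sprintf("  accuracy %.0f%%, near-class audio detection %.0f%%, overall %.0f%%\n",
              x$summary$accuracy_pct, x$summary$audio_detection_near_pct,
              x$summary$audio_detection_all_pct))
  invisible(x)
}
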