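#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorized with
#' recycling.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(sqrt(a), 1))
}

#' Distance class of a bout relative to the audio recorders
#'
#' Locates a bout at the GPS fix nearest in time to its midpoint, takes the
#' minimum distance to any recorder, and classes the bout as `near` when that
#' distance is below `threshold_m`. A bout with no fix within `max_fix_gap_s`
#' of its midpoint is flagged unlocatable (`NA` class) and excluded from
#' distance-gated counts: brief stationarity between flights can leave the
#' true song post unregistered by a 3-min GPS schedule.
#'
#' @param bouts A `bouts` data.frame (or any data.frame with `start_s`,
#'   `end_s`).
#' @param track A `gps_track` data.frame (`time_s`, `lat`, `lon`).
#' @param recorders data.frame with `id`, `lat`, `lon`.
#' @param threshold_m Near/far threshold in meters (default 20).
#' @param max_fix_gap_s Maximum fix-to-midpoint time gap (default 900 s).
#' @return The input with columns `nearest_recorder`, `min_distance_m`,
#'   `distance_class` (`"near"`, `"far"`, or `NA`) appended.
#' @export
bout_distance_class <- function(bouts, track, recorders, threshold_m = 20,
                                max_fix_gap_s = 900) {
  stopifnot(is.data.frame(track), nrow(track) >= 1,
            all(c("time_s", "lat", "lon") %in% names(track)),
            all(c("id", "lat", "lon") %in% names(recorders)))
  mid <- (bouts$start_s + bouts$end_s) / 2
  nearest <- character(nrow(bouts))
  dist_m <- rep(NA_real_, nrow(bouts))
  cls <- rep(NA_character_, nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    j <- which.min(abs(track$time_s - mid[i]))
    if (abs(track$time_s[j] - mid[i]) > max_fix_gap_s) {
      nearest[i] <- NA_character_
      next
    }
    d <- haversine_m(track$lat[j], track$lon[j], recorders$lat, recorders$lon)
    k <- which.min(d)
    nearest[i] <- recorders$id[k]
    dist_m[i] <- d[k]
    cls[i] <- if (d[k] < threshold_m) "near" else "far"
  }
  bouts$nearest_recorder <- nearest
  bouts$min_distance_m <- dist_m
  bouts$distance_class <- cls
  bouts
}

# interval-overlap matrix after expanding both sides by tol_s; >0 means the
# expanded intervals intersect
expanded_overlap <- function(m_start, m_end, a_start, a_end, tol_s) {
  outer(seq_along(m_start), seq_along(a_start), function(i, j) {
    pmin(m_end[i] + tol_s, a_end[j] + tol_s) -
      pmax(m_start[i] - tol_s, a_start[j] - tol_s)
  })
}

#' Match model song bouts to audio-annotated bouts
#'
#' Greedy one-to-one matching by descending overlap after expanding every
#' interval by the `tol_s` annotation uncertainty: the pair with the largest
#' expanded overlap is matched first, both bouts are removed, and so on. A
#' pair is eligible only if its expanded intervals intersect. Unmatched model
#' bouts are "model only" (no audio confirmation); unmatched audio bouts are
#' "audio only" (song the model missed).
#'
#' @param model_bouts,audio_bouts data.frames with `start_s`, `end_s` on the
#'   same (GMT epoch) clock.
#' @param tol_s Timing tolerance in seconds (default 1).
#' @return A `bout_matching` list: `pairs` (data.frame `model_idx`,
#'   `audio_idx`, `model_s`, `audio_s`), `model_only_idx`, `audio_only_idx`.
#' @export
match_bouts <- function(model_bouts, audio_bouts, tol_s = 1) {
  nm <- nrow(model_bouts); na <- nrow(audio_bouts)
  pairs <- data.frame(model_idx = integer(0), audio_idx = integer(0),
                      model_s = numeric(0), audio_s = numeric(0))
  if (nm > 0 && na > 0) {
    ov <- expanded_overlap(model_bouts$start_s, model_bouts$end_s,
                           audio_bouts$start_s, audio_bouts$end_s, tol_s)
    ov[ov <= 0] <- NA
    while (any(is.finite(ov))) {
      k <- arrayInd(which.max(ov), dim(ov))
      i <- k[1]; j <- k[2]
      pairs <- rbind(pairs, data.frame(
        model_idx = i, audio_idx = j,
        model_s = model_bouts$end_s[i] - model_bouts$start_s[i],
        audio_s = audio_bouts$end_s[j] - audio_bouts$start_s[j]))
      ov[i, ] <- NA
      ov[, j] <- NA
    }
  }
  structure(list(pairs = pairs,
                 model_only_idx = setdiff(seq_len(nm), pairs$model_idx),
                 audio_only_idx = setdiff(seq_len(na), pairs$audio_idx)),
            class = "bout_matching")
}

#' Confusion counts by distance class
#'
#' Tabulates, for each distance class, the number of model-classified song
#' bouts, audio-recorded bouts, matches, and singletons on either side.
#' Matched pairs are counted in the class of the model bout — a matched
#' audio bout follows its pair, since both sides were gated by the same GPS
#' fixes — and singletons in their own bout's class, so
#' `n_model = n_match + n_model_only` and `n_audio = n_match + n_audio_only`
#' hold within every class. Bouts with `NA` class are excluded.
#'
#' @param matching A `bout_matching` from [match_bouts()].
#' @param model_class,audio_class Character vectors (`"near"`/`"far"`/`NA`)
#'   classifying each model and audio bout, e.g. from
#'   [bout_distance_class()].
#' @return A `match_counts` data.frame with rows `near` and `far` and columns
#'   `n_model`, `n_audio`, `n_match`, `n_model_only`, `n_audio_only`.
#' @export
match_counts <- function(matching, model_class, audio_class) {
  stopifnot(inherits(matching, "bout_matching"))
  cnt <- function(cls) {
    pair_in <- !is.na(model_class[matching$pairs$model_idx]) &
      model_class[matching$pairs$model_idx] == cls
    n_match <- sum(pair_in)
    n_model_only <- sum(model_class[matching$model_only_idx] == cls, na.rm = TRUE)
    n_audio_only <- sum(audio_class[matching$audio_only_idx] == cls, na.rm = TRUE)
    data.frame(
      class = cls,
      n_model = n_match + n_model_only,
      n_audio = n_match + n_audio_only,
      n_match = n_match,
      n_model_only = n_model_only,
      n_audio_only = n_audio_only)
  }
  out <- rbind(cnt("near"), cnt("far"))
  structure(out, class = c("match_counts", "data.frame"))
}

#' Assemble the distance-classed confusion table
#'
#' Formats per-class confusion counts as the three-row table of the
#' validation summary: one row per distance class (`<20`, `>20`) and an `All`
#' row equal to the column sums of the other two.
#'
#' @param counts A `match_counts` data.frame (rows `near`, `far`), or any
#'   data.frame with columns `class`, `n_model`, `n_audio`, `n_match`,
#'   `n_model_only`, `n_audio_only`.
#' @param threshold_m Threshold used for the row labels (default 20).
#' @return data.frame with columns `distance`, `model`, `audio`, `match`,
#'   `model_only`, `audio_only` and rows `<20`, `>20`, `All`.
#' @export
build_table2 <- function(counts, threshold_m = 20) {
  need <- c("class", "n_model", "n_audio", "n_match", "n_model_only", "n_audio_only")
  stopifnot(all(need %in% names(counts)))
  near <- counts[counts$class == "near", , drop = FALSE]
  far <- counts[counts$class == "far", , drop = FALSE]
  row0 <- function() data.frame(class = NA, n_model = 0, n_audio = 0,
                                n_match = 0, n_model_only = 0, n_audio_only = 0)
  if (nrow(near) == 0) near <- row0()
  if (nrow(far) == 0) far <- row0()
  num <- c("n_model", "n_audio", "n_match", "n_model_only", "n_audio_only")
  all_row <- near[num] + far[num]
  out <- data.frame(distance = c(sprintf("<%g", threshold_m),
                                 sprintf(">%g", threshold_m), "All"),
                    rbind(near[num], far[num], all_row))
  names(out) <- c("distance", "model", "audio", "match", "model_only", "audio_only")
  rownames(out) <- NULL
  out
}

#' Song-classification accuracy
#'
#' Percentage of true song bouts the model classified as song:
#' `100 * n_detected_by_model / n_true`. In the validation arithmetic,
#' `n_true` is the model's near-recorder bout count corrected upward by the
#' audio-only bouts (false negatives evident on the recordings).
#'
#' @param n_detected_by_model Bouts the model classified as song.
#' @param n_true True song bouts (>= `n_detected_by_model`, > 0).
#' @return Percentage (0-100).
#' @export
classification_accuracy <- function(n_detected_by_model, n_true) {
  stopifnot(n_detected_by_model >= 0)
  if (n_true <= 0) stop("n_true must be positive")
  if (n_detected_by_model > n_true)
    stop("n_detected_by_model cannot exceed n_true")
  100 * n_detected_by_model / n_true
}

#' Spearman rank correlation from the S statistic
#'
#' Closed form `rho = 1 - 6 S / (n (n^2 - 1))`, where `S` is the sum of
#' squared rank differences (possibly tie-corrected and hence non-integer).
#'
#' @param S Rank statistic, >= 0.
#' @param n Number of pairs, >= 2.
#' @return The rank correlation coefficient.
#' @export
spearman_from_S <- function(S, n) {
  stopifnot(S >= 0)
  if (n < 2) stop("need at least 2 pairs")
  1 - 6 * S / (n * (n^2 - 1))
}

#' Summary percentages of the confusion table
#'
#' The worked validation arithmetic: classification accuracy
#' (near-class model bouts over the audio-corrected truth), the audio
#' detection rate of near-class bouts, the far-class and overall fractions of
#' model bouts that the recorders captured.
#'
#' @param table2 Output of [build_table2()].
#' @return List of raw percentages (`accuracy_pct`, `audio_detection_near_pct`,
#'   `audio_detection_far_pct`, `audio_detection_all_pct`) plus `n_true_near`,
#'   the corrected near-class truth count.
#' @export
validation_summary <- function(table2) {
  near <- table2[table2$distance != "All" & grepl("^<", table2$distance), ]
  far <- table2[grepl("^>", table2$distance), ]
  all <- table2[table2$distance == "All", ]
  n_true_near <- near$model + near$audio_only
  list(
    n_true_near = n_true_near,
    accuracy_pct = classification_accuracy(near$model, n_true_near),
    audio_detection_near_pct = 100 * near$audio / n_true_near,
    audio_detection_far_pct = if (far$model > 0) 100 * far$audio / far$model else NA_real_,
    audio_detection_all_pct = if (all$model > 0) 100 * all$audio / all$model else NA_real_)
}

#' Duration statistics for matched song-bout pairs
#'
#' Compares model and audio bout durations: Shapiro-Wilk normality check on
#' each duration sample; when either `W` falls below `shapiro_cutoff` the
#' durations are treated as non-normal and a Spearman rank correlation plus a
#' Wilcoxon signed-rank test are run on all pairs; a paired t test (df =
#' n - 1) is run on the subset with recorded (audio) duration of at least
#' `min_recorded_s`, where durations are close enough to normal. All
#' p-values are two-sided; the Wilcoxon uses the exact distribution for
#' n <= 25 and the normal approximation with continuity correction above. A
#' branch with too few pairs is skipped with the reason recorded.
#'
#' @param pairs data.frame with columns `model_s`, `audio_s` (durations in
#'   seconds of matched bouts).
#' @param min_recorded_s Audio-duration threshold of the t-test subset
#'   (default 20).
#' @param shapiro_cutoff Shapiro-Wilk W below which durations are treated as
#'   non-normal (default 0.9).
#' @param min_pairs Minimum pairs per test branch (default 3).
#' @return A `duration_stats` list: `n`, `mean_diff_s`, `shapiro`
#'   (W and p per sample), `spearman` (rho, S, n, p), `wilcoxon` (V, n, p),
#'   `paired_t` (t, df, n, p, mean_diff_s), `skipped` (named reasons).
#' @export
duration_statistics <- function(pairs, min_recorded_s = 20,
                                shapiro_cutoff = 0.9, min_pairs = 3) {
  stopifnot(all(c("model_s", "audio_s") %in% names(pairs)))
  n <- nrow(pairs)
  skipped <- character(0)
  out <- list(n = n, mean_diff_s = if (n > 0) mean(pairs$model_s - pairs$audio_s) else NA_real_,
              shapiro = NULL, spearman = NULL, wilcoxon = NULL, paired_t = NULL)

  if (n >= min_pairs) {
    sh <- function(x) {
      if (length(unique(x)) < 3) return(list(W = NA_real_, p = NA_real_))
      s <- shapiro.test(x)
      list(W = unname(s$statistic), p = s$p.value)
    }
    out$shapiro <- list(model = sh(pairs$model_s), audio = sh(pairs$audio_s))

    ct <- suppressWarnings(cor.test(pairs$model_s, pairs$audio_s,
                                    method = "spearman", exact = FALSE))
    out$spearman <- list(rho = unname(ct$estimate), S = unname(ct$statistic),
                         n = n, p = ct$p.value)

    d <- pairs$model_s - pairs$audio_s
    if (all(d == 0)) {
      out$wilcoxon <- list(V = 0, n = n, p = 1)
    } else {
      wt <- suppressWarnings(wilcox.test(pairs$model_s, pairs$audio_s,
                                         paired = TRUE, exact = n <= 25,
                                         correct = TRUE))
      out$wilcoxon <- list(V = unname(wt$statistic), n = n, p = wt$p.value)
    }
  } else {
    skipped <- c(skipped, all_pairs = sprintf(
      "only %d matched pair(s); need %d for the correlation and signed-rank branch",
      n, min_pairs))
  }

  sub <- pairs[pairs$audio_s >= min_recorded_s, , drop = FALSE]
  dsub <- sub$model_s - sub$audio_s
  if (nrow(sub) >= min_pairs &&
      stats::sd(dsub) > 1e-9 * max(1, abs(mean(dsub)))) {
    tt <- t.test(sub$model_s, sub$audio_s, paired = TRUE)
    out$paired_t <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                         n = nrow(sub), p = tt$p.value,
                         mean_diff_s = mean(dsub))
  } else {
    skipped <- c(skipped, long_bouts = sprintf(
      "only %d pair(s) with recorded duration >= %g s (or zero variance); paired t skipped",
      nrow(sub), min_recorded_s))
  }
  out$skipped <- skipped
  structure(out, class = "duration_stats")
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf("Matched song-bout duration comparison (n = %d)\n", x$n))
  if (!is.null(x$spearman))
    cat(sprintf("  Spearman: rho = %.3f, S = %.4g, p = %.4g\n",
                x$spearman$rho, x$spearman$S, x$spearman$p))
  if (!is.null(x$wilcoxon))
    cat(sprintf("  Wilcoxon signed-rank: V = %.1f, p = %.4g; mean diff %.2f s\n",
                x$wilcoxon$V, x$wilcoxon$p, x$mean_diff_s))
  if (!is.null(x$paired_t))
    cat(sprintf("  Paired t (audio >= threshold): t = %.3f, df = %d, p = %.4g\n",
                x$paired_t$t, x$paired_t$df, x$paired_t$p))
  for (s in x$skipped) cat("  [skipped] ", s, "\n", sep = "")
  invisible(x)
}
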