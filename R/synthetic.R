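#' Generator configuration for a synthetic night
#'
#' Parameters of the seeded synthetic-night generator: the night span, the
#' dwell-time distributions of the behavior script, and movement rates. The
#' script is semi-Markov — each behavior has an explicit bout-duration
#' distribution — because real bout durations are strongly non-geometric
#' (song bouts range from seconds to several minutes), which is what makes
#' the 10-s song filter and the duration statistics meaningful.
#'
#' Song-bout durations default to a lognormal with median 25 s (sdlog 0.9)
#' truncated to 11-204 s, the duration regime of nocturnal churring song in
#' July. Leaps are brief foraging bursts of 1-5 s.
#'
#' @param date Night start date (GMT), `"YYYY-MM-DD"`.
#' @param night_start,night_end Clock times (GMT) bounding the recording
#'   night; `night_end` earlier than `night_start` rolls over midnight.
#' @param sing_meanlog,sing_sdlog,sing_min_s,sing_max_s Truncated-lognormal
#'   song-bout duration parameters (seconds).
#' @param rest_post_meanlog,rest_post_sdlog,rest_post_min_s,rest_post_max_s
#'   Rest-bout durations at song posts (truncated lognormal, seconds).
#' @param rest_patch_min_s,rest_patch_max_s Uniform rest durations between
#'   leaps at foraging patches (seconds).
#' @param leap_min_s,leap_max_s Uniform leap-burst durations (seconds).
#' @param session_min_s,session_max_s Uniform dwell at one site before
#'   commuting to another (seconds).
#' @param p_sing Probability a rest bout at a song post is followed by song.
#' @param p_leap Probability a rest bout at a patch is followed by a leap.
#' @param p_fly Probability the bird commutes to a new site when a session
#'   ends (0 pins it to its first site for the whole night).
#' @param p_post Probability the next site is a song post rather than a
#'   foraging patch.
#' @param fly_speed_mps Commuting flight speed (m/s); flight duration is
#'   site-to-site distance over speed, at least `fly_min_s`.
#' @param fly_min_s Minimum flight duration (seconds).
#' @param audio_miss_prob Probability an audible song bout is missing from
#'   the ground-truth annotation table (detection failure; default 0 so the
#'   truth is exact).
#' @return A `night_config` list.
#' @export
night_config <- function(date = "2019-07-23",
                         night_start = "21:00:00", night_end = "06:00:00",
                         sing_meanlog = log(25), sing_sdlog = 0.9,
                         sing_min_s = 11, sing_max_s = 204,
                         rest_post_meanlog = log(90), rest_post_sdlog = 0.7,
                         rest_post_min_s = 10, rest_post_max_s = 1200,
                         rest_patch_min_s = 15, rest_patch_max_s = 60,
                         leap_min_s = 1, leap_max_s = 5,
                         session_min_s = 600, session_max_s = 1500,
                         p_sing = 0.7, p_leap = 0.5, p_fly = 1, p_post = 0.7,
                         fly_speed_mps = 10, fly_min_s = 5,
                         audio_miss_prob = 0) {
  cfg <- as.list(environment())
  dur <- c(sing_min_s = sing_min_s, sing_max_s = sing_max_s,
           rest_post_min_s = rest_post_min_s, rest_post_max_s = rest_post_max_s,
           rest_patch_min_s = rest_patch_min_s, rest_patch_max_s = rest_patch_max_s,
           leap_min_s = leap_min_s, leap_max_s = leap_max_s,
           session_min_s = session_min_s, session_max_s = session_max_s,
           fly_speed_mps = fly_speed_mps, fly_min_s = fly_min_s)
  if (any(dur <= 0)) stop("duration parameters must be positive: ",
                          paste(names(dur)[dur <= 0], collapse = ", "))
  stopifnot(sing_max_s > sing_min_s, session_max_s >= session_min_s,
            p_sing >= 0, p_sing <= 1, p_leap >= 0, p_leap <= 1,
            p_fly >= 0, p_fly <= 1, audio_miss_prob >= 0, audio_miss_prob <= 1)
  origin <- as.numeric(as.POSIXct(paste(date, night_start), tz = "GMT"))
  end_t <- as.numeric(as.POSIXct(paste(date, night_end), tz = "GMT"))
  if (end_t <= origin) end_t <- end_t + 86400
  cfg$origin <- origin
  cfg$night_seconds <- end_t - origin
  structure(cfg, class = "night_config")
}

#' Site geometry for a synthetic night
#'
#' Fixed coordinates (WGS84 decimal degrees) of song posts, foraging patches
#' and stationary audio recorders, plus the GPS error scale. The default
#' layout places one song post within the 20-m audibility radius of a
#' recorder and the remaining posts beyond it, so both distance classes of
#' the validation are exercised.
#'
#' GPS error is isotropic with a half-normal radial magnitude of scale
#' `gps_error_sd` (default `20 / 1.96` m), so that ~95% of fixes fall within
#' 20 m of the true position — the stated +/- 20 m spatial error read as a
#' 95% radius.
#'
#' @param song_posts,foraging_patches,recorders data.frames with columns
#'   `id`, `lat`, `lon`.
#' @param gps_error_sd Radial GPS error scale in meters.
#' @return A `site_geometry` list.
#' @export
site_geometry <- function(song_posts, foraging_patches, recorders,
                          gps_error_sd = 20 / 1.96) {
  for (d in list(song_posts, foraging_patches, recorders))
    stopifnot(is.data.frame(d), all(c("id", "lat", "lon") %in% names(d)))
  stopifnot(gps_error_sd >= 0, nrow(song_posts) >= 1, nrow(recorders) >= 1)
  dmin <- vapply(seq_len(nrow(song_posts)), function(i)
    min(haversine_m(song_posts$lat[i], song_posts$lon[i],
                    recorders$lat, recorders$lon)), 0)
  if (!any(dmin < 20) || !any(dmin > 20))
    stop("geometry must contain at least one song post within 20 m of a ",
         "recorder and at least one farther than 20 m from all recorders")
  ids <- c(song_posts$id, foraging_patches$id)
  if (anyDuplicated(ids)) stop("site ids must be unique")
  sites <- rbind(cbind(song_posts[c("id", "lat", "lon")], type = "post"),
                 cbind(foraging_patches[c("id", "lat", "lon")], type = "patch"))
  structure(list(song_posts = song_posts, foraging_patches = foraging_patches,
                 recorders = recorders, gps_error_sd = gps_error_sd,
                 sites = sites),
            class = "site_geometry")
}

#' @rdname site_geometry
#' @export
default_site_geometry <- function() {
  # around Klein Schietveld (51.35 N, 4.49 E); P1 sits ~5 m from recorder R1
  # (well inside the 20-m audibility radius even under GPS error), all other
  # sites are well beyond 20 m of both recorders
  posts <- data.frame(id = c("P1", "P2", "P3"),
                      lat = c(51.350045, 51.35000, 51.34800),
                      lon = c(4.49000, 4.49216, 4.48600))
  patches <- data.frame(id = c("F1", "F2"),
                        lat = c(51.35400, 51.34600),
                        lon = c(4.49500, 4.48300))
  recorders <- data.frame(id = c("R1", "R2"),
                          lat = c(51.35000, 51.35200),
                          lon = c(4.49000, 4.49300))
  site_geometry(posts, patches, recorders)
}

#' Emission specification for the synthetic acceleration forward model
#'
#' Behavior-specific generative parameters for the dynamic acceleration
#' component, plus a slowly varying static (gravity/tag-angle) component.
#' Effective dynamic standard deviations must be ordered
#' `sigma_rest < sigma_sing < sigma_fly` (quiet rest, medium-amplitude body
#' vibration during song, strong wingbeat signal in flight); leaps are brief
#' bursts stronger still. Rest has two sub-regimes — deep rest
#' (`sigma_rest_deep`) and alert rest (`sigma_rest`), drawn per rest
#' interval — mirroring the two inactive states of the five-state
#' classification. Song is rendered as zero-mean band-limited noise rather
#' than an explicit trill tone: the trill repetition rate exceeds the
#' 12.5 Hz Nyquist limit of 25 Hz sampling, so what the tag records is the
#' aliased/envelope energy, characterized only by its amplitude. Flight
#' carries a 6 Hz wingbeat sinusoid (below Nyquist) holding
#' `wingbeat_tone_share` of the flight variance.
#'
#' @param sigma_rest,sigma_sing,sigma_fly,sigma_leap Effective dynamic sds
#'   (g) per behavior; `sigma_rest` is the louder (alert) rest regime.
#' @param sigma_rest_deep Deep-rest dynamic sd (g), below `sigma_rest`.
#' @param p_deep_rest Probability a rest interval is deep rest.
#' @param wingbeat_hz Wingbeat frequency (Hz), below the 12.5 Hz Nyquist
#'   limit.
#' @param wingbeat_tone_share Fraction of flight variance carried by the
#'   wingbeat sinusoid (the rest is noise).
#' @param static_walk_sd Per-sample sd (g) of the bounded random walk forming
#'   the static component; its correlation time is far above the 2-s
#'   smoothing window, so running-mean subtraction removes it.
#' @param static_start Starting value (g) of the static component.
#' @param sample_rate Sampling rate, fixed at 25 Hz.
#' @return An `emission_spec` list.
#' @export
emission_spec <- function(sigma_rest = 0.012, sigma_sing = 0.05,
                          sigma_fly = 0.15, sigma_leap = 0.35,
                          sigma_rest_deep = 0.004, p_deep_rest = 0.5,
                          wingbeat_hz = 6, wingbeat_tone_share = 0.3,
                          static_walk_sd = 1e-4, static_start = -0.2,
                          sample_rate = 25) {
  stopifnot(sigma_rest > 0, sigma_sing > 0, sigma_fly > 0, sigma_leap > 0,
            sigma_rest_deep > 0, sigma_rest_deep <= sigma_rest,
            p_deep_rest >= 0, p_deep_rest <= 1,
            wingbeat_tone_share >= 0, wingbeat_tone_share < 1,
            sample_rate == 25)
  if (!(sigma_rest < sigma_sing && sigma_sing < sigma_fly))
    stop("need sigma_rest < sigma_sing < sigma_fly")
  structure(as.list(environment()), class = "emission_spec")
}

# truncated lognormal by inverse-cdf (exact, no rejection loop)
r_trunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

r_sing_duration <- function(n, config) {
  r_trunc_lnorm(n, config$sing_meanlog, config$sing_sdlog,
                config$sing_min_s, config$sing_max_s)
}

site_coords <- function(geom, id) {
  i <- match(id, geom$sites$id)
  if (anyNA(i)) stop("unknown site id: ", paste(id[is.na(i)], collapse = ", "))
  geom$sites[i, c("lat", "lon"), drop = FALSE]
}

#' Simulate a night-long behavior script
#'
#' Builds a gap-free tiling of the night with rest, sing, fly and leap
#' intervals under a semi-Markov site-session model: the bird dwells at one
#' site (alternating rest with song at song posts, or rest with leap bursts
#' at foraging patches) for a session, then commutes by flight to another
#' site. Song and rest occur only at stationary sites; song bouts are always
#' flanked by rest at the same post; leaps occur only at foraging patches;
#' flights connect distinct sites. The script always ends in rest (a
#' non-rest bout is never truncated by the end of the night).
#'
#' @param config A [night_config()].
#' @param geom A [site_geometry()].
#' @param seed Integer seed; the script is deterministic given
#'   `(config, geom, seed)`.
#' @return A `behavior_script` data.frame with columns `behavior`, `start_s`,
#'   `end_s` (seconds since night start), `location_id` (site for stationary
#'   intervals, `NA` for flight), `from_id`, `to_id` (flight endpoints),
#'   and attributes `night_seconds`, `origin` (GMT epoch seconds of night
#'   start).
#' @export
simulate_behavior_script <- function(config = night_config(),
                                     geom = default_site_geometry(),
                                     seed = 1) {
  stopifnot(inherits(config, "night_config"), inherits(geom, "site_geometry"))
  rng <- local_rng(seed)
  on.exit(rng())

  night <- config$night_seconds
  sites <- geom$sites
  cur <- if (any(sites$type == "post")) {
    sites$id[sites$type == "post"][sample.int(sum(sites$type == "post"), 1)]
  } else sites$id[sample.int(nrow(sites), 1)]

  beh <- character(0); st <- numeric(0); en <- numeric(0)
  loc <- character(0); from <- character(0); to <- character(0)
  add <- function(b, t0, t1, l = NA_character_, f = NA_character_, tt = NA_character_) {
    beh <<- c(beh, b); st <<- c(st, t0); en <<- c(en, t1)
    loc <<- c(loc, l); from <<- c(from, f); to <<- c(to, tt)
  }

  t <- 0
  while (t < night) {
    session_end <- min(t + runif(1, config$session_min_s, config$session_max_s), night)
    at_post <- sites$type[match(cur, sites$id)] == "post"
    while (t < session_end) {
      rest_dur <- if (at_post) {
        min(max(r_trunc_lnorm(1, config$rest_post_meanlog, config$rest_post_sdlog,
                              config$rest_post_min_s, config$rest_post_max_s), 1),
            config$rest_post_max_s)
      } else runif(1, config$rest_patch_min_s, config$rest_patch_max_s)
      rest_dur <- min(rest_dur, night - t)
      add("rest", t, t + rest_dur, l = cur)
      t <- t + rest_dur
      if (t >= session_end) break
      if (at_post && runif(1) < config$p_sing) {
        dur <- r_sing_duration(1, config)
        # never truncate a song bout against the night end; leave rest instead
        if (t + dur + 1 <= night) { add("sing", t, t + dur, l = cur); t <- t + dur }
        else break
      } else if (!at_post && runif(1) < config$p_leap) {
        dur <- runif(1, config$leap_min_s, config$leap_max_s)
        if (t + dur + 1 <= night) { add("leap", t, t + dur, l = cur); t <- t + dur }
        else break
      }
    }
    if (t >= night) break
    if (config$p_fly > 0 && runif(1) < config$p_fly && nrow(sites) > 1) {
      # ensure flight departs from a rest interval, not a song/leap bout
      if (beh[length(beh)] != "rest") {
        pad <- min(runif(1, 3, 10), night - t)
        add("rest", t, t + pad, l = cur)
        t <- t + pad
        if (t >= night) break
      }
      others <- sites[sites$id != cur, , drop = FALSE]
      pick_post <- runif(1) < config$p_post && any(others$type == "post")
      cand <- if (pick_post) others[others$type == "post", , drop = FALSE]
              else if (any(others$type == "patch")) others[others$type == "patch", , drop = FALSE]
              else others
      nxt <- cand$id[sample.int(nrow(cand), 1)]
      a <- site_coords(geom, cur); b <- site_coords(geom, nxt)
      dur <- max(haversine_m(a$lat, a$lon, b$lat, b$lon) / config$fly_speed_mps,
                 config$fly_min_s)
      if (t + dur + 1 <= night) {
        add("fly", t, t + dur, f = cur, tt = nxt)
        t <- t + dur
        cur <- nxt
      }
    }
  }
  # close any numerical shortfall with rest at the current site
  if (length(en) == 0 || en[length(en)] < night) {
    t0 <- if (length(en)) en[length(en)] else 0
    add("rest", t0, night, l = cur)
  }

  scr <- data.frame(behavior = beh, start_s = st, end_s = en,
                    location_id = loc, from_id = from, to_id = to,
                    stringsAsFactors = FALSE)
  scr <- merge_script_runs(scr)
  structure(scr, night_seconds = night, origin = config$origin,
            class = c("behavior_script", "data.frame"))
}

# merge adjacent intervals with equal behavior and location
merge_script_runs <- function(scr) {
  if (nrow(scr) <= 1) return(scr)
  keep <- logical(nrow(scr))
  keep[1] <- TRUE
  j <- 1
  for (i in 2:nrow(scr)) {
    same <- scr$behavior[i] == scr$behavior[j] &&
      identical(scr$location_id[i], scr$location_id[j]) &&
      scr$behavior[i] != "fly"
    if (same) scr$end_s[j] <- scr$end_s[i]
    else { keep[i] <- TRUE; j <- i }
  }
  out <- scr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# behavior label of the interval containing each time (seconds since night
# start); times exactly at a boundary belong to the following interval
script_behavior_at <- function(script, times) {
  i <- findInterval(times, script$start_s)
  i[i < 1] <- 1
  script$behavior[i]
}

# true (lat, lon) at each time: site coordinates when stationary, linear
# interpolation along the route during flight
script_position_at <- function(script, geom, times) {
  i <- findInterval(times, script$start_s)
  i[i < 1] <- 1
  lat <- numeric(length(times)); lon <- numeric(length(times))
  stat <- script$behavior[i] != "fly"
  if (any(stat)) {
    cc <- site_coords(geom, script$location_id[i[stat]])
    lat[stat] <- cc$lat; lon[stat] <- cc$lon
  }
  if (any(!stat)) {
    ii <- i[!stat]
    a <- site_coords(geom, script$from_id[ii])
    b <- site_coords(geom, script$to_id[ii])
    frac <- (times[!stat] - script$start_s[ii]) /
      (script$end_s[ii] - script$start_s[ii])
    lat[!stat] <- a$lat + frac * (b$lat - a$lat)
    lon[!stat] <- a$lon + frac * (b$lon - a$lon)
  }
  data.frame(lat = lat, lon = lon)
}

#' Render the acceleration trace of a behavior script
#'
#' Forward model from script to 25 Hz single-axis acceleration: each sample
#' is a slowly varying static gravity component (bounded random walk,
#' reflected into [-1, 1] g) plus the behavior-specific dynamic component of
#' the interval containing its timestamp. Song and flight split their
#' variance evenly between a phase-randomized oscillation and white noise;
#' rest and leap are pure noise at their respective scales.
#'
#' @param script A `behavior_script`.
#' @param spec An [emission_spec()].
#' @param seed Integer seed.
#' @return A raw [accel_trace()] spanning the night at 25 Hz, with attributes
#'   `static_g` (the static component) and `behavior` (per-sample generating
#'   behavior) for downstream scoring.
#' @export
render_acceleration <- function(script, spec = emission_spec(), seed = 1) {
  stopifnot(inherits(script, "behavior_script"), inherits(spec, "emission_spec"))
  rng <- local_rng(seed)
  on.exit(rng())

  night <- attr(script, "night_seconds")
  origin <- attr(script, "origin")
  rate <- spec$sample_rate
  n <- round(night * rate)
  trel <- (seq_len(n) - 1) / rate
  lab <- script_behavior_at(script, trel)
  iv <- findInterval(trel, script$start_s)

  # static component: bounded random walk, reflected into [-1, 1] g
  # (triangle-wave folding; identity on [-1, 1])
  static <- spec$static_start + cumsum(rnorm(n, 0, spec$static_walk_sd))
  static <- 1 - abs(((static + 1) %% 4) - 2)

  dyn <- numeric(n)
  phase <- runif(nrow(script), 0, 2 * pi)  # one wingbeat phase per interval
  # per-interval deep/alert assignment for the two inactive sub-regimes
  deep <- runif(nrow(script)) < spec$p_deep_rest
  for (b in c("rest", "sing", "fly", "leap")) {
    m <- lab == b
    if (!any(m)) next
    dyn[m] <- switch(b,
      rest = rnorm(sum(m), 0, ifelse(deep[iv[m]], spec$sigma_rest_deep,
                                     spec$sigma_rest)),
      leap = rnorm(sum(m), 0, spec$sigma_leap),
      sing = rnorm(sum(m), 0, spec$sigma_sing),
      fly  = {
        amp <- spec$sigma_fly * sqrt(2 * spec$wingbeat_tone_share)
        amp * sin(2 * pi * spec$wingbeat_hz * trel[m] + phase[iv[m]]) +
          rnorm(sum(m), 0, spec$sigma_fly * sqrt(1 - spec$wingbeat_tone_share))
      })
  }

  tr <- accel_trace(origin + trel, static + dyn, kind = "raw", sample_rate = rate)
  attr(tr, "static_g") <- static
  attr(tr, "behavior") <- lab
  tr
}

#' Render the GPS track of a behavior script
#'
#' One fix every 180 s from night start (inclusive of both ends of the
#' night): the true position at the fix time (site coordinates when
#' stationary, linear interpolation along the route in flight) displaced by
#' an isotropic error with uniform bearing and half-normal radial magnitude
#' of scale `geom$gps_error_sd`.
#'
#' @param script A `behavior_script`.
#' @param geom A [site_geometry()].
#' @param seed Integer seed.
#' @param fix_interval_s Spacing of fixes in seconds (default 180).
#' @return A `gps_track` data.frame: `time_s` (GMT epoch), `lat`, `lon`.
#' @export
render_gps <- function(script, geom, seed = 1, fix_interval_s = 180) {
  stopifnot(inherits(script, "behavior_script"), inherits(geom, "site_geometry"))
  rng <- local_rng(seed)
  on.exit(rng())
  night <- attr(script, "night_seconds")
  origin <- attr(script, "origin")
  trel <- seq(0, night, by = fix_interval_s)
  pos <- script_position_at(script, geom, pmin(trel, night - 1e-9))
  r <- abs(rnorm(length(trel), 0, geom$gps_error_sd))
  theta <- runif(length(trel), 0, 2 * pi)
  m_per_deg <- 6371000 * pi / 180
  lat <- pos$lat + r * cos(theta) / m_per_deg
  lon <- pos$lon + r * sin(theta) / (m_per_deg * cos(pos$lat * pi / 180))
  structure(data.frame(time_s = origin + trel, lat = lat, lon = lon),
            class = c("gps_track", "data.frame"))
}

#' Render the audio-recorder ground truth of a behavior script
#'
#' Emits one annotation row per song bout of at least 10 s whose song post
#' lies within 20 m of a recorder (the audibility radius); bouts farther than
#' 20 m from every recorder leave no trace. Boundaries carry the +/- 1 s
#' timing uncertainty of manual annotation; a row whose jittered duration
#' falls below 10 s is dropped, mirroring the convention that only bouts of
#' at least 10 s are annotated.
#'
#' @param script A `behavior_script`.
#' @param geom A [site_geometry()].
#' @param seed Integer seed.
#' @param audible_m Audibility radius in meters (default 20).
#' @param min_bout_s Minimum annotated bout duration (default 10).
#' @param miss_prob Probability an audible bout is missed (default 0).
#' @return An `audio_bouts` data.frame: `recorder_id`, `begin_s`, `end_s`
#'   (GMT epoch seconds).
#' @export
render_audio_truth <- function(script, geom, seed = 1, audible_m = 20,
                               min_bout_s = 10, miss_prob = 0) {
  stopifnot(inherits(script, "behavior_script"), inherits(geom, "site_geometry"))
  rng <- local_rng(seed)
  on.exit(rng())
  origin <- attr(script, "origin")
  sing <- script[script$behavior == "sing", , drop = FALSE]
  out <- data.frame(recorder_id = character(0), begin_s = numeric(0),
                    end_s = numeric(0))
  if (nrow(sing) > 0) {
    cc <- site_coords(geom, sing$location_id)
    for (i in seq_len(nrow(sing))) {
      if (sing$end_s[i] - sing$start_s[i] < min_bout_s) next
      d <- haversine_m(cc$lat[i], cc$lon[i], geom$recorders$lat, geom$recorders$lon)
      if (min(d) >= audible_m) next
      if (miss_prob > 0 && runif(1) < miss_prob) next
      b <- origin + sing$start_s[i] + runif(1, -1, 1)
      e <- origin + sing$end_s[i] + runif(1, -1, 1)
      if (e - b < min_bout_s) next
      out <- rbind(out, data.frame(recorder_id = geom$recorders$id[which.min(d)],
                                   begin_s = b, end_s = e))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("audio_bouts", "data.frame"))
}

#' Per-second ground-truth behavior labels of a script
#'
#' @param script A `behavior_script`.
#' @param step_s Label grid spacing in seconds (default 1).
#' @return data.frame `time_s` (GMT epoch, start of each step), `behavior`
#'   (label of the behavior covering the step midpoint).
#' @export
script_to_labels <- function(script, step_s = 1) {
  stopifnot(inherits(script, "behavior_script"))
  night <- attr(script, "night_seconds")
  origin <- attr(script, "origin")
  starts <- seq(0, night - step_s, by = step_s)
  data.frame(time_s = origin + starts,
             behavior = script_behavior_at(script, starts + step_s / 2))
}
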