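test_that("a script with no song, flight or leaping is one rest interval", {
  cfg <- night_config(p_sing = 0, p_leap = 0, p_fly = 0)
  scr <- simulate_behavior_script(cfg, seed = 3)
  expect_equal(nrow(scr), 1L)
  expect_equal(scr$behavior, "rest")
  expect_equal(scr$start_s, 0)
  expect_equal(scr$end_s, cfg$night_seconds)
})

test_that("scripts tile the night exactly for many seeds", {
  cfg <- quick_night()
  for (seed in 1:10) {
    scr <- simulate_behavior_script(cfg, default_site_geometry(), seed = seed)
    expect_equal(sum(scr$end_s - scr$start_s), attr(scr, "night_seconds"))
    expect_equal(scr$start_s[1], 0)
    expect_equal(scr$start_s[-1], head(scr$end_s, -1))  # gap-free, no overlap
    expect_true(all(scr$end_s > scr$start_s))
  }
})

test_that("song bouts are flanked by rest at the same post; leaps happen at patches", {
  geom <- default_site_geometry()
  scr <- simulate_behavior_script(night_config(), geom, seed = 5)
  posts <- geom$song_posts$id
  patches <- geom$foraging_patches$id
  for (i in which(scr$behavior == "sing")) {
    expect_true(scr$location_id[i] %in% posts)
    expect_equal(scr$behavior[i - 1], "rest")
    expect_equal(scr$location_id[i - 1], scr$location_id[i])
    expect_equal(scr$behavior[i + 1], "rest")
    expect_equal(scr$location_id[i + 1], scr$location_id[i])
  }
  expect_true(all(scr$location_id[scr$behavior == "leap"] %in% patches))
  fly <- scr[scr$behavior == "fly", ]
  expect_true(all(fly$from_id != fly$to_id))
})

test_that("sing durations follow the truncated lognormal duration regime", {
  cfg <- night_config()
  rng <- nightsong:::local_rng(1); on.exit(rng())
  d <- nightsong:::r_sing_duration(1000, cfg)
  expect_true(all(d >= 11 & d <= 204))
  expect_gt(median(d), 25 * 0.5)
  expect_lt(median(d), 25 * 1.5)
  # and the in-script bout durations respect the same bounds
  scr <- simulate_behavior_script(cfg, seed = 2)
  sdur <- with(scr[scr$behavior == "sing", ], end_s - start_s)
  expect_true(all(sdur >= 11 & sdur <= 204))
})

test_that("non-positive duration parameters are rejected", {
  expect_error(night_config(leap_min_s = 0), "positive")
  expect_error(night_config(fly_speed_mps = -1), "positive")
  expect_error(emission_spec(sigma_sing = 0))
  expect_error(emission_spec(sigma_rest = 0.2), "sigma_rest < sigma_sing")
})

test_that("generation is reproducible: identical seeds give identical outputs", {
  cfg <- quick_night()
  geom <- default_site_geometry()
  a <- simulate_behavior_script(cfg, geom, seed = 11)
  b <- simulate_behavior_script(cfg, geom, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_behavior_script(cfg, geom, seed = 12)))
  expect_identical(render_acceleration(a, seed = 4), render_acceleration(b, seed = 4))
  expect_identical(render_gps(a, geom, seed = 4), render_gps(b, geom, seed = 4))
  expect_identical(render_audio_truth(a, geom, seed = 4),
                   render_audio_truth(b, geom, seed = 4))
})

test_that("an all-rest script with vanishing noise renders a constant trace", {
  scr <- make_script("rest", 60, location_id = "P1")
  spec <- emission_spec(sigma_rest_deep = 1e-9, sigma_rest = 1e-8,
                        sigma_sing = 1e-7, sigma_fly = 1e-6, sigma_leap = 1e-6,
                        p_deep_rest = 1, static_walk_sd = 0, static_start = 0.3)
  tr <- render_acceleration(scr, spec, seed = 1)
  expect_equal(nrow(tr), 60 * 25)
  expect_true(all(abs(tr$accel_g - 0.3) < 1e-6))
})

test_that("trace length and per-behavior amplitude ordering match the spec", {
  scr <- simulate_behavior_script(quick_night(), seed = 7)
  spec <- emission_spec()
  tr <- render_acceleration(scr, spec, seed = 8)
  expect_equal(nrow(tr), attr(scr, "night_seconds") * 25)
  dyn <- tr$accel_g - attr(tr, "static_g")
  sds <- tapply(dyn, attr(tr, "behavior"), sd)
  expect_lt(sds[["rest"]], sds[["sing"]])
  expect_lt(sds[["sing"]], sds[["fly"]])
  # static component stays within physical bounds
  expect_true(all(abs(attr(tr, "static_g")) <= 1))
})

test_that("GPS fixes sit exactly on the post when the error scale is zero", {
  geom <- tiny_geometry(gps_error_sd = 0)
  scr <- make_script("rest", 3600, location_id = "P1")
  gps <- render_gps(scr, geom, seed = 1)
  expect_equal(nrow(gps), floor(3600 / 180) + 1)
  expect_equal(gps$lat, rep(geom$song_posts$lat[1], nrow(gps)))
  expect_equal(gps$lon, rep(geom$song_posts$lon[1], nrow(gps)))
})

test_that("default GPS error calibration: ~95% of fixes within 20 m", {
  geom <- tiny_geometry()
  scr <- make_script("rest", 32400, location_id = "P1")
  d <- unlist(lapply(1:56, function(s) {
    gps <- render_gps(scr, geom, seed = s)
    haversine_m(gps$lat, gps$lon, geom$song_posts$lat[1], geom$song_posts$lon[1])
  }))
  expect_gte(length(d), 10000)
  expect_gte(mean(d < 20), 0.93)
})

test_that("audio truth obeys the 20-m audibility and 10-s annotation rules", {
  # no recorder within 20 m of the singing post -> empty table
  geom <- tiny_geometry()
  far_script <- make_script(c("rest", "sing", "rest"), c(60, 30, 60),
                            location_id = "P2")
  expect_equal(nrow(render_audio_truth(far_script, geom, seed = 1)), 0L)

  # a 30-s bout 5 m from the recorder -> one row, duration within jitter
  near_script <- make_script(c("rest", "sing", "rest"), c(60, 30, 60),
                             location_id = "P1")
  tab <- render_audio_truth(near_script, geom, seed = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$recorder_id, "R1")
  expect_gte(tab$end_s - tab$begin_s, 28)
  expect_lte(tab$end_s - tab$begin_s, 32)

  # a 9-s bout is below the annotation minimum -> no row
  short_script <- make_script(c("rest", "sing", "rest"), c(60, 9, 60),
                              location_id = "P1")
  expect_equal(nrow(render_audio_truth(short_script, geom, seed = 3)), 0L)
})

test_that("every audio row's generating song post is within 20 m of its recorder", {
  geom <- default_site_geometry()
  for (seed in 1:5) {
    scr <- simulate_behavior_script(night_config(), geom, seed = seed)
    tab <- render_audio_truth(scr, geom, seed = seed + 100)
    org <- attr(scr, "origin")
    for (i in seq_len(nrow(tab))) {
      j <- which(scr$behavior == "sing" &
                   abs(scr$start_s + org - tab$begin_s[i]) <= 1.01)
      expect_length(j, 1L)
      cc <- nightsong:::site_coords(geom, scr$location_id[j])
      r <- geom$recorders[geom$recorders$id == tab$recorder_id[i], ]
      expect_lt(haversine_m(cc$lat, cc$lon, r$lat, r$lon), 20)
    }
  }
})
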