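# Track ingestion, exclusion filter, speed/directionality, constriction split.

test_that("spots-table round trip preserves positions to 1e-6 um", {
  co <- simulate_cohort(phenotype_presets("control"), 12, seed = 41,
                        n_frames = 80)
  co <- generate_calcium_traces(co, seed = 42)
  p <- file.path(tempdir(), "spots.csv")
  write_tracks(co, p)
  ts <- read_tracks(p, geometry = co$geometry)
  expect_equal(length(ts), 12)
  for (id in names(co$tracks$tracks)) {
    expect_equal(ts$tracks[[id]]$x, co$tracks$tracks[[id]]$x, tolerance = 1e-6)
    expect_equal(ts$tracks[[id]]$y, co$tracks$tracks[[id]]$y, tolerance = 1e-6)
    expect_equal(ts$tracks[[id]]$attachments$intensity,
                 co$tracks$tracks[[id]]$attachments$intensity,
                 tolerance = 1e-6)
  }
})

test_that("reader errors name missing columns and duplicated pairs", {
  p <- file.path(tempdir(), "bad1.csv")
  write.csv(data.frame(TRACK_ID = 1, FRAME = 0:1, POSITION_X = c(0, 1)),
            p, row.names = FALSE)
  expect_error(read_tracks(p), "POSITION_T.*POSITION_Y|POSITION_Y.*POSITION_T")
  p2 <- file.path(tempdir(), "bad2.csv")
  write.csv(data.frame(TRACK_ID = c(3, 3, 3), FRAME = c(0, 1, 1),
                       POSITION_T = c(0, 30, 30), POSITION_X = c(0, 1, 2),
                       POSITION_Y = 0), p2, row.names = FALSE)
  expect_error(read_tracks(p2), "TRACK_ID=3.*FRAME=1")
  # two-row file, one track
  p3 <- file.path(tempdir(), "tiny.csv")
  write.csv(data.frame(TRACK_ID = 1, FRAME = 0:1, POSITION_T = c(0, 30),
                       POSITION_X = c(0, 5), POSITION_Y = c(0, 0)),
            p3, row.names = FALSE)
  ts <- read_tracks(p3)
  expect_equal(length(ts), 1)
  expect_equal(length(ts$tracks[[1]]$x), 2)
})

test_that("exclusion filter keeps the boundary and is idempotent", {
  disp <- c(150, 99.9, 100, 20, 300)
  trks <- lapply(seq_along(disp), function(i)
    track(i, 0:1, c(0, 30), x = c(0, disp[i]), y = c(0, 0)))
  ts <- trackset(trks, 30)
  kept <- filter_tracks(ts)
  expect_setequal(names(kept$tracks), c("1", "3", "5"))   # {150, 100, 300}
  expect_identical(names(filter_tracks(kept)$tracks), names(kept$tracks))
  # straight 200-um tracks: identity
  ts2 <- trackset(lapply(1:4, function(i) straight_track(i, n = 5, step_x = 50)), 30)
  expect_equal(length(filter_tracks(ts2)), 4)
  expect_match(kept$provenance$filter_log, "excluded 2 of 5")
})

test_that("speed and directionality match hand computations", {
  tr <- track(1, 0:1, c(0, 60), x = c(0, 30), y = c(0, 0))
  expect_equal(track_speed(tr), 30)
  zz <- zigzag_track()
  expect_equal(track_speed(zz), 2 * sqrt(200) / 2)         # 14.142...
  expect_equal(track_directionality(zz), 20 / (2 * sqrt(200)))  # 0.7071
  expect_equal(track_directionality(straight_track()), 1)
  expect_equal(track_directionality(loop_track()), 0)
  st <- track(9, 0:2, c(0, 30, 60), x = rep(1, 3), y = rep(2, 3))
  expect_equal(track_speed(st), 0)
  expect_warning(d <- track_directionality(st), "zero path")
  expect_equal(d, 0)
  expect_error(track_speed(track(1, 0:1, c(0, 30), c(0, 1), c(0, 0))), NA)
  expect_equal(track_fmi(zz), 20 / (2 * sqrt(200)))
})

test_that("kinematics are invariant to translation and time rescaling", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 12
    tr <- track(rep, 0:(n - 1), (0:(n - 1)) * 30,
                x = cumsum(rnorm(n, 2, 3)), y = cumsum(rnorm(n, 0, 3)))
    sh <- track(rep, tr$frames, tr$times, tr$x + 55, tr$y - 31)
    expect_equal(track_speed(sh), track_speed(tr))
    expect_equal(track_directionality(sh), track_directionality(tr))
    rs <- track(rep, tr$frames, tr$times * 3, tr$x, tr$y)
    expect_equal(track_directionality(rs), track_directionality(tr))
    expect_equal(track_speed(rs), track_speed(tr) / 3)
  }
})

test_that("split_at_constriction follows first entry / first exit", {
  g <- device_geometry()
  mono <- track(1, 0:30, (0:30) * 30, x = seq(0, 300, by = 10), y = rep(0, 31))
  sp <- split_at_constriction(mono, g)
  expect_true(length(sp$pre) > 0 && length(sp$during) > 0 && length(sp$post) > 0)
  expect_equal(c(sp$pre, sp$during, sp$post), 1:31)
  short <- track(2, 0:4, (0:4) * 30, x = seq(0, 80, by = 20), y = rep(0, 5))
  sp2 <- split_at_constriction(short, g)
  expect_false(sp2$entered)
  expect_equal(sp2$pre, 1:5)
  expect_length(sp2$during, 0)
  # oscillation across the entry line, then passage
  osc_x <- c(50, 90, 105, 95, 110, 118, 130, 200)
  osc <- track(3, 0:7, (0:7) * 30, x = osc_x, y = rep(0, 8))
  sp3 <- split_at_constriction(osc, g)
  bf <- bf_split_scan(osc_x, 100, 120)
  expect_equal(sp3$pre, bf$pre)
  expect_equal(sp3$during, bf$during)
  expect_equal(sp3$post, bf$post)
})

test_that("split matches the brute-force scan on random simulated tracks", {
  co <- simulate_cohort(phenotype_presets("control"), 10, seed = 51)
  g <- co$geometry
  for (tr in co$tracks$tracks) {
    sp <- split_at_constriction(tr, g)
    bf <- bf_split_scan(tr$x, g$constriction_x, constriction_exit(g))
    expect_equal(sp$pre, bf$pre)
    expect_equal(sp$during, bf$during)
    expect_equal(sp$post, bf$post)
  }
})

test_that("peri_summary reproduces hand computations and degenerate cases", {
  g <- device_geometry()
  # hand-built 6-point track: pre (3 pts), during (1), post (2)
  tr <- track(1, 0:5, (0:5) * 60,
              x = c(0, 40, 80, 110, 130, 170), y = c(0, 30, 0, 0, 0, 30))
  ts <- trackset(list(tr), 60, g)
  s <- peri_summary(ts, n_boot = 50, seed = 1, min_points = 2)
  pre_path <- 50 + 50                       # (0,0)->(40,30)->(80,0)
  expect_equal(s$per_cell$pre_speed, pre_path / 120 * 60)
  expect_equal(s$per_cell$pre_dir, 80 / pre_path)
  post_path <- sqrt(40^2 + 30^2)            # (130,0)->(170,30)
  expect_equal(s$per_cell$post_speed, post_path / 60 * 60)
  expect_equal(s$per_cell$post_dir, 1)
  expect_equal(s$per_cell$post_euclidean, post_path)
  expect_equal(s$per_cell$crossing_frame, 4)
  expect_equal(s$population$crossing_fraction, 1)

  # straight constant-speed tracks: post/pre ratios exactly 1
  ts2 <- trackset(lapply(1:6, function(i) straight_track(i, n = 31, step_x = 10)),
                  30, g)
  s2 <- peri_summary(ts2, n_boot = 50, seed = 1)
  expect_equal(s2$population$speed_ratio, 1)
  expect_equal(s2$population$dir_ratio, 1)

  # nobody crosses: crossing fraction 0, empty post statistics
  ts3 <- trackset(lapply(1:3, function(i)
    track(i, 0:9, (0:9) * 30, x = seq(0, 90, by = 10), y = rep(0, 10))), 30, g)
  s3 <- peri_summary(ts3, n_boot = 50, seed = 1)
  expect_equal(s3$population$crossing_fraction, 0)
  expect_true(is.na(s3$population$median_post_speed))
})

test_that("peri_summary equals a per-frame brute force on random tracks", {
  co <- simulate_cohort(phenotype_presets("control"), 10, seed = 61)
  ts <- co$tracks
  s <- peri_summary(ts, n_boot = 50, seed = 1, trim_arrest = FALSE,
                    min_points = 2)
  g <- co$geometry
  for (i in seq_len(10)) {
    tr <- ts$tracks[[i]]
    bf <- bf_split_scan(tr$x, g$constriction_x, constriction_exit(g))
    row <- s$per_cell[s$per_cell$track_id == tr$track_id, ]
    if (length(bf$pre) >= 2) {
      path <- sum(sqrt(diff(tr$x[bf$pre])^2 + diff(tr$y[bf$pre])^2))
      el <- tr$times[bf$pre[length(bf$pre)]] - tr$times[bf$pre[1]]
      expect_equal(row$pre_speed, path / el * 60)
      net <- sqrt((tr$x[max(bf$pre)] - tr$x[1])^2 + (tr$y[max(bf$pre)] - tr$y[1])^2)
      expect_equal(row$pre_dir, net / path)
    }
    if (length(bf$post) >= 2) {
      i0 <- bf$post[1]; iN <- length(tr$x)
      expect_equal(row$post_euclidean,
                   sqrt((tr$x[iN] - tr$x[i0])^2 + (tr$y[iN] - tr$y[i0])^2))
    }
  }
})

test_that("eccentricity timecourse pools by region", {
  g <- device_geometry()
  mk <- function(id, e) track(id, 0:30, (0:30) * 30, x = seq(0, 300, by = 10),
                              y = rep(0, 31),
                              attachments = list(eccentricity = rep(e, 31)))
  ts <- trackset(list(mk(1, 0.8), mk(2, 0.8)), 30, g)
  ecc <- eccentricity_timecourse(ts)
  expect_equal(unname(ecc), c(0.8, 0.8, 0.8))
  # cells with no during segment are excluded from the during mean
  pre_only <- track(3, 0:4, (0:4) * 30, x = seq(0, 80, by = 20), y = rep(0, 5),
                    attachments = list(eccentricity = rep(0.2, 5)))
  ts2 <- trackset(list(mk(1, 0.8), pre_only), 30, g)
  ecc2 <- eccentricity_timecourse(ts2)
  expect_equal(unname(ecc2["during"]), 0.8)
  expect_equal(unname(ecc2["before"]), 0.5)
  ts3 <- trackset(list(straight_track(1, n = 5)), 30, g)
  expect_error(eccentricity_timecourse(ts3), "eccentricity attachment")
})

test_that("track and trackset constructors validate invariants", {
  expect_error(track(1, 0, 0, 1, 1), "at least 2")
  expect_error(track(1, 0:1, c(0, 0), c(0, 1), c(0, 1)), "strictly increasing")
  expect_error(track(1, 0:1, c(0, 30), c(0, 1), c(0, 1),
                     attachments = list(e = 1)), "length mismatch")
  t1 <- straight_track(1); t1b <- straight_track(1)
  expect_error(trackset(list(t1, t1b), 30), "duplicate")
  t2 <- track(2, 0:2, c(0, 30, 90), x = c(0, 1, 2), y = c(0, 0, 0))
  expect_error(trackset(list(t2), 30), "uniform")
})
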