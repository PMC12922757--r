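# Synthetic-data generator: cohorts, traces, vesicles, rendering.

test_that("identical seeds give bit-identical cohorts, traces and counts", {
  ph <- phenotype_presets("control")
  a <- simulate_cohort(ph, 30, seed = 11, n_frames = 100)
  b <- simulate_cohort(ph, 30, seed = 11, n_frames = 100)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$tracks$tracks[[7]]$x, b$tracks$tracks[[7]]$x)
  a <- generate_calcium_traces(a, seed = 12)
  b <- generate_calcium_traces(b, seed = 12)
  expect_identical(a$traces[[3]]$intensity, b$traces[[3]]$intensity)
  a <- generate_vesicle_counts(a, seed = 13)
  b <- generate_vesicle_counts(b, seed = 13)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- simulate_cohort(ph, 30, seed = 99, n_frames = 100)
  expect_false(identical(a$tracks$tracks[[1]]$x, c2$tracks$tracks[[1]]$x))
})

test_that("zero heading noise with positive bias gives straight +x tracks", {
  ph <- phenotype_params("det", noise_sigma = 0, gradient_bias = 0.5,
                         persistence = 0.7, step_cv = 0.3)
  co <- simulate_cohort(ph, 10, seed = 2, n_frames = 80)
  for (tr in co$tracks$tracks) {
    expect_true(all(abs(diff(tr$y)) < 1e-12))
    expect_true(all(diff(tr$x) >= 0))
    expect_equal(track_directionality(tr), 1.0)
  }
})

test_that("no bias and no persistence gives an isotropic walk", {
  ph <- phenotype_params("iso", gradient_bias = 0, persistence = 0,
                         noise_sigma = 1)
  # start mid-chamber so the reflecting inlet wall cannot rectify the walk
  co <- simulate_cohort(ph, 500, seed = 5, n_frames = 60,
                        calibrate_directionality = FALSE,
                        x0_range = c(140, 160))
  net_x <- vapply(co$tracks$tracks, function(t) t$x[length(t$x)] - t$x[1], 0)
  se <- stats::sd(net_x) / sqrt(length(net_x))
  expect_lt(abs(mean(net_x)), 3 * se)
})

test_that("all positions stay within the chamber and dwell has the stated mean", {
  ph <- phenotype_presets("control")
  co <- simulate_cohort(ph, 200, seed = 3)
  g <- co$geometry
  for (tr in co$tracks$tracks) {
    expect_true(all(tr$x >= 0 & tr$x <= g$chamber_length))
    expect_true(all(tr$y >= 0 & tr$y <= g$chamber_width))
  }
  # every track id appears exactly once in the ground truth
  expect_identical(sort(co$ground_truth$track_id),
                   sort(as.integer(names(co$tracks$tracks))))
  dw <- co$ground_truth$dwell_frames
  expect_lt(abs(mean(dw, na.rm = TRUE) - 4), 3 * stats::sd(dw, na.rm = TRUE) /
              sqrt(sum(!is.na(dw))))
})

test_that("calcium traces: degenerate and by-construction cases", {
  ph <- phenotype_params("nospike", spike_prob = 0)
  co <- simulate_cohort(ph, 15, seed = 7, n_frames = 100)
  co0 <- generate_calcium_traces(co, noise_cv = 0, seed = 8)
  for (tr in co0$traces) expect_true(all(tr$intensity == 100))
  folds <- vapply(co0$traces, calcium_fold_change, 0, geometry = co$geometry)
  expect_true(all(abs(folds[!is.na(folds)] - 1) < 1e-12))

  ph1 <- phenotype_params("allspike", spike_prob = 1)
  co1 <- simulate_cohort(ph1, 25, seed = 9, n_frames = 120)
  co1 <- generate_calcium_traces(co1, spike_amp = 400, seed = 10)
  gt <- co1$ground_truth
  ex <- constriction_exit(co1$geometry)
  crossed <- !is.na(gt$exit_frame)
  expect_true(all(gt$spike[crossed]))
  for (k in which(crossed)) {
    tr <- co1$traces[[k]]
    x0 <- tr$x[tr$times == gt$spike_time[k]]
    expect_true(x0 > ex && x0 <= ex + co1$geometry$cell_length)
  }
})

test_that("vesicle counts recover the target medians", {
  ph44 <- phenotype_params("same", vesicle_median_pre = 4, vesicle_median_post = 4)
  co <- simulate_cohort(ph44, 300, seed = 21, n_frames = 40)
  co <- generate_vesicle_counts(co, dispersion = 5, seed = 22)
  gt <- co$ground_truth
  expect_equal(median(gt$vesicle_post) - median(gt$vesicle_pre), 0)

  ph47 <- phenotype_params("shift", vesicle_median_pre = 4, vesicle_median_post = 7)
  co2 <- simulate_cohort(ph47, 300, seed = 23, n_frames = 40)
  co2 <- generate_vesicle_counts(co2, dispersion = 5, seed = 24)
  expect_equal(median(co2$ground_truth$vesicle_pre), 4)
  expect_equal(median(co2$ground_truth$vesicle_post), 7)
  # polarity readout rises with vesicle load
  expect_gt(cor(co2$ground_truth$pmlc_ratio, co2$ground_truth$vesicle_post), 0.5)

  co3 <- simulate_cohort(ph47, 1, seed = 25, n_frames = 40)
  co3 <- generate_vesicle_counts(co3, seed = 26)
  expect_equal(nrow(co3$ground_truth), 1)
  expect_true(is.finite(co3$ground_truth$vesicle_pre))
})

test_that("renderer: single circular cell closes the cortical identity fixture", {
  ph <- phenotype_params("one")
  co <- simulate_cohort(ph, 1, seed = 31, n_frames = 60)
  fr <- render_frames(co, frames = 20L, shape_mode = "depolarized",
                      cortical_ratio = 1, band_width = 3, seed = 1)[[1]]
  expect_true(all(fr$nucleus_mask[fr$nucleus_mask > 0] ==
                    fr$cell_mask[fr$nucleus_mask > 0]))
  rr <- cortex_cytosol_ratio(fr$channels$cortical, fr$cell_mask == 1,
                             band_width = 3)
  expect_equal(rr$ratio, 1.0)
  # x2 cortical ring measured with the same band definition
  fr2 <- render_frames(co, frames = 20L, shape_mode = "depolarized",
                       cortical_ratio = 2, band_width = 3, seed = 1)[[1]]
  rr2 <- cortex_cytosol_ratio(fr2$channels$cortical, fr2$cell_mask == 1,
                              band_width = 3)
  expect_lt(abs(rr2$ratio - 2) / 2, 0.05)
})

test_that("renderer: keratocyte mode yields the analytic ellipse metrics", {
  ph <- phenotype_params("one")
  co <- simulate_cohort(ph, 1, seed = 32, n_frames = 60)
  fr <- render_frames(co, frames = 20L, shape_mode = "keratocyte",
                      keratocyte_axis_ratio = 2, axis_jitter_sd = 0,
                      seed = 2)[[1]]
  sm <- shape_metrics(fr$cell_mask)
  expect_lt(abs(sm$eccentricity - sqrt(1 - 1 / 4)), 0.03)  # 0.866
  expect_gt(sm$orientation, 45)
  expect_true(classify_keratocyte(sm))
})

test_that("renderer: nucleus is squeezed to the gap inside the constriction", {
  ph <- phenotype_params("one", noise_sigma = 0.2)
  g <- device_geometry(gap_width = 3)
  co <- simulate_cohort(ph, 1, seed = 33, geometry = g, n_frames = 120)
  gt <- co$ground_truth
  expect_false(is.na(gt$entry_frame[1]))
  fr_d <- gt$entry_frame[1] + 1L  # a frame inside the dwell
  if (fr_d < gt$exit_frame[1]) {
    fr <- render_frames(co, frames = fr_d, seed = 3)[[1]]
    rows <- range(which(fr$nucleus_mask == 1, arr.ind = TRUE)[, 1])
    expect_lte(diff(rows) + 1, ceiling(3 / fr$pixel_size) + 1)
  }
  # rendering is reproducible bit-for-bit
  fa <- render_frames(co, frames = 30L, seed = 4)[[1]]
  fb <- render_frames(co, frames = 30L, seed = 4)[[1]]
  expect_identical(fa$channels, fb$channels)
  expect_identical(fa$cell_mask, fb$cell_mask)
})

test_that("rendered image text round-trips", {
  m <- matrix(rnorm(200), 10, 20)
  p <- file.path(tempdir(), "img.tsv")
  write_image_txt(m, p)
  expect_equal(unname(read_image_txt(p)), unname(m), tolerance = 1e-12)
})
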