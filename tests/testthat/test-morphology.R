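# Shape metrics, keratocyte classifier, NE folds, 3D nucleus, fiber alignment.

test_that("disc, square and ellipse reproduce their analytic metrics", {
  d <- make_disc(50)
  sd_ <- shape_metrics(d)
  expect_lt(abs(sd_$form_factor - 1), 0.02)
  expect_lt(sd_$eccentricity, 0.05)
  expect_gt(sd_$solidity, 0.98)
  expect_lt(abs(sd_$area - pi * 50^2) / (pi * 50^2), 0.01)

  q <- shape_metrics(make_square(100))
  expect_equal(q$solidity, 1.0)
  expect_lt(abs(q$form_factor - pi / 4), 0.02)
  expect_equal(q$aspect_ratio, 1.0)

  e <- shape_metrics(make_ellipse_mask(60, 30, 60))
  expect_lt(abs(e$eccentricity - sqrt(1 - 1 / 4)), 0.03)
  expect_lt(abs(e$orientation - 60), 3)
})

test_that("metrics are translation invariant and rotation stable", {
  base <- make_ellipse_mask(40, 20, 0)
  m1 <- shape_metrics(base)
  shifted <- matrix(0L, nrow(base) + 30, ncol(base) + 30)
  shifted[16:(15 + nrow(base)), 21:(20 + ncol(base))] <- base
  m2 <- shape_metrics(shifted)
  for (col in c("area", "perimeter", "eccentricity", "solidity", "form_factor"))
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-12)

  ff <- ecc <- sol <- numeric(0)
  for (th in c(0, 30, 60, 90)) {
    m <- shape_metrics(make_ellipse_mask(40, 20, th))
    ff <- c(ff, m$form_factor); ecc <- c(ecc, m$eccentricity)
    sol <- c(sol, m$solidity)
    expect_lt(abs(m$orientation - th), 3)
  }
  expect_lt(diff(range(ff)), 0.02)
  expect_lt(diff(range(ecc)), 0.02)
  expect_lt(diff(range(sol)), 0.02)
})

test_that("form factor is maximal for the disc across the fixture family", {
  ff_disc <- shape_metrics(make_disc(40))$form_factor
  ff_ell <- shape_metrics(make_ellipse_mask(40, 20, 30))$form_factor
  ff_star <- shape_metrics(make_star(5, 40, 15))$form_factor
  expect_gt(ff_disc, ff_ell)
  expect_gt(ff_ell, ff_star)
})

test_that("border-touching labels are flagged but measured", {
  m <- matrix(0L, 30, 30); m[1:10, 5:15] <- 1L
  sm <- shape_metrics(m)
  expect_true(sm$touches_border)
  expect_equal(sm$area, 110)
})

test_that("classifier equals a brute-force truth table and is strict", {
  ors <- seq(0, 90, length.out = 20)
  eccs <- seq(0, 0.99, length.out = 20)
  sols <- seq(0.5, 1, length.out = 20)
  grid <- expand.grid(orientation = ors, eccentricity = eccs, solidity = sols)
  got <- classify_keratocyte(grid)
  want <- logical(nrow(grid))
  for (i in seq_len(nrow(grid)))   # naive row-by-row oracle
    want[i] <- (grid$orientation[i] > 45) && (grid$eccentricity[i] > 0.75) &&
      (grid$solidity[i] > 0.9)
  expect_identical(got, want)
  # strict boundaries, one coordinate at a time
  expect_true(classify_keratocyte(data.frame(orientation = 60, eccentricity = 0.8, solidity = 0.95)))
  expect_false(classify_keratocyte(data.frame(orientation = 45, eccentricity = 0.8, solidity = 0.95)))
  expect_false(classify_keratocyte(data.frame(orientation = 60, eccentricity = 0.75, solidity = 0.95)))
  expect_false(classify_keratocyte(data.frame(orientation = 60, eccentricity = 0.8, solidity = 0.9)))
  expect_false(classify_keratocyte(data.frame(orientation = 30, eccentricity = 0.8, solidity = 0.95)))
})

test_that("keratocyte fraction recovers forced and simulated shape states", {
  co <- simulate_cohort(phenotype_presets("control"), 40, seed = 81,
                        n_frames = 120)
  fr_nums <- co$tracks$tracks[[1]]$frames
  # forced 50/50 cohort
  modes <- rep(c("keratocyte", "amoeboid"), 20)
  frames <- render_frames(co, frames = fr_nums[c(60, 80)], cells = 1:16,
                          shape_mode = modes, seed = 6, max_retries = 60)
  met <- do.call(rbind, lapply(frames, function(f) {
    sm <- shape_metrics(f$cell_mask)
    sm$cell <- sm$label
    pos <- f$cells$x[match(sm$label, f$cells$cell)]
    sm$region <- as.character(classify_position(pmin(pmax(pos, 0), 300),
                                                co$geometry))
    sm
  }))
  frac <- keratocyte_fraction(met, "after")
  usable <- unique(met$cell[met$region == "after" & !met$touches_border])
  truth <- mean(modes[usable] == "keratocyte")
  expect_lt(abs(frac - truth), 1 / length(usable) + 1e-9)  # within one cell
  # all-amoeboid cohort: zero
  fr0 <- render_frames(co, frames = fr_nums[70], cells = 1:12,
                       shape_mode = "amoeboid", seed = 7, max_retries = 60)
  met0 <- {
    f <- fr0[[1]]
    sm <- shape_metrics(f$cell_mask); sm$cell <- sm$label
    pos <- f$cells$x[match(sm$label, f$cells$cell)]
    sm$region <- as.character(classify_position(pmin(pmax(pos, 0), 300),
                                                co$geometry))
    sm
  }
  expect_equal(keratocyte_fraction(met0, "after"), 0)
  expect_true(is.na(keratocyte_fraction(met0, "nonexistent-region")))
})

test_that("NE fold counting finds constructed concavity defects", {
  expect_equal(count_ne_folds(make_disc(30)), 0L)
  expect_equal(count_ne_folds(make_star(5, 40, 15), min_defect_area = 20), 5L)
  # disc with one rectangular notch
  d <- make_disc(30)
  cx <- (nrow(d) + 1) / 2
  notch <- d
  notch[(cx - 2):(cx + 2), (cx + 15):ncol(d)] <- 0L   # 5-px-deep slot
  area_notch <- sum(d) - sum(notch)
  expect_equal(count_ne_folds(notch, min_defect_area = area_notch / 3), 1L)
  expect_equal(count_ne_folds(notch, min_defect_area = area_notch * 2), 0L)
  # monotone non-increasing in the area threshold
  st <- make_star(5, 40, 15)
  counts <- vapply(c(1, 10, 50, 200, 1000), function(a)
    count_ne_folds(st, min_defect_area = a), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(count_ne_folds(matrix(c(1, 1, 0, 0), 2)), "10 px")
})

test_that("3D nuclear metrics match the analytic ellipsoid", {
  st <- make_ellipsoid(4, 2, 1.5, voxel = 0.25)
  m <- nucleus_3d_metrics(st, voxel_size = 0.25)
  expect_lt(abs(m$volume - 4 / 3 * pi * 4 * 2 * 1.5) / (4 / 3 * pi * 12), 0.05)
  expect_lt(abs(m$height - 3), 0.25 + 1e-9)
  sph <- make_ellipsoid(2, 2, 2, voxel = 0.2)
  expect_lt(abs(nucleus_3d_metrics(sph, 0.2)$elongation - 1), 0.05)
  expect_error(nucleus_3d_metrics(array(0L, c(3, 3, 3))), "empty")
})

test_that("elongation correlation handles exact and degenerate cases", {
  v <- c(1.2, 1.5, 2.0, 2.4, 3.1)
  expect_equal(elongation_correlation(v, v), 1.0)
  expect_equal(elongation_correlation(v, 10 - 2 * v), -1.0)
  expect_true(is.na(elongation_correlation(v, rep(2, 5))))
  expect_error(elongation_correlation(v, v[1:3]), "paired")
  expect_error(elongation_correlation(c(1, 2), c(1, 2)), "n >= 3")
  # coupled generator: recovered r close to the simulated coupling
  set.seed(91)
  cell <- runif(200, 1, 3)
  nuc <- 0.8 * cell + rnorm(200, 0, sqrt(1 - 0.8^2) * sd(cell))
  r <- elongation_correlation(cell, nuc)
  expect_gt(r, 0.7); expect_lt(r, 0.9)
})

test_that("fiber alignment fractions follow the uniform-angle analytics", {
  expect_equal(unname(fiber_alignment_fractions(rep(0, 10), rep(0, 10))),
               c(1, 1))
  set.seed(92)
  a <- runif(4000, 0, 90)
  f <- fiber_alignment_fractions(a, runif(4000, 0, 90), tolerance = 15)
  expect_lt(abs(f["cells_aligned"] - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 4000))
  none <- fiber_alignment_fractions(c(50, 60), c(5, 5), tolerance = 15)
  expect_equal(unname(none["cells_aligned"]), 0)
  expect_true(is.na(none["nuclei_aligned_given_cell"]))
})
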