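# Agent-based cohort simulator: biased persistent random walk with a single
# dwell-then-pass constriction, calibrated post-constriction modifiers, and
# full latent-state bookkeeping for recovery tests.

.cta_env <- new.env(parent = emptyenv())

#' Pre-draw every random quantity the simulator consumes
#'
#' Drawing all randomness up front (matrices indexed cell x frame) makes the
#' trajectory a continuous deterministic function of the phenotype parameters
#' given the RNG state, which the directionality calibration exploits
#' (common random numbers).
#' @noRd
.make_draws <- function(n, n_frames, step_cv) {
  sl <- sqrt(log(1 + step_cv^2))
  list(
    eps = matrix(stats::rnorm(n * n_frames), n, n_frames),
    jit = matrix(stats::rlnorm(n * n_frames, -sl^2 / 2, sl), n, n_frames),
    u_dwell = stats::runif(n),
    u_pass = stats::runif(n),
    u_state1 = stats::runif(n),
    u_state2 = stats::runif(n),
    u_x0 = stats::runif(n),
    u_y0 = stats::runif(n),
    th0 = stats::rnorm(n),
    th0_unif = stats::runif(n, -pi, pi),
    ecc_eps = matrix(stats::rnorm(n * n_frames), n, n_frames)
  )
}

# phase codes
.PH_PRE <- 0L; .PH_DWELL <- 1L; .PH_CROSS <- 2L; .PH_POST <- 3L

#' Core trajectory engine (vectorized over cells)
#' @noRd
.sim_core <- function(ph, n, geom, dt, n_frames, sigma_post, draws,
                      x0_range = c(2, 12)) {
  p <- ph$persistence; b <- ph$gradient_bias
  sig_pre <- ph$noise_sigma
  l0 <- ph$base_speed * dt / 60
  cx <- geom$constriction_x; ex <- constriction_exit(geom)
  L <- geom$chamber_length; W <- geom$chamber_width; sat <- geom$saturation_x
  kap <- if (p + b > 0) p / (p + b) else 0
  stat_sd <- function(s) if (kap < 1 && kap > 0) s / sqrt(1 - kap^2) else s

  X <- Y <- matrix(NA_real_, n, n_frames)
  PH <- matrix(.PH_PRE, n, n_frames)
  x <- x0_range[1] + diff(x0_range) * draws$u_x0
  y <- W * (0.2 + 0.6 * draws$u_y0)
  theta <- if (p + b > 0) draws$th0 * stat_sd(sig_pre) else draws$th0_unif
  # cells seeded past the pillar (nonstandard x0_range) start post-constriction
  phase <- ifelse(x < cx, .PH_PRE, .PH_POST)
  dwell_total <- if (ph$dwell_mean_frames > 1)
    1L + stats::qgeom(draws$u_dwell, 1 / ph$dwell_mean_frames) else rep(1L, n)
  pass <- draws$u_pass <= ph$pass_prob
  dwell_left <- dwell_total
  entry_idx <- exit_idx <- rep(NA_integer_, n)
  sig <- ifelse(phase == .PH_POST, sigma_post, sig_pre)
  smult <- ifelse(phase == .PH_POST, ph$post_speed_factor, 1)
  X[, 1] <- x; Y[, 1] <- y; PH[, 1] <- phase

  for (t in 2:n_frames) {
    mv <- which(phase == .PH_PRE | phase == .PH_POST)
    if (length(mv)) {
      th <- theta[mv]
      if (p + b > 0) th <- atan2(p * sin(th), p * cos(th) + b)
      th <- th + draws$eps[mv, t] * sig[mv]
      g <- ifelse(x[mv] < sat, 1, pmax(0.02, 1 - (x[mv] - sat) / (L - sat)))
      step <- l0 * draws$jit[mv, t] * smult[mv] * g
      nx <- x[mv] + step * cos(th)
      ny <- y[mv] + step * sin(th)
      ny <- ifelse(ny < 0, -ny, ifelse(ny > W, 2 * W - ny, ny))
      # reflective at the cell inlet; arrest (clamp) at the chemoattractant
      # end, where saturated cells stop rather than bounce
      nx <- pmin(ifelse(nx < 0, -nx, nx), L)
      x[mv] <- nx; y[mv] <- ny; theta[mv] <- th
      hit <- mv[phase[mv] == .PH_PRE & nx >= cx]
      if (length(hit)) {
        x[hit] <- cx
        phase[hit] <- .PH_DWELL
        entry_idx[hit] <- t
      }
    }
    dw <- which(phase == .PH_DWELL)
    if (length(dw)) {
      dwell_left[dw] <- dwell_left[dw] - 1L
      done <- dw[dwell_left[dw] <= 0L & pass[dw]]
      phase[done] <- .PH_CROSS
    }
    cr <- which(phase == .PH_CROSS)
    if (length(cr)) {
      x[cr] <- x[cr] + l0 * draws$jit[cr, t]
      out <- cr[x[cr] > ex]
      if (length(out)) {
        phase[out] <- .PH_POST
        exit_idx[out] <- t
        sig[out] <- sigma_post
        smult[out] <- ph$post_speed_factor
        theta[out] <- draws$eps[out, t] * stat_sd(sigma_post)
      }
    }
    X[, t] <- x; Y[, t] <- y; PH[, t] <- phase
  }

  post_state <- ifelse(draws$u_state1 < ph$polarity_loss_prob, "depolarized",
                ifelse(draws$u_state2 < ph$keratocyte_prob, "keratocyte",
                       "amoeboid"))
  post_state[is.na(exit_idx)] <- NA_character_
  list(X = X, Y = Y, PH = PH, entry_idx = entry_idx, exit_idx = exit_idx,
       dwell_total = dwell_total, post_state = post_state)
}

#' net/path directionality of one coordinate segment
#' @noRd
.seg_dir <- function(x, y) {
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path <= 0) return(0)
  sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2) / path
}

#' post/pre median directionality ratio of a raw simulation (internal,
#' mirrors the pipeline's segment rule: pre = frames before first entry,
#' post = frames from first exit, trimmed at saturation_x)
#' @noRd
.dir_ratio <- function(sim, geom, min_pts = 3L, min_final_x = 100) {
  n <- nrow(sim$X)
  pre <- post <- rep(NA_real_, n)
  sat <- geom$saturation_x
  nf <- ncol(sim$X)
  for (i in seq_len(n)) {
    if (sim$X[i, nf] - sim$X[i, 1] < min_final_x) next  # exclusion filter
    e <- sim$entry_idx[i]
    if (!is.na(e) && e - 1L >= min_pts)
      pre[i] <- .seg_dir(sim$X[i, 1:(e - 1L)], sim$Y[i, 1:(e - 1L)])
    xo <- sim$exit_idx[i]
    if (!is.na(xo)) {
      idx <- xo:ncol(sim$X)
      ov <- which(sim$X[i, idx] > sat)
      if (length(ov)) idx <- idx[seq_len(ov[1] - 1L)]
      if (length(idx) >= min_pts)
        post[i] <- .seg_dir(sim$X[i, idx], sim$Y[i, idx])
    }
  }
  if (all(is.na(pre)) || all(is.na(post))) return(NA_real_)
  stats::median(post, na.rm = TRUE) / stats::median(pre, na.rm = TRUE)
}

#' Calibrate the post-segment heading noise for a target directionality ratio
#'
#' Deterministic: a pilot cohort with a fixed internal seed and common random
#' numbers makes the measured ratio a continuous monotone function of the
#' post-segment noise sigma, which is solved by bisection. Results are
#' memoized per (phenotype, geometry, dt, n_frames).
#' @noRd
.calibrate_sigma_post <- function(ph, geom, dt, n_frames,
                                  n_pilot = 2000L, pilot_seed = 104729L) {
  f <- ph$post_directionality_factor
  if (ph$noise_sigma == 0 || (ph$persistence + ph$gradient_bias) == 0)
    return(ph$noise_sigma)
  key <- paste(ph$base_speed, ph$persistence, ph$gradient_bias, ph$noise_sigma,
               ph$post_speed_factor, f, ph$dwell_mean_frames, ph$pass_prob,
               ph$step_cv, geom$constriction_x, geom$pillar_extent,
               geom$chamber_length, geom$chamber_width, geom$saturation_x,
               dt, n_frames, n_pilot, pilot_seed, sep = "|")
  hit <- .cta_env$calib[[key]]
  if (!is.null(hit)) return(hit)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(pilot_seed)
  draws <- .make_draws(n_pilot, n_frames, ph$step_cv)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  ratio_at <- function(s)
    .dir_ratio(.sim_core(ph, n_pilot, geom, dt, n_frames, s, draws), geom)
  lo <- 0.02; hi <- 3.0
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)   # decreasing in sigma
  out <- if (is.na(r_lo) || is.na(r_hi)) {
    warning("directionality calibration pilot produced no crossing cells; using noise_sigma")
    ph$noise_sigma
  } else if (f >= r_lo) {
    if (f > r_lo * 1.02)
      warning(sprintf("post_directionality_factor %.3g unattainable (max %.3g); clamping", f, r_lo))
    lo
  } else if (f <= r_hi) {
    hi
  } else {
    stats::uniroot(function(s) ratio_at(s) - f, c(lo, hi), tol = 1e-3)$root
  }
  if (is.null(.cta_env$calib)) .cta_env$calib <- list()
  .cta_env$calib[[key]] <- out
  out
}

#' Simulate a cohort of chemotaxing cells through a single constriction
#'
#' Each cell performs a biased persistent random walk toward +x:
#' `heading(t+1) = angle(persistence * heading(t) + gradient_bias * x_hat) + noise`,
#' with log-normal step-length jitter, reflective walls, and linear speed
#' decay beyond `saturation_x` (chemoattractant saturation arrest). On
#' reaching the constriction the cell dwells a geometric number of frames
#' (mean `dwell_mean_frames`), traverses the pillar, and continues with
#' `post_speed_factor` applied to its speed and with post-segment heading
#' noise calibrated so that the cohort's post/pre median-directionality ratio
#' equals `post_directionality_factor` (see the methods vignette).
#'
#' All randomness derives from `seed`; identical inputs give bit-identical
#' cohorts. Latent draws (entry/exit frames, dwell, post-constriction
#' morphology state) are recorded in `ground_truth`.
#'
#' @param phenotype a [phenotype_params()] object
#' @param n_cells number of cells (>= 1)
#' @param geometry a [device_geometry()]
#' @param dt frame interval, s
#' @param n_frames number of frames
#' @param seed integer seed (required; no hidden global state)
#' @param calibrate_directionality logical; disable to use `noise_sigma`
#'   unchanged in the post segment
#' @param x0_range starting-x interval at the cell inlet, um
#' @return object of class `cta_cohort`: list with `tracks` (a `cta_trackset`),
#'   `traces` (NULL until [generate_calcium_traces()]), `ground_truth`
#'   (data.frame), `seed`, `geometry`, `phenotype`
#' @examples
#' co <- simulate_cohort(phenotype_presets("control"), n_cells = 20, seed = 1)
#' head(co$ground_truth)
#' @export
simulate_cohort <- function(phenotype, n_cells, geometry = device_geometry(gap_width = 3),
                            dt = 30, n_frames = 180, seed,
                            calibrate_directionality = TRUE,
                            x0_range = c(2, 12)) {
  stopifnot(inherits(phenotype, "cta_phenotype"))
  if (n_cells < 1) cta_stop("n_cells must be >= 1")
  if (missing(seed)) cta_stop("seed is required")
  sigma_post <- if (calibrate_directionality)
    .calibrate_sigma_post(phenotype, geometry, dt, n_frames)
  else phenotype$noise_sigma

  set.seed(seed)
  draws <- .make_draws(n_cells, n_frames, phenotype$step_cv)
  sim <- .sim_core(phenotype, n_cells, geometry, dt, n_frames, sigma_post,
                   draws, x0_range = x0_range)

  frames <- 0:(n_frames - 1L)
  times <- frames * dt
  ecc_base <- matrix(0.80, n_cells, n_frames)
  ecc_base[sim$PH == .PH_DWELL | sim$PH == .PH_CROSS] <- 0.93
  for (i in seq_len(n_cells)) {
    if (is.na(sim$exit_idx[i])) next
    idx <- sim$exit_idx[i]:n_frames
    ecc_base[i, idx] <- switch(sim$post_state[i],
                               keratocyte = 0.87, depolarized = 0.55, 0.80)
  }
  ecc <- ecc_base + 0.02 * draws$ecc_eps
  ecc[] <- pmin(0.98, pmax(0.05, ecc))

  tracks <- lapply(seq_len(n_cells), function(i) {
    track(track_id = i, frames = frames, times = times,
          x = sim$X[i, ], y = sim$Y[i, ],
          attachments = list(eccentricity = ecc[i, ]))
  })
  ts <- trackset(tracks, frame_interval = dt, geometry = geometry,
                 provenance = list(source = "simulate_cohort", seed = seed))

  gt <- data.frame(
    track_id = seq_len(n_cells),
    phenotype = phenotype$label,
    entry_frame = frames[sim$entry_idx],
    exit_frame = frames[sim$exit_idx],
    dwell_frames = ifelse(is.na(sim$entry_idx), NA_integer_, sim$dwell_total),
    post_state = sim$post_state,
    spike = NA, spike_time = NA_real_,
    vesicle_pre = NA_integer_, vesicle_post = NA_integer_,
    pmlc_ratio = NA_real_,
    stringsAsFactors = FALSE)

  structure(list(tracks = ts, traces = NULL, ground_truth = gt, seed = seed,
                 geometry = geometry, phenotype = phenotype,
                 dt = dt, n_frames = n_frames, sigma_post = sigma_post),
            class = "cta_cohort")
}

#' @export
print.cta_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort '%s': %d cells x %d frames (dt = %g s, seed %d)\n",
              x$phenotype$label, nrow(x$ground_truth), x$n_frames, x$dt, x$seed))
  cat(sprintf("  crossed constriction: %d; traces: %s\n",
              sum(!is.na(x$ground_truth$exit_frame)),
              if (is.null(x$traces)) "none" else "attached"))
  invisible(x)
}

#' Attach calcium traces to a simulated cohort
#'
#' Each trace is `baseline * (1 + noise_cv * N(0,1))`, floored at zero, plus
#' - with probability `spike_prob` of the cohort phenotype, for cells that
#' crossed - a single exponentially decaying spike initiated at a frame where
#' the cell lies within one cell length past the pillar exit. Spike times are
#' recorded in the ground truth.
#'
#' @param cohort a `cta_cohort`
#' @param baseline baseline fluorescence, a.u.
#' @param noise_cv multiplicative noise CV
#' @param spike_amp spike amplitude, a.u.
#' @param spike_decay spike decay constant, s
#' @param seed integer seed
#' @return the cohort with `traces` attached (list of `cta_trace`) and
#'   ground-truth spike columns filled; trace intensities are also attached
#'   to the tracks (written as MEAN_INTENSITY)
#' @export
generate_calcium_traces <- function(cohort, baseline = 100, noise_cv = 0.1,
                                    spike_amp = 400, spike_decay = 90, seed) {
  stopifnot(inherits(cohort, "cta_cohort"))
  if (missing(seed)) cta_stop("seed is required")
  set.seed(seed)
  geom <- cohort$geometry
  ex <- constriction_exit(geom)
  ph <- cohort$phenotype
  ids <- names(cohort$tracks$tracks)
  traces <- vector("list", length(ids))
  gt <- cohort$ground_truth
  for (k in seq_along(ids)) {
    tr <- cohort$tracks$tracks[[k]]
    nf <- length(tr$times)
    inten <- pmax(0, baseline * (1 + noise_cv * stats::rnorm(nf)))
    spiked <- FALSE; t0 <- NA_real_
    crossed <- !is.na(gt$exit_frame[k])
    if (crossed && stats::runif(1) < ph$spike_prob) {
      win <- which(tr$x > ex & tr$x <= ex + geom$cell_length)
      win <- win[win >= which(tr$frames == gt$exit_frame[k])]
      if (length(win)) {
        onset <- win[sample.int(length(win), 1)]
        t0 <- tr$times[onset]
        add <- spike_amp * exp(-(tr$times - t0) / spike_decay)
        add[tr$times < t0] <- 0
        inten <- inten + add
        spiked <- TRUE
      }
    }
    traces[[k]] <- structure(list(track_id = tr$track_id, times = tr$times,
                                  intensity = inten, x = tr$x),
                             class = "cta_trace")
    cohort$tracks$tracks[[k]]$attachments$intensity <- inten
    gt$spike[k] <- spiked
    gt$spike_time[k] <- t0
  }
  cohort$ground_truth <- gt
  cohort$traces <- traces
  cohort
}

#' Negative-binomial mean whose distribution has the target median
#'
#' Chooses mu so that P(X <= m-1) + P(X <= m) = 1, centering the median m in
#' its attainment interval (maximal margin on both sides).
#' @noRd
.nb_mu_for_median <- function(m, size) {
  if (m == 0) return(0.3)
  stats::uniroot(function(mu)
    stats::pnbinom(m - 1, size = size, mu = mu) +
      stats::pnbinom(m, size = size, mu = mu) - 1,
    c(1e-3, 10 * m + 10))$root
}

#' Draw per-cell nuclear-envelope vesicle counts
#'
#' Pre- and post-constriction counts are negative-binomial with means chosen
#' so the distribution medians equal the phenotype's
#' `vesicle_median_pre`/`vesicle_median_post`. Each cell is also assigned a
#' cortical pMLC II polarity ratio positively coupled to its post-constriction
#' vesicle count, for scatter summaries.
#'
#' @param cohort a `cta_cohort`
#' @param dispersion negative-binomial size parameter
#' @param seed integer seed
#' @return the cohort with ground-truth columns `vesicle_pre`, `vesicle_post`,
#'   `pmlc_ratio` filled
#' @export
generate_vesicle_counts <- function(cohort, dispersion = 5, seed) {
  stopifnot(inherits(cohort, "cta_cohort"))
  if (missing(seed)) cta_stop("seed is required")
  set.seed(seed)
  ph <- cohort$phenotype
  n <- nrow(cohort$ground_truth)
  mu_pre <- .nb_mu_for_median(ph$vesicle_median_pre, dispersion)
  mu_post <- .nb_mu_for_median(ph$vesicle_median_post, dispersion)
  pre <- stats::rnbinom(n, size = dispersion, mu = mu_pre)
  post <- stats::rnbinom(n, size = dispersion, mu = mu_post)
  cohort$ground_truth$vesicle_pre <- pre
  cohort$ground_truth$vesicle_post <- post
  cohort$ground_truth$pmlc_ratio <-
    pmax(0.5, 1 + 0.12 * post + stats::rnorm(n, 0, 0.15))
  cohort
}
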