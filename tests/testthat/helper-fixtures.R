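# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, closed forms, direct arithmetic) and
# never call the code paths they check.

make_disc <- function(r, n = 2 * r + 11) {
  cx <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) as.integer((i - cx)^2 + (j - cx)^2 <= r^2))
  m
}

make_square <- function(s, pad = 6) {
  m <- matrix(0L, s + 2 * pad, s + 2 * pad)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- 1L
  m
}

make_ellipse_mask <- function(a, b, theta_deg = 0, n = 2 * max(a, b) + 21) {
  th <- theta_deg * pi / 180
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    # x = column, y = row (package image convention)
    u <- (j - cx) * cos(th) + (i - cx) * sin(th)
    v <- -(j - cx) * sin(th) + (i - cx) * cos(th)
    as.integer((u / a)^2 + (v / b)^2 <= 1)
  })
}

# k-pointed star: radius alternates r_out / r_in -> k deep concavity defects
make_star <- function(k = 5, r_out = 40, r_in = 15, n = 2 * r_out + 21) {
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    dx <- j - cx; dy <- i - cx
    r <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    # boundary radius of the star polygon-ish outline
    ph <- (ang * k / 2) %% pi
    rb <- r_in + (r_out - r_in) * abs(cos(ph))^8
    as.integer(r <= rb & r <= r_out)
  })
}

make_ellipsoid <- function(a, b, c, voxel = 0.25, pad = 3) {
  nx <- ceiling(2 * a / voxel) + 2 * pad
  ny <- ceiling(2 * b / voxel) + 2 * pad
  nz <- ceiling(2 * c / voxel) + 2 * pad
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  arr <- array(0L, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    w <- 1 - ((z - cz) * voxel / c)^2
    if (w <= 0) next
    arr[, , z] <- outer(seq_len(ny), seq_len(nx), function(i, j)
      as.integer(((j - cx) * voxel / a)^2 + ((i - cy) * voxel / b)^2 <= w))
  }
  arr
}

# --- track fixtures -------------------------------------------------------

straight_track <- function(id = 1, n = 10, step_x = 30, dt = 30) {
  track(id, frames = 0:(n - 1), times = (0:(n - 1)) * dt,
        x = (0:(n - 1)) * step_x, y = rep(0, n))
}

zigzag_track <- function(id = 1) {
  # (0,0) -> (10,10) -> (20,0) over 2 min
  track(id, frames = 0:2, times = c(0, 60, 120),
        x = c(0, 10, 20), y = c(0, 10, 0))
}

loop_track <- function(id = 1) {
  track(id, frames = 0:4, times = (0:4) * 30,
        x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
}

# --- independent oracles --------------------------------------------------

# closed-form eigenfunction expansion of the fixed-boundary diffusion problem
fourier_deviation <- function(t, D_cm2s = 5e-6, L = 300, nmax = 400,
                              x = seq(0, L, by = 1)) {
  D <- D_cm2s * 1e8
  n <- seq_len(nmax)
  dev <- vapply(x, function(xx)
    sum(2 * (-1)^n / (n * pi) * sin(n * pi * xx / L) *
          exp(-D * n^2 * pi^2 * t / L^2)), 0)
  max(abs(dev))
}

fourier_establishment <- function(tol = 0.1, D_cm2s = 5e-6, L = 300,
                                  t_grid = seq(0.5, 4000, by = 0.5)) {
  for (t in t_grid) if (fourier_deviation(t, D_cm2s, L) < tol) return(t)
  NA_real_
}

# naive per-frame scan of the first-entry/first-exit split rule
bf_split_scan <- function(x, cx, ex) {
  n <- length(x)
  pre <- during <- post <- integer(0)
  state <- "pre"
  for (i in seq_len(n)) {
    if (state == "pre") {
      if (x[i] >= cx) state <- if (x[i] > ex) "post" else "during"
    } else if (state == "during") {
      if (x[i] > ex) state <- "post"
    }
    if (state == "pre") pre <- c(pre, i)
    else if (state == "during") during <- c(during, i)
    else post <- c(post, i)
  }
  list(pre = pre, during = during, post = post)
}

# naive per-sample windowing of the calcium fold change
bf_fold_change <- function(x, inten, cx, ex, w) {
  pre <- inten[x >= cx - w & x < cx]
  post <- inten[x > ex & x <= ex + w]
  if (!length(pre) || !length(post) || mean(pre) == 0) return(NA_real_)
  mean(post) / mean(pre)
}

# exact binomial CI (Clopper-Pearson)
binom_ci <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

small_run_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$simulate$n_cells <- 40L
  cfg$simulate$n_frames <- 120L
  cfg$analysis$n_boot <- 200L
  cfg$render$n_frames <- 1L
  cfg$phenotypes <- cfg$phenotypes[c("control", "knockout")]
  cfg
}
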