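#' Solve the 1D chemoattractant diffusion gradient in the chamber
#'
#' Solves dC/dt = D d2C/dx2 on \[0, chamber_length\] with fixed-concentration
#' (reservoir) boundaries C(0) = 0 at the cell inlet and C(L) = `C0_boundary`
#' at the chemoattractant inlet, initial condition C = 0 in the interior.
#' The steady state is the linear profile C(x) = C0 x / L. Integration uses
#' the unconditionally stable Crank-Nicolson scheme with a constant-coefficient
#' tridiagonal (Thomas) solve.
#'
#' @param geometry a [device_geometry()] object
#' @param D diffusion coefficient, cm^2/s (default 5e-6, typical small peptide)
#' @param C0_boundary source concentration (profiles are reported relative to it)
#' @param t_end final time, s
#' @param dx grid spacing, um; must divide `chamber_length`
#' @param dt time step, s
#' @param save_every interval between saved profiles, s
#' @return object of class `cta_field`: list with `x_grid` (um), `times` (s),
#'   `C` (time x space matrix, normalized to C0), `D` (cm^2/s), `C0`
#' @examples
#' f <- solve_gradient(device_geometry(), t_end = 120)
#' gradient_establishment_time(f, tol = 0.1)
#' @export
solve_gradient <- function(geometry = device_geometry(), D = 5e-6,
                           C0_boundary = 1, t_end = 3600, dx = 1, dt = 0.5,
                           save_every = 1) {
  if (D <= 0 || dx <= 0 || dt <= 0 || t_end <= 0 || save_every <= 0)
    cta_stop("D, dx, dt, t_end and save_every must all be positive")
  if (C0_boundary <= 0) cta_stop("C0_boundary must be positive")
  L <- geometry$chamber_length
  n_cells <- L / dx
  if (abs(n_cells - round(n_cells)) > 1e-9)
    cta_stop("dx = ", dx, " um does not divide the chamber length ", L, " um")
  n_cells <- round(n_cells)
  x <- seq(0, L, by = dx)
  N <- length(x)
  D_um <- D * 1e8                       # cm^2/s -> um^2/s
  a <- D_um * dt / dx^2

  n_int <- N - 2L
  # constant-coefficient tridiagonal (Thomas) solver factory: diagonal dia,
  # off-diagonals off (symmetric)
  make_thomas <- function(dia, off) {
    cp <- numeric(n_int)
    cp[1] <- off / dia
    for (i in 2:n_int) cp[i] <- off / (dia - off * cp[i - 1])
    function(d) {
      dp <- numeric(n_int)
      dp[1] <- d[1] / dia
      for (i in 2:n_int) dp[i] <- (d[i] - off * dp[i - 1]) / (dia - off * cp[i - 1])
      u <- numeric(n_int)
      u[n_int] <- dp[n_int]
      for (i in (n_int - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
      u
    }
  }
  # Crank-Nicolson: (1+a) u_i - a/2 (u_{i-1}+u_{i+1}) = rhs
  thomas_cn <- make_thomas(1 + a, -a / 2)
  # Rannacher startup: two backward-Euler half-steps damp the high-mode
  # content of the discontinuous initial profile that CN would leave ringing
  a_be <- a / 2
  thomas_be <- make_thomas(1 + 2 * a_be, -a_be)

  u <- rep(0, N); u[N] <- 1             # normalized to C0
  n_steps <- ceiling(t_end / dt)
  save_stride <- max(1L, round(save_every / dt))
  save_idx <- unique(c(seq(0L, n_steps, by = save_stride), n_steps))
  Cout <- matrix(NA_real_, length(save_idx), N)
  times <- save_idx * dt
  Cout[1, ] <- u
  row <- 2L
  interior <- 2:(N - 1)
  for (s in seq_len(n_steps)) {
    if (s == 1L) {
      for (half in 1:2) {
        rhs <- u[interior]
        rhs[n_int] <- rhs[n_int] + a_be * 1
        u[interior] <- thomas_be(rhs)
      }
    } else {
      rhs <- (1 - a) * u[interior] +
        (a / 2) * (u[interior - 1] + u[interior + 1])
      rhs[n_int] <- rhs[n_int] + (a / 2) * 1   # implicit-side boundary term
      u[interior] <- thomas_cn(rhs)
    }
    if (row <= length(save_idx) && s == save_idx[row]) {
      Cout[row, ] <- u
      row <- row + 1L
    }
  }
  structure(list(x_grid = x, times = times, C = Cout, D = D, C0 = C0_boundary,
                 geometry = geometry),
            class = "cta_field")
}

#' @export
print.cta_field <- function(x, ...) {
  cat(sprintf("concentration field: %d positions x %d times (D = %g cm^2/s)\n",
              length(x$x_grid), length(x$times), x$D))
  invisible(x)
}

#' Time for the gradient to come within tolerance of the linear steady state
#'
#' Returns the first saved time at which
#' max_x |C(x,t) - x/L| < `tol` (concentrations normalized to C0). If the
#' tolerance is never reached within the solved time span, returns the
#' sentinel `NA_real_` (with a message) rather than erroring.
#'
#' @param field a `cta_field` from [solve_gradient()]
#' @param tol tolerance as a fraction of the source concentration C0
#' @return establishment time in seconds, or `NA_real_` if not established
#' @export
gradient_establishment_time <- function(field, tol = 0.1) {
  if (tol <= 0) cta_stop("tol must be positive")
  steady <- field$x_grid / max(field$x_grid)
  dev <- apply(field$C, 1, function(p) max(abs(p - steady)))
  hit <- which(dev < tol)
  if (length(hit) == 0L) {
    message("gradient not established within ", max(field$times), " s at tol = ", tol)
    return(NA_real_)
  }
  field$times[hit[1]]
}

#' Export a concentration field as CSV (columns x_um, t_s, C_norm)
#'
#' @param field a `cta_field`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_field_csv <- function(field, path) {
  dt <- data.table::data.table(
    x_um = rep(field$x_grid, each = length(field$times)),
    t_s = rep(field$times, times = length(field$x_grid)),
    C_norm = as.vector(field$C))
  data.table::fwrite(dt, path)
  invisible(path)
}
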