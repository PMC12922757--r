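# data.table is used via :: only; declare awareness for [.data.table dispatch
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

# user-facing errors carry class "cta_error" (CLI exit code 1)
cta_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("cta_error", "error")))
}

#' Shift a matrix by (di, dj), filling exposed cells
#' @noRd
mat_shift <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  src_r <- ri - di; src_c <- ci - dj
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ri[ok_r], ci[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Binary erosion with a 3x3 square structuring element
#'
#' Repeated `iter` times. Input is coerced to logical.
#'
#' @param mask logical or 0/1 matrix
#' @param iter number of erosion passes (band width in pixels)
#' @return logical matrix
#' @export
bin_erode <- function(mask, iter = 1) {
  m <- mask > 0
  for (k in seq_len(iter)) {
    out <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      out <- out & mat_shift(m, di, dj, fill = FALSE)
    }
    m <- out
  }
  m
}

#' Binary dilation with a 3x3 square structuring element
#' @inheritParams bin_erode
#' @return logical matrix
#' @export
bin_dilate <- function(mask, iter = 1) {
  m <- mask > 0
  for (k in seq_len(iter)) {
    out <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      out <- out | mat_shift(m, di, dj, fill = FALSE)
    }
    m <- out
  }
  m
}

#' Connected-component labelling of a binary matrix
#'
#' Two-pass row-run labelling with union-find merging; 8- or 4-connectivity.
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 8 (default) or 4
#' @return integer matrix of labels, 0 = background
#' @export
label_connected <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  # collect runs per row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (i in seq_len(nr)) {
    r <- m[i, ]
    if (!any(r)) next
    d <- diff(c(FALSE, r, FALSE))
    s <- which(d == 1); e <- which(d == -1) - 1L
    run_row <- c(run_row, rep.int(i, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
  }
  n_run <- length(run_row)
  if (n_run == 0L) return(lab)
  parent <- seq_len(n_run)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  slack <- if (connectivity == 8L) 1L else 0L
  prev_idx <- integer(0)
  rows <- unique(run_row)
  by_row <- split(seq_len(n_run), run_row)
  for (ri in seq_along(rows)) {
    cur_idx <- by_row[[ri]]
    if (ri > 1L && rows[ri] == rows[ri - 1L] + 1L) {
      for (a in cur_idx) for (b in prev_idx) {
        if (run_s[a] <= run_e[b] + slack && run_e[a] >= run_s[b] - slack) union(a, b)
      }
    }
    prev_idx <- cur_idx
  }
  roots <- vapply(seq_len(n_run), find, 0L)
  ids <- match(roots, unique(roots))
  for (k in seq_len(n_run)) lab[run_row[k], run_s[k]:run_e[k]] <- ids[k]
  lab
}

#' 3x3 box blur with zero padding (output has a 1-px pad border)
#' @noRd
box_blur3_pad <- function(m) {
  p <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  s <- matrix(0, nrow(p), ncol(p))
  for (di in -1:1) for (dj in -1:1) s <- s + mat_shift(p, di, dj, fill = 0)
  s / 9
}

#' Polygon area by the shoelace formula
#' @noRd
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Scanline fill of a simple polygon onto an nr x nc pixel grid
#'
#' Pixel (i, j) is filled when its center (x = j, y = i) lies inside the
#' polygon. Used to rasterize convex hulls.
#' @noRd
polygon_fill <- function(px, py, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  n <- length(px)
  x2 <- px[c(2:n, 1)]; y2 <- py[c(2:n, 1)]
  for (i in seq_len(nr)) {
    yc <- i
    crosses <- ((py <= yc & y2 > yc) | (y2 <= yc & py > yc))
    if (!any(crosses)) next
    xs <- px[crosses] + (yc - py[crosses]) * (x2[crosses] - px[crosses]) / (y2[crosses] - py[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      j1 <- ceiling(xs[k]); j2 <- floor(xs[k + 1])
      if (j2 >= j1) out[i, max(1, j1):min(nc, j2)] <- TRUE
    }
  }
  out
}

#' Fold an angle in degrees into [0, 90] relative to a reference axis
#' @noRd
fold_angle_deg <- function(a, reference = 0) {
  d <- (a - reference) %% 180
  ifelse(d > 90, 180 - d, d)
}

#' Convex hull of pixel corners; returns hull vertices (x, y)
#' @noRd
pixel_hull <- function(xs, ys) {
  cx <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  h <- grDevices::chull(cx, cy)
  list(x = cx[h], y = cy[h])
}
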