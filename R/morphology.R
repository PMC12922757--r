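# Shape metrics on label images, keratocyte-like classification, and nuclear
# morphology. Image convention: matrices with x = column index, y = row index
# (pixel centers at integer coordinates); angles measured from the +x
# (migration / fiber) axis and folded into [0, 90] degrees.

#' Perimeter of a binary mask by an anti-aliased boundary walk
#'
#' The mask is smoothed with a 3x3 box filter and the 0.5-level contour is
#' traced with sub-pixel (marching-squares) interpolation; the perimeter is
#' the traced polygon length. This keeps a digital disc's form factor at
#' ~0.99 and a digital square's at ~pi/4, where naive pixel-edge counting
#' inflates perimeters by up to ~27% (disc) and chain-code weightings cannot
#' serve discs and squares simultaneously.
#'
#' @param mask logical or 0/1 matrix (single object)
#' @return perimeter in pixel units
#' @export
mask_perimeter <- function(mask) {
  m <- mask > 0
  if (sum(m) == 0) return(0)
  if (sum(m) == 1) return(4)        # single pixel: crack length
  z <- box_blur3_pad(m * 1)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) return(4 * sqrt(sum(m)))
  sum(vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), 0))
}

.one_label_metrics <- function(mask, pixel_size, reference_axis) {
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  npx <- nrow(idx)
  area_px <- npx
  cxm <- mean(xs); cym <- mean(ys)
  mu20 <- mean((xs - cxm)^2); mu02 <- mean((ys - cym)^2)
  mu11 <- mean((xs - cxm) * (ys - cym))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  orient_raw <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  orientation <- fold_angle_deg(orient_raw, reference_axis)
  per_px <- mask_perimeter(mask)
  # solidity by pixel counting against the rasterized pixel-center hull:
  # exact 1 for convex digitized shapes, where a corner-hull area ratio
  # understates small ellipses by up to ~10%
  solidity <- if (npx >= 3) {
    h <- grDevices::chull(xs, ys)
    filled <- polygon_fill(xs[h], ys[h], nrow(mask), ncol(mask)) | mask
    npx / sum(filled)
  } else 1
  form_factor <- if (per_px > 0) 4 * pi * area_px / per_px^2 else NA_real_
  # bounding box in the reference-axis frame
  ar <- reference_axis * pi / 180
  u <- (xs - cxm) * cos(ar) + (ys - cym) * sin(ar)
  v <- -(xs - cxm) * sin(ar) + (ys - cym) * cos(ar)
  eu <- diff(range(u)) + 1; ev <- diff(range(v)) + 1
  aspect_ratio <- max(eu, ev) / min(eu, ev)
  border <- any(ys == 1L | xs == 1L | ys == nrow(mask) | xs == ncol(mask))
  data.frame(area = area_px * pixel_size^2,
             perimeter = per_px * pixel_size,
             eccentricity = ecc, solidity = solidity,
             orientation = orientation, form_factor = form_factor,
             aspect_ratio = aspect_ratio,
             centroid_x = cxm * pixel_size, centroid_y = cym * pixel_size,
             touches_border = border)
}

#' Shape metrics per labeled object
#'
#' Computes, for every positive label of an integer label image: area,
#' anti-aliased perimeter (see [mask_perimeter()]), eccentricity of the
#' second-central-moment ellipse, solidity (area / pixel-corner convex-hull
#' area), orientation of the major axis relative to `reference_axis` folded
#' into \[0, 90\] degrees, form factor `4*pi*area/perimeter^2`, and the
#' aspect ratio of the bounding box aligned with the reference axis. Objects
#' touching the image border are flagged but their metrics are still returned.
#'
#' @param mask integer label matrix, 0 = background
#' @param pixel_size um per pixel (areas in um^2, perimeters in um)
#' @param reference_axis migration/fiber axis, degrees from +x
#' @return data.frame with one row per label
#' @examples
#' m <- matrix(0L, 40, 40); m[10:30, 10:30] <- 1L
#' shape_metrics(m)
#' @export
shape_metrics <- function(mask, pixel_size = 1, reference_axis = 0) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) cta_stop("label image contains no objects")
  out <- do.call(rbind, lapply(labs, function(l)
    cbind(label = l, .one_label_metrics(mask == l, pixel_size, reference_axis))))
  rownames(out) <- NULL
  out
}

#' Classify keratocyte-like morphology
#'
#' A cell is keratocyte-like when its major axis is more than 45 degrees off
#' the migration axis, its eccentricity exceeds 0.75, and its solidity
#' exceeds 0.9 (all inequalities strict). Accepts a [shape_metrics()] row
#' (or data.frame, vectorized).
#'
#' @param m data.frame with columns orientation, eccentricity, solidity
#' @param thresholds named list of the three strict thresholds
#' @return logical vector
#' @export
classify_keratocyte <- function(m, thresholds = list(orientation = 45,
                                                     eccentricity = 0.75,
                                                     solidity = 0.9)) {
  m$orientation > thresholds$orientation &
    m$eccentricity > thresholds$eccentricity &
    m$solidity > thresholds$solidity
}

#' Fraction of keratocyte-like cells per region
#'
#' `metrics` holds one row per (cell, frame) with a region label; a cell
#' counts as keratocyte-like in a region when the classifier fires on the
#' majority of its frames there.
#'
#' @param metrics data.frame with columns `cell`, `region`, and the
#'   [classify_keratocyte()] metric columns
#' @param region region to evaluate (default "after")
#' @param thresholds passed to [classify_keratocyte()]
#' @return fraction in \[0,1\], or `NA_real_` when the region is empty
#' @export
keratocyte_fraction <- function(metrics, region = "after",
                                thresholds = list(orientation = 45,
                                                  eccentricity = 0.75,
                                                  solidity = 0.9)) {
  d <- metrics[metrics$region == region, , drop = FALSE]
  if ("touches_border" %in% names(d))
    d <- d[!d$touches_border, , drop = FALSE]   # clipped objects are unusable
  if (!nrow(d)) return(NA_real_)
  k <- classify_keratocyte(d, thresholds)
  per_cell <- tapply(k, d$cell, function(v) mean(v) > 0.5)
  mean(per_cell)
}

#' Count nuclear-envelope folds as convexity defects
#'
#' NE folds/invaginations appear as concavities of the nuclear outline. The
#' nuclear mask's convex hull is rasterized; the defect set (hull minus mask)
#' is opened by one pixel to discard the 1-px discretization slivers that any
#' smooth digitized boundary produces, and each remaining connected component
#' with area >= `min_defect_area` counts as one fold.
#'
#' @param nucleus_mask logical or 0/1 matrix, a single nucleus
#' @param min_defect_area minimum defect area, um^2
#' @param pixel_size um per pixel
#' @param connectivity component connectivity (8 or 4)
#' @return integer fold count
#' @export
count_ne_folds <- function(nucleus_mask, min_defect_area = 1, pixel_size = 1,
                           connectivity = 8) {
  m <- nucleus_mask > 0
  if (sum(m) < 10) cta_stop("nucleus mask smaller than 10 px")
  idx <- which(m, arr.ind = TRUE)
  hull <- pixel_hull(idx[, 2], idx[, 1])
  hull_m <- polygon_fill(hull$x, hull$y, nrow(m), ncol(m))
  defects <- hull_m & !m
  defects <- bin_dilate(bin_erode(defects, 1), 1)   # opening: drop slivers
  if (!any(defects)) return(0L)
  lab <- label_connected(defects, connectivity)
  areas <- tabulate(lab[lab > 0]) * pixel_size^2
  sum(areas >= min_defect_area)
}

#' 3D nuclear morphology from a labeled z-stack
#'
#' @param stack 3D logical/0-1 array (y, x, z), a single nucleus
#' @param voxel_size um per voxel, length-3 (x, y, z) or scalar
#' @param reference_axis fiber axis in the xy plane, degrees from +x
#' @return list with `volume` (um^3), `height` (z extent, um), `elongation`
#'   (mid-plane bounding-box extent along the reference axis / perpendicular)
#' @export
nucleus_3d_metrics <- function(stack, voxel_size = 1, reference_axis = 0) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  occ <- stack > 0
  if (!any(occ)) cta_stop("empty nucleus stack")
  volume <- sum(occ) * prod(voxel_size)
  zocc <- which(apply(occ, 3, any))
  height <- (max(zocc) - min(zocc) + 1) * voxel_size[3]
  zmid <- zocc[ceiling(length(zocc) / 2)]
  sl <- occ[, , zmid]
  idx <- which(sl, arr.ind = TRUE)
  ar <- reference_axis * pi / 180
  xs <- idx[, 2] * voxel_size[1]; ys <- idx[, 1] * voxel_size[2]
  u <- xs * cos(ar) + ys * sin(ar)
  v <- -xs * sin(ar) + ys * cos(ar)
  eu <- diff(range(u)) + voxel_size[1]
  ev <- diff(range(v)) + voxel_size[2]
  list(volume = volume, height = height, elongation = eu / ev)
}

#' Pearson correlation of paired cell and nuclear aspect ratios
#'
#' @param cell_ar,nuc_ar equal-length numeric vectors, n >= 3
#' @return correlation coefficient, or `NA_real_` when either vector has zero
#'   variance
#' @export
elongation_correlation <- function(cell_ar, nuc_ar) {
  if (length(cell_ar) != length(nuc_ar)) cta_stop("vectors must be paired")
  if (length(cell_ar) < 3) cta_stop("need n >= 3 pairs")
  if (stats::sd(cell_ar) == 0 || stats::sd(nuc_ar) == 0) return(NA_real_)
  stats::cor(cell_ar, nuc_ar)
}

#' Fiber-alignment fractions of cells and their nuclei
#'
#' Orientations are given relative to the fiber axis and folded into
#' \[0, 90\] degrees; an object is aligned when its angle is <= `tolerance`.
#' Returns the fraction of aligned cells and, among aligned cells, the
#' fraction whose nuclei are also aligned (NA when no cell is aligned).
#'
#' @param cell_orientations,nucleus_orientations paired angles, degrees
#' @param tolerance alignment tolerance, degrees
#' @return named numeric vector (cells_aligned, nuclei_aligned_given_cell)
#' @export
fiber_alignment_fractions <- function(cell_orientations, nucleus_orientations,
                                      tolerance = 15) {
  if (length(cell_orientations) != length(nucleus_orientations))
    cta_stop("orientation vectors must be paired")
  ca <- fold_angle_deg(abs(cell_orientations))
  na_ <- fold_angle_deg(abs(nucleus_orientations))
  cell_ok <- ca <= tolerance
  f1 <- mean(cell_ok)
  f2 <- if (any(cell_ok)) mean(na_[cell_ok] <= tolerance) else NA_real_
  c(cells_aligned = f1, nuclei_aligned_given_cell = f2)
}
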