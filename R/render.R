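# Ground-truth image renderer: draws cells and nuclei as label masks plus
# nucleus / membrane / calcium / cortical-marker channels, one frame at a
# time. Images are plain matrices (x = column, y = row, pixel centers at
# integer coordinates) serialized as TSV text.

#' Write an image matrix as TSV text
#' @param m numeric or integer matrix
#' @param path output path
#' @export
write_image_txt <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a TSV text image written by [write_image_txt()]
#' @param path input path
#' @return numeric matrix
#' @export
read_image_txt <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

#' Rasterize a (possibly truncated) ellipse
#'
#' Pixels whose centers fall inside the ellipse centered at (cx, cy) um with
#' semi-axes (a, b) um, major axis at `angle` rad. `fan_fraction` > 0 cuts
#' away the rear of the shape perpendicular to `heading` (fan / half-disc
#' morphology): the shape is truncated at a line `(1 - 2*fan_fraction) *
#' extent` behind the center.
#' @noRd
.raster_ellipse <- function(nr, nc, pixel_size, cx, cy, a, b, angle,
                            heading = 0, fan_fraction = 0) {
  # bounding window in pixels
  rmax <- max(a, b) / pixel_size + 2
  i0 <- max(1L, floor(cy / pixel_size - rmax)); i1 <- min(nr, ceiling(cy / pixel_size + rmax))
  j0 <- max(1L, floor(cx / pixel_size - rmax)); j1 <- min(nc, ceiling(cx / pixel_size + rmax))
  out <- matrix(FALSE, nr, nc)
  if (i0 > i1 || j0 > j1) return(out)
  jj <- j0:j1; ii <- i0:i1
  dx <- outer(rep(1, length(ii)), jj * pixel_size - cx)
  dy <- outer(ii * pixel_size - cy, rep(1, length(jj)))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (fan_fraction > 0) {
    uh <- dx * cos(heading) + dy * sin(heading)
    # rear extent of the shape along the heading
    ext <- sqrt((a * cos(angle - heading))^2 + (b * sin(angle - heading))^2)
    inside <- inside & (uh >= -(1 - 2 * fan_fraction) * ext)
  }
  out[ii, jj] <- inside
  out
}

#' Render image frames from a simulated cohort
#'
#' Draws each cell and its nucleus on a chamber-sized canvas at the requested
#' frames. Amoeboid cells are ellipses (axis ratio `amoeboid_axis_ratio`)
#' elongated along the heading; keratocyte-like cells are ellipses (axis
#' ratio `keratocyte_axis_ratio`, optional rear fan truncation) with the
#' major axis perpendicular to the heading; depolarized cells are discs.
#' Nuclei are ~4-um discs, compressed to the gap width (area-preserving)
#' while the cell is inside the constriction. Cells overlapping after
#' rasterization are re-jittered up to `max_retries` times, then error.
#'
#' Channels: `nucleus` (nucleus mask intensity), `membrane` (1-px boundary
#' band), `calcium` (uniform at the cell's trace intensity, or
#' `calcium_baseline`), `cortical` (uniform interior with the boundary band of
#' `band_width` px multiplied by `cortical_ratio`; the band is defined by the
#' same erosion as the analysis in [cortex_cytosol_ratio()], so the identity
#' fixture closes).
#'
#' @param cohort a `cta_cohort`
#' @param pixel_size um per pixel
#' @param frames frame numbers to render (default: 3 spread over the movie)
#' @param cortical_ratio cortex/cytosol intensity ratio to paint (>= 1)
#' @param band_width cortical band width, px
#' @param shape_mode "auto" (use simulated per-cell states) or a single
#'   mode / per-cell vector of "amoeboid", "keratocyte", "depolarized"
#'   forced for every rendered frame
#' @param cells track ids to draw (default all; dense late-movie fields near
#'   the saturation arrest may be physically impossible to tile without
#'   overlap, in which case draw a subset)
#' @param cell_radius equivalent cell radius, um
#' @param amoeboid_axis_ratio,keratocyte_axis_ratio shape axis ratios
#' @param fan_fraction rear truncation of keratocyte shapes (0 = ellipse)
#' @param nucleus_diameter um
#' @param axis_jitter_sd SD of the per-cell polarity-axis jitter around the
#'   migration axis, degrees
#' @param interior_intensity cytosolic cortical-marker intensity, a.u.
#' @param calcium_baseline fallback calcium intensity when no traces attached
#' @param seed jitter seed for overlap resolution
#' @param max_retries placement attempts per cell
#' @return list of `cta_frame` objects: named `channels`, `cell_mask`,
#'   `nucleus_mask`, `pixel_size`, `frame_index`, `cells` (placement table)
#' @export
render_frames <- function(cohort, pixel_size = 1, frames = NULL,
                          cortical_ratio = 2, band_width = 3,
                          shape_mode = "auto", cells = NULL, cell_radius = 6,
                          amoeboid_axis_ratio = 1.8, keratocyte_axis_ratio = 2,
                          fan_fraction = 0, nucleus_diameter = 4,
                          axis_jitter_sd = 12, interior_intensity = 100,
                          calcium_baseline = 100, seed = 1, max_retries = 20) {
  stopifnot(inherits(cohort, "cta_cohort"))
  if (pixel_size <= 0) cta_stop("pixel_size must be > 0")
  if (cortical_ratio < 1) cta_stop("cortical_ratio must be >= 1")
  geom <- cohort$geometry
  trs <- cohort$tracks$tracks
  n_cells <- length(trs)
  all_frames <- trs[[1]]$frames
  if (is.null(frames))
    frames <- all_frames[unique(round(seq(2, length(all_frames) - 1, length.out = 3)))]
  if (!all(frames %in% all_frames)) cta_stop("requested frames not in the cohort")
  nr <- ceiling(geom$chamber_width / pixel_size)
  nc <- ceiling(geom$chamber_length / pixel_size)
  gt <- cohort$ground_truth
  modes_forced <- if (identical(shape_mode, "auto")) NULL
    else rep_len(shape_mode, n_cells)
  draw_cells <- if (is.null(cells)) seq_len(n_cells) else {
    if (!all(cells %in% seq_len(n_cells))) cta_stop("unknown cell ids in 'cells'")
    as.integer(cells)
  }
  set.seed(seed)

  lapply(frames, function(fr) {
    fi <- which(all_frames == fr)
    cell_mask <- matrix(0L, nr, nc)
    nuc_mask <- matrix(0L, nr, nc)
    placed <- vector("list", n_cells)
    for (k in draw_cells) {
      tr <- trs[[k]]
      x <- tr$x[fi]; y <- tr$y[fi]
      # The morphological polarity axis follows the chemotactic (migration)
      # axis with modest angular jitter, not the instantaneous velocity:
      # frame-to-frame headings in the realistic noise regime wander far too
      # widely to define a cell shape, and the classifier measures
      # orientation against the migration axis.
      heading <- stats::rnorm(1, 0, axis_jitter_sd * pi / 180)
      during <- !is.na(gt$entry_frame[k]) && fr >= gt$entry_frame[k] &&
        (is.na(gt$exit_frame[k]) || fr < gt$exit_frame[k])
      post <- !is.na(gt$exit_frame[k]) && fr >= gt$exit_frame[k]
      mode <- if (!is.null(modes_forced)) modes_forced[k]
        else if (post && !is.na(gt$post_state[k])) gt$post_state[k]
        else "amoeboid"
      ok <- FALSE
      for (try in 0:max_retries) {
        # jitter escalates with the retry count so dense fields can resolve
        cx <- x + if (try > 0) stats::rnorm(1, 0, 1 + 0.4 * try) else 0
        cy <- y + if (try > 0) stats::rnorm(1, 0, 1 + 0.4 * try) else 0
        cm <- switch(mode,
          amoeboid = .raster_ellipse(nr, nc, pixel_size, cx, cy,
            cell_radius * sqrt(amoeboid_axis_ratio),
            cell_radius / sqrt(amoeboid_axis_ratio), heading),
          keratocyte = .raster_ellipse(nr, nc, pixel_size, cx, cy,
            cell_radius * sqrt(keratocyte_axis_ratio),
            cell_radius / sqrt(keratocyte_axis_ratio), heading + pi / 2,
            heading = heading, fan_fraction = fan_fraction),
          depolarized = .raster_ellipse(nr, nc, pixel_size, cx, cy,
            cell_radius, cell_radius, 0),
          cta_stop("unknown shape mode '", mode, "'"))
        if (!any(cm)) { ok <- TRUE; break }  # off-canvas cell: skip silently
        if (!any(cell_mask[cm] > 0)) {
          cell_mask[cm] <- k
          # nucleus: disc, squeezed to the gap while inside the constriction
          rn <- nucleus_diameter / 2
          if (during && geom$gap_width / 2 < rn) {
            bn <- geom$gap_width / 2
            an <- rn^2 / bn       # area-preserving elongation along x
          } else {
            an <- bn <- rn
          }
          nm <- .raster_ellipse(nr, nc, pixel_size, cx, cy, an, bn, 0)
          nm <- nm & cm            # nucleus_mask subset of cell_mask
          nuc_mask[nm] <- k
          placed[[k]] <- data.frame(cell = k, x = cx, y = cy, mode = mode,
                                    heading = heading, during = during,
                                    post = post)
          ok <- TRUE
          break
        }
      }
      if (!ok) cta_stop("could not place cell ", k, " at frame ", fr,
                        " without overlap after ", max_retries, " retries")
    }
    # channels
    calcium <- matrix(0, nr, nc)
    cortical <- matrix(0, nr, nc)
    membrane <- matrix(0, nr, nc)
    nucleus_ch <- matrix(0, nr, nc)
    nucleus_ch[nuc_mask > 0] <- 150
    for (k in seq_len(n_cells)) {
      cm <- cell_mask == k
      if (!any(cm)) next
      interior <- bin_erode(cm, band_width)
      cortical[cm] <- interior_intensity * cortical_ratio
      cortical[interior] <- interior_intensity
      membrane[cm & !bin_erode(cm, 1)] <- 120
      ca <- if (!is.null(cohort$traces)) cohort$traces[[k]]$intensity[fi]
        else calcium_baseline
      calcium[cm] <- ca
    }
    structure(list(channels = list(nucleus = nucleus_ch, membrane = membrane,
                                   calcium = calcium, cortical = cortical),
                   cell_mask = cell_mask, nucleus_mask = nuc_mask,
                   pixel_size = pixel_size, frame_index = fr,
                   cells = do.call(rbind, placed)),
              class = "cta_frame")
  })
}

#' @export
print.cta_frame <- function(x, ...) {
  cat(sprintf("rendered frame %d: %d x %d px (%g um/px), %d cells\n",
              x$frame_index, nrow(x$cell_mask), ncol(x$cell_mask),
              x$pixel_size, length(unique(x$cell_mask[x$cell_mask > 0]))))
  invisible(x)
}

#' Write rendered frames to a directory as TSV text images
#'
#' One file per channel and mask per frame
#' (`frame<NNN>_<channel>.tsv`, `frame<NNN>_cell_mask.tsv`, ...), plus a
#' `frames_manifest.json` listing files, pixel size and frame indices.
#'
#' @param frames list of `cta_frame` from [render_frames()]
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(frames, function(fr) {
    tag <- sprintf("frame%03d", fr$frame_index)
    files <- c()
    for (ch in names(fr$channels)) {
      f <- file.path(dir, paste0(tag, "_", ch, ".tsv"))
      write_image_txt(fr$channels[[ch]], f)
      files[ch] <- basename(f)
    }
    for (mk in c("cell_mask", "nucleus_mask")) {
      f <- file.path(dir, paste0(tag, "_", mk, ".tsv"))
      write_image_txt(fr[[mk]], f)
      files[mk] <- basename(f)
    }
    list(frame_index = fr$frame_index, pixel_size = fr$pixel_size,
         files = as.list(files))
  })
  mf <- file.path(dir, "frames_manifest.json")
  jsonlite::write_json(entries, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
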