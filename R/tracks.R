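# Track container and constriction-aligned kinematics.

#' Construct a single cell track
#'
#' @param track_id scalar id
#' @param frames integer frame numbers
#' @param times acquisition times, s (strictly increasing)
#' @param x,y centroid positions, um
#' @param attachments named list of per-frame vectors (e.g. `eccentricity`,
#'   `intensity`), each the same length as `frames`
#' @return object of class `cta_track`
#' @export
track <- function(track_id, frames, times, x, y, attachments = list()) {
  n <- length(frames)
  if (n < 2L) cta_stop("a track needs at least 2 points (track ", track_id, ")")
  if (length(times) != n || length(x) != n || length(y) != n)
    cta_stop("frames, times, x, y must have equal length (track ", track_id, ")")
  if (any(diff(times) <= 0))
    cta_stop("times must be strictly increasing (track ", track_id, ")")
  for (nm in names(attachments))
    if (length(attachments[[nm]]) != n)
      cta_stop("attachment '", nm, "' length mismatch (track ", track_id, ")")
  structure(list(track_id = track_id, frames = as.integer(frames),
                 times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), attachments = attachments),
            class = "cta_track")
}

#' Construct a set of tracks
#'
#' @param tracks list of [track()] objects with unique ids
#' @param frame_interval frame interval, s (uniform within 1%)
#' @param geometry a [device_geometry()]
#' @param provenance free-form list (source file, filter log, ...)
#' @return object of class `cta_trackset`
#' @export
trackset <- function(tracks, frame_interval, geometry = device_geometry(),
                     provenance = list()) {
  ids <- vapply(tracks, function(t) as.character(t$track_id), "")
  if (anyDuplicated(ids))
    cta_stop("duplicate track ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (tr in tracks) {
    dts <- diff(tr$times)
    if (any(abs(dts - frame_interval) > 0.01 * frame_interval))
      cta_stop("track ", tr$track_id, ": frame interval not uniform within 1%")
  }
  names(tracks) <- ids
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 geometry = geometry, provenance = provenance),
            class = "cta_trackset")
}

#' @export
print.cta_trackset <- function(x, ...) {
  cat(sprintf("track set: %d tracks, frame interval %g s\n",
              length(x$tracks), x$frame_interval))
  invisible(x)
}

#' @export
length.cta_trackset <- function(x) length(x$tracks)

#' Subset a track by point indices (keeps attachments aligned)
#' @param tr a `cta_track`
#' @param idx integer indices (>= 2 of them)
#' @export
subset_track <- function(tr, idx) {
  track(tr$track_id, tr$frames[idx], tr$times[idx], tr$x[idx], tr$y[idx],
        lapply(tr$attachments, function(a) a[idx]))
}

#' Read a spots-table CSV into a track set
#'
#' Expects the TrackMate-dialect columns `TRACK_ID`, `FRAME`, `POSITION_T`,
#' `POSITION_X`, `POSITION_Y`; optional `MEAN_INTENSITY` and `ECCENTRICITY`
#' become the `intensity` and `eccentricity` attachments. Rows with missing
#' required values are dropped and counted in the provenance log; a duplicated
#' (track, frame) pair is an error naming the pair.
#'
#' @param path CSV path
#' @param frame_interval frame interval, s; inferred from POSITION_T when NULL
#' @param geometry a [device_geometry()]
#' @return a `cta_trackset`
#' @export
read_tracks <- function(path, frame_interval = NULL, geometry = device_geometry()) {
  dt <- data.table::fread(path, showProgress = FALSE)
  req <- c("TRACK_ID", "FRAME", "POSITION_T", "POSITION_X", "POSITION_Y")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols))
    cta_stop("spots table is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  # tolerate TrackMate's repeated-header/units rows: coerce and drop malformed
  for (cc in req) suppressWarnings(data.table::set(dt, j = cc, value = as.numeric(dt[[cc]])))
  bad <- !stats::complete.cases(dt[, req, with = FALSE])
  n_dropped <- sum(bad)
  dt <- dt[!bad]
  dup <- duplicated(dt[, c("TRACK_ID", "FRAME"), with = FALSE])
  if (any(dup)) {
    d1 <- dt[which(dup)[1]]
    cta_stop("duplicated (track, frame) pair: TRACK_ID=", d1$TRACK_ID,
             ", FRAME=", d1$FRAME)
  }
  data.table::setorderv(dt, c("TRACK_ID", "FRAME"))
  if (is.null(frame_interval)) {
    dts <- dt[, diff(POSITION_T), by = TRACK_ID]$V1
    frame_interval <- stats::median(dts)
  }
  tracks <- lapply(split(dt, by = "TRACK_ID"), function(g) {
    att <- list()
    if ("ECCENTRICITY" %in% names(g)) att$eccentricity <- as.numeric(g$ECCENTRICITY)
    if ("MEAN_INTENSITY" %in% names(g)) att$intensity <- as.numeric(g$MEAN_INTENSITY)
    track(g$TRACK_ID[1], g$FRAME, g$POSITION_T, g$POSITION_X, g$POSITION_Y, att)
  })
  trackset(unname(tracks), frame_interval, geometry,
           provenance = list(source = path, rows_dropped = n_dropped,
                             filter_log = character(0)))
}

#' Write a track set (or cohort) as a spots-table CSV
#'
#' @param x a `cta_trackset` or `cta_cohort`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_tracks <- function(x, path) {
  if (inherits(x, "cta_cohort")) x <- x$tracks
  stopifnot(inherits(x, "cta_trackset"))
  rows <- lapply(x$tracks, function(tr) {
    cols <- list(TRACK_ID = tr$track_id, FRAME = tr$frames,
                 POSITION_T = tr$times, POSITION_X = tr$x,
                 POSITION_Y = tr$y)
    if (!is.null(tr$attachments$intensity))
      cols$MEAN_INTENSITY <- tr$attachments$intensity
    if (!is.null(tr$attachments$eccentricity))
      cols$ECCENTRICITY <- tr$attachments$eccentricity
    data.table::as.data.table(cols)
  })
  data.table::fwrite(data.table::rbindlist(rows, fill = TRUE), path)
  invisible(path)
}

#' Exclude tracks by net final x displacement
#'
#' Retains tracks whose net final displacement along the migration axis
#' (last x minus first x) is at least `min_final_x`; tracks with *less* than
#' the threshold are excluded (the boundary is retained). Idempotent; excluded
#' ids are appended to the provenance filter log.
#'
#' @param ts a `cta_trackset`
#' @param min_final_x threshold, um
#' @return filtered `cta_trackset`
#' @export
filter_tracks <- function(ts, min_final_x = 100) {
  stopifnot(inherits(ts, "cta_trackset"))
  disp <- vapply(ts$tracks, function(tr) tr$x[length(tr$x)] - tr$x[1], 0)
  keep <- disp >= min_final_x
  dropped <- names(ts$tracks)[!keep]
  ts$tracks <- ts$tracks[keep]
  ts$provenance$filter_log <- c(ts$provenance$filter_log %||% character(0),
    sprintf("filter_tracks(min_final_x=%g): excluded %d of %d [%s]",
            min_final_x, length(dropped), length(keep),
            paste(dropped, collapse = ",")))
  ts
}

#' Mean migration speed of a track (path length / elapsed time)
#'
#' @param tr a `cta_track`
#' @return speed in um/min
#' @export
track_speed <- function(tr) {
  elapsed <- tr$times[length(tr$times)] - tr$times[1]
  if (elapsed <= 0) cta_stop("zero elapsed time in track ", tr$track_id)
  path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  path / elapsed * 60
}

#' Directionality (confinement ratio) of a track
#'
#' Net Euclidean displacement divided by accumulated path length, in \[0, 1\];
#' 1 for perfectly straight monotone motion. A stationary track (zero path
#' length) is defined as 0 with a warning.
#'
#' @param tr a `cta_track`
#' @export
track_directionality <- function(tr) {
  path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  if (path <= 0) {
    warning("zero path length in track ", tr$track_id, "; directionality set to 0")
    return(0)
  }
  net <- sqrt((tr$x[length(tr$x)] - tr$x[1])^2 + (tr$y[length(tr$y)] - tr$y[1])^2)
  net / path
}

#' x-axis forward migration index of a track
#'
#' Net x displacement / path length; signed (negative for net retrograde
#' motion). Provided as the standard chemotaxis-tool companion to the
#' confinement ratio.
#' @param tr a `cta_track`
#' @export
track_fmi <- function(tr) {
  path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  if (path <= 0) return(0)
  (tr$x[length(tr$x)] - tr$x[1]) / path
}

#' Split a track at the constriction
#'
#' First-entry/first-exit rule on the centroid: `pre` is all points before the
#' first point with x >= constriction_x, `during` the points from first entry
#' up to (excluding) the first point past the pillar exit, `post` everything
#' from first exit on. Cells that never reach the constriction have empty
#' during/post.
#'
#' @param tr a `cta_track`
#' @param geometry a [device_geometry()]
#' @return list of index vectors `pre`, `during`, `post` plus `entered`,
#'   `crossed` flags
#' @export
split_at_constriction <- function(tr, geometry = device_geometry()) {
  cx <- geometry$constriction_x
  ex <- constriction_exit(geometry)
  n <- length(tr$x)
  entry <- which(tr$x >= cx)[1]
  if (is.na(entry))
    return(list(pre = seq_len(n), during = integer(0), post = integer(0),
                entered = FALSE, crossed = FALSE))
  after <- which(tr$x > ex)
  exit <- after[after >= entry][1]
  if (is.na(exit))
    return(list(pre = seq_len(entry - 1L), during = entry:n, post = integer(0),
                entered = TRUE, crossed = FALSE))
  list(pre = seq_len(entry - 1L),
       during = if (exit > entry) entry:(exit - 1L) else integer(0),
       post = exit:n, entered = TRUE, crossed = TRUE)
}

.seg_speed <- function(tr, idx) {
  if (length(idx) < 2L) return(NA_real_)
  elapsed <- tr$times[idx[length(idx)]] - tr$times[idx[1]]
  sum(sqrt(diff(tr$x[idx])^2 + diff(tr$y[idx])^2)) / elapsed * 60
}

.seg_directionality <- function(tr, idx) {
  if (length(idx) < 2L) return(NA_real_)
  .seg_dir(tr$x[idx], tr$y[idx])
}

#' Pre/post-constriction kinematic summary of a cohort
#'
#' Computes, per cell, pre- and post-constriction speed (um/min) and
#' directionality, the post-constriction Euclidean distance (straight line
#' from the pillar-exit point to the final point), and the crossing frame;
#' and, per population, the crossing fraction (cells with a post segment /
#' cells that entered), medians, post/pre ratios of medians, and seeded
#' bootstrap percentile confidence intervals of the ratios.
#'
#' Post-constriction speed/directionality are computed on the post segment
#' truncated at the first point beyond `saturation_x` when `trim_arrest` is
#' TRUE (default): arrest in the saturating chemoattractant region is not
#' chemotaxis. The post-constriction Euclidean distance always uses the full
#' post segment.
#'
#' @param ts a (filtered) `cta_trackset`
#' @param n_boot bootstrap resamples for the ratio CIs
#' @param seed bootstrap seed
#' @param min_points minimum segment points for a per-cell statistic
#' @param trim_arrest truncate the post segment at `saturation_x`
#' @param conf confidence level
#' @return object of class `cta_peri`: list with `per_cell` (data.frame) and
#'   `population` (named list)
#' @export
peri_summary <- function(ts, n_boot = 2000, seed = 1, min_points = 3,
                         trim_arrest = TRUE, conf = 0.95) {
  stopifnot(inherits(ts, "cta_trackset"))
  geom <- ts$geometry
  sat <- geom$saturation_x
  rows <- lapply(ts$tracks, function(tr) {
    sp <- split_at_constriction(tr, geom)
    post_idx <- sp$post
    post_eu <- NA_real_; crossing_frame <- NA_integer_
    if (sp$crossed) {
      i0 <- post_idx[1]; iN <- length(tr$x)
      post_eu <- sqrt((tr$x[iN] - tr$x[i0])^2 + (tr$y[iN] - tr$y[i0])^2)
      crossing_frame <- tr$frames[i0]
      if (trim_arrest) {
        ov <- which(tr$x[post_idx] > sat)
        if (length(ov)) post_idx <- post_idx[seq_len(ov[1] - 1L)]
      }
    }
    use_pre <- length(sp$pre) >= min_points
    use_post <- length(post_idx) >= min_points
    data.frame(
      track_id = as.character(tr$track_id),
      entered = sp$entered, crossed = sp$crossed,
      pre_speed = if (use_pre) .seg_speed(tr, sp$pre) else NA_real_,
      pre_dir = if (use_pre) .seg_directionality(tr, sp$pre) else NA_real_,
      post_speed = if (use_post) .seg_speed(tr, post_idx) else NA_real_,
      post_dir = if (use_post) .seg_directionality(tr, post_idx) else NA_real_,
      post_euclidean = post_eu, crossing_frame = crossing_frame,
      stringsAsFactors = FALSE)
  })
  pc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_entered <- sum(pc$entered)
  # nobody crossing (or even entering) reports 0, not a missing value
  crossing_fraction <- if (n_entered > 0) sum(pc$crossed) / n_entered else 0

  med <- function(v) if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  ratio_of <- function(d, pre_col, post_col) {
    a <- med(d[[post_col]]); b <- med(d[[pre_col]])
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  }
  speed_ratio <- ratio_of(pc, "pre_speed", "post_speed")
  dir_ratio <- ratio_of(pc, "pre_dir", "post_dir")

  boot_ci <- function(pre_col, post_col) {
    if (is.na(ratio_of(pc, pre_col, post_col)) || nrow(pc) < 3) return(c(NA_real_, NA_real_))
    pre_v <- pc[[pre_col]]; post_v <- pc[[post_col]]
    set.seed(seed)
    n <- nrow(pc)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      a <- med(post_v[i]); d <- med(pre_v[i])
      if (is.na(a) || is.na(d) || d == 0) NA_real_ else a / d
    }, 0)
    stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE)
  }
  pop <- list(
    n_tracks = nrow(pc), n_entered = n_entered, n_crossed = sum(pc$crossed),
    crossing_fraction = crossing_fraction,
    median_pre_speed = med(pc$pre_speed), median_post_speed = med(pc$post_speed),
    median_pre_dir = med(pc$pre_dir), median_post_dir = med(pc$post_dir),
    median_post_euclidean = med(pc$post_euclidean),
    speed_ratio = speed_ratio, dir_ratio = dir_ratio,
    speed_ratio_ci = boot_ci("pre_speed", "post_speed"),
    dir_ratio_ci = boot_ci("pre_dir", "post_dir"))
  structure(list(per_cell = pc, population = pop,
                 params = list(n_boot = n_boot, seed = seed,
                               min_points = min_points,
                               trim_arrest = trim_arrest, conf = conf)),
            class = "cta_peri")
}

#' @export
print.cta_peri <- function(x, ...) {
  p <- x$population
  cat(sprintf("peri-constriction summary: %d tracks, %d entered, %d crossed (fraction %.3f)\n",
              p$n_tracks, p$n_entered, p$n_crossed, p$crossing_fraction))
  cat(sprintf("  median speed pre %.2f -> post %.2f um/min (ratio %.3f)\n",
              p$median_pre_speed, p$median_post_speed, p$speed_ratio))
  cat(sprintf("  median directionality pre %.3f -> post %.3f (ratio %.3f)\n",
              p$median_pre_dir, p$median_post_dir, p$dir_ratio))
  invisible(x)
}

#' Mean cell eccentricity by constriction region
#'
#' Pools the per-frame eccentricity attachment by region (before/during/after
#' the constriction, from the track split); each cell contributes its segment
#' mean, and cells without a segment are excluded from that region.
#'
#' @param ts a `cta_trackset` whose tracks carry an `eccentricity` attachment
#' @return named numeric vector (before, during, after)
#' @export
eccentricity_timecourse <- function(ts) {
  stopifnot(inherits(ts, "cta_trackset"))
  geom <- ts$geometry
  acc <- list(before = numeric(0), during = numeric(0), after = numeric(0))
  for (tr in ts$tracks) {
    ecc <- tr$attachments$eccentricity
    if (is.null(ecc)) cta_stop("track ", tr$track_id, " has no eccentricity attachment")
    sp <- split_at_constriction(tr, geom)
    if (length(sp$pre)) acc$before <- c(acc$before, mean(ecc[sp$pre]))
    if (length(sp$during)) acc$during <- c(acc$during, mean(ecc[sp$during]))
    if (length(sp$post)) acc$after <- c(acc$after, mean(ecc[sp$post]))
  }
  vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, 0)
}
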