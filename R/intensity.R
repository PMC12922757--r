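# Peri-constriction calcium analysis and single-cell intensity metrics.

#' Construct a calcium trace
#'
#' @param track_id cell id
#' @param times sample times, s
#' @param intensity fluorescence, a.u. (>= 0)
#' @param x position along the migration axis per sample, um
#' @return object of class `cta_trace`
#' @export
calcium_trace <- function(track_id, times, intensity, x) {
  n <- length(times)
  if (length(intensity) != n || length(x) != n)
    cta_stop("times, intensity, x must have equal length")
  if (any(intensity < 0)) cta_stop("intensity must be >= 0")
  structure(list(track_id = track_id, times = as.numeric(times),
                 intensity = as.numeric(intensity), x = as.numeric(x)),
            class = "cta_trace")
}

#' Post/pre-constriction calcium fold change
#'
#' Mean intensity over the post window (one cell length just past the pillar
#' exit, `(exit, exit + cell_length]`) divided by mean intensity over the pre
#' window (one cell length just before the pillar, `[constriction_x -
#' cell_length, constriction_x)`). If either window is uncovered by the trace
#' the cell is not evaluable and `NA_real_` is returned (excluded from
#' population statistics).
#'
#' @param trace a `cta_trace`
#' @param geometry a [device_geometry()]
#' @param stat "mean" (default) or "peak" window statistic
#' @return fold change, or `NA_real_`
#' @export
calcium_fold_change <- function(trace, geometry = device_geometry(),
                                stat = c("mean", "peak")) {
  stat <- match.arg(stat)
  cx <- geometry$constriction_x
  ex <- constriction_exit(geometry)
  w <- geometry$cell_length
  pre <- trace$intensity[trace$x >= cx - w & trace$x < cx]
  post <- trace$intensity[trace$x > ex & trace$x <= ex + w]
  if (!length(pre) || !length(post)) return(NA_real_)
  f <- if (stat == "mean") mean else max
  if (f(pre) == 0) return(NA_real_)
  f(post) / f(pre)
}

#' Detect calcium spikes in a trace
#'
#' A spike is a local maximum whose intensity exceeds a rolling-median
#' baseline by more than `k_mad` times the MAD of the detrended trace.
#' Detected spikes closer than `min_separation` are merged (largest kept).
#' Each spike is flagged post-constriction when the cell is past the pillar
#' exit at spike time.
#'
#' @param trace a `cta_trace` with >= 10 samples
#' @param k_mad threshold multiplier on the MAD
#' @param min_separation minimum spike separation, s
#' @param baseline_window rolling-median window, samples (odd)
#' @param geometry a [device_geometry()]
#' @return data.frame with columns time, x, intensity, post (possibly 0 rows)
#' @export
detect_spikes <- function(trace, k_mad = 5, min_separation = 60,
                          baseline_window = 15,
                          geometry = device_geometry()) {
  v <- trace$intensity
  n <- length(v)
  if (n < 10) cta_stop("need at least 10 samples to detect spikes")
  bw <- min(baseline_window, if (n %% 2 == 1) n else n - 1)
  if (bw %% 2 == 0) bw <- bw - 1
  baseline <- stats::runmed(v, bw)
  resid <- v - baseline
  s <- stats::mad(resid)
  thr <- k_mad * s
  is_peak <- c(FALSE, diff(v) > 0) & c(diff(v) < 0, FALSE) |
    (seq_len(n) == which.max(v) & n > 2)
  cand <- which(is_peak & resid > thr)
  if (!length(cand))
    return(data.frame(time = numeric(0), x = numeric(0),
                      intensity = numeric(0), post = logical(0)))
  # greedy non-maximum suppression within min_separation
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(trace$times[i] - trace$times[kept]) >= min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  ex <- constriction_exit(geometry)
  data.frame(time = trace$times[kept], x = trace$x[kept],
             intensity = v[kept], post = trace$x[kept] > ex)
}

#' Cortex-to-cytosol intensity ratio of one cell
#'
#' The cortex is the band of `band_width` px at the cell boundary (mask minus
#' its `band_width`-fold erosion); the cytosol is the eroded interior, minus
#' the nucleus when a nucleus mask is supplied. The ratio of mean intensities
#' is the polarity readout for cortical markers such as pMLC II.
#'
#' @param channel intensity matrix
#' @param cell_mask logical/0-1 matrix of one cell
#' @param band_width cortical band width, px (>= 1)
#' @param nucleus_mask optional nucleus mask to exclude from the cytosol
#' @return list with cortex_mean, cytosol_mean, ratio, and (when a nucleus
#'   mask is given) cytosol_mean_incl_nucleus / ratio_incl_nucleus; plus
#'   band_width
#' @export
cortex_cytosol_ratio <- function(channel, cell_mask, band_width = 3,
                                 nucleus_mask = NULL) {
  if (band_width < 1) cta_stop("band_width must be >= 1 px")
  m <- cell_mask > 0
  if (!any(m)) cta_stop("empty cell mask")
  interior <- bin_erode(m, band_width)
  if (!any(interior))
    cta_stop("interior empty after eroding ", band_width,
             " px; use a smaller band_width")
  cortex <- m & !interior
  cyt <- interior
  out <- list(cortex_mean = mean(channel[cortex]), band_width = band_width)
  if (!is.null(nucleus_mask)) {
    cyt_ex <- interior & !(nucleus_mask > 0)
    if (!any(cyt_ex)) cta_stop("cytosol empty after excluding the nucleus")
    out$cytosol_mean <- mean(channel[cyt_ex])
    out$cytosol_mean_incl_nucleus <- mean(channel[cyt])
    out$ratio <- out$cortex_mean / out$cytosol_mean
    out$ratio_incl_nucleus <- out$cortex_mean / out$cytosol_mean_incl_nucleus
  } else {
    out$cytosol_mean <- mean(channel[cyt])
    out$ratio <- out$cortex_mean / out$cytosol_mean
  }
  out
}

#' Nuclear-envelope enrichment fractions
#'
#' Splits a cell's integrated intensity into nuclear compartments. The NE is
#' the band of `ne_band` px on each side of the nuclear boundary (dilation
#' minus erosion of the nucleus mask, clipped to the cell); the nucleoplasm
#' is the eroded nuclear interior; the total nuclear compartment is their
#' union, so fraction_total_nuclear = fraction_nucleoplasm + fraction_NE
#' exactly. Fractions are of the whole-cell integrated intensity.
#'
#' @param channel intensity matrix
#' @param cell_mask,nucleus_mask logical/0-1 matrices; nucleus must be nested
#'   in the cell
#' @param ne_band half-width of the NE band, px
#' @return named numeric vector (fraction_total_nuclear, fraction_nucleoplasm,
#'   fraction_NE)
#' @export
ne_fraction <- function(channel, cell_mask, nucleus_mask, ne_band = 2) {
  cm <- cell_mask > 0; nm <- nucleus_mask > 0
  if (any(nm & !cm)) cta_stop("nucleus mask is not nested within the cell mask")
  ne <- bin_dilate(nm, ne_band) & !bin_erode(nm, ne_band) & cm
  nucleoplasm <- bin_erode(nm, ne_band)
  total <- sum(channel[cm])
  if (total <= 0) cta_stop("cell has zero integrated intensity")
  f_ne <- sum(channel[ne]) / total
  f_np <- sum(channel[nucleoplasm]) / total
  c(fraction_total_nuclear = f_np + f_ne,
    fraction_nucleoplasm = f_np, fraction_NE = f_ne)
}

#' Kapur maximum-entropy threshold
#'
#' Splits a histogram at the level maximizing the sum of the Shannon
#' entropies of the sub-histograms below and above the split.
#'
#' @param x numeric vector (or matrix) of intensities
#' @param n_bins histogram bins
#' @return threshold value (upper edge of the below-class)
#' @export
max_entropy_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  P <- cumsum(p)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  best <- -Inf; best_t <- 1L
  for (t in seq_len(n_bins - 1)) {
    w0 <- P[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    H <- ent(p[1:t] / w0) + ent(p[(t + 1):n_bins] / w1)
    if (H > best) { best <- H; best_t <- t }
  }
  br[best_t + 1]
}

#' Mander's colocalization coefficients
#'
#' M1 is the fraction of channel-1 intensity (within the mask) occurring at
#' pixels where channel 2 exceeds its threshold; M2 symmetrically. Thresholds
#' default to the maximum-entropy split of each channel within the mask.
#'
#' @param ch1,ch2 intensity matrices of equal shape
#' @param mask optional logical ROI (default: everything)
#' @param t1,t2 channel thresholds; NULL = maximum entropy
#' @return list with M1, M2, t1, t2 (M's are `NA_real_` when a channel's
#'   integrated intensity in the mask is zero)
#' @export
manders <- function(ch1, ch2, mask = NULL, t1 = NULL, t2 = NULL) {
  if (!all(dim(ch1) == dim(ch2))) cta_stop("channels must have equal shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  mask <- mask > 0
  v1 <- ch1[mask]; v2 <- ch2[mask]
  if (is.null(t1)) t1 <- max_entropy_threshold(v1)
  if (is.null(t2)) t2 <- max_entropy_threshold(v2)
  s1 <- sum(v1); s2 <- sum(v2)
  M1 <- if (s1 > 0) sum(v1[v2 > t2]) / s1 else NA_real_
  M2 <- if (s2 > 0) sum(v2[v1 > t1]) / s2 else NA_real_
  list(M1 = M1, M2 = M2, t1 = t1, t2 = t2)
}
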