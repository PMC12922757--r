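#' Constricted chemotaxis chamber geometry
#'
#' Describes the migration chamber of a single-constriction microfluidic
#' chemotaxis device: a shallow channel (default 5 um high, 300 um long)
#' with a pillar-defined constriction whose leading edge sits
#' `constriction_x` um from the cell inlet and which extends
#' `pillar_extent` um along the migration (x) axis. The chemoattractant
#' reservoir is at x = `chamber_length`; the concentration becomes
#' near-saturating around `saturation_x`. `cell_length` is the window size
#' used for peri-constriction quantification (one cell length).
#'
#' @param chamber_length chamber length along the migration axis, um
#' @param chamber_height channel height, um (informational)
#' @param chamber_width lateral extent used for reflective side walls, um
#' @param constriction_x pillar leading edge from the cell inlet, um
#' @param pillar_extent pillar depth along the migration axis, um
#' @param gap_width constriction gap, um (3 = nuclear squeezing, 5 = free passage)
#' @param cell_length peri-constriction analysis window, um
#' @param saturation_x onset of near-saturating chemoattractant, um
#' @return object of class `cta_geometry`
#' @examples
#' g <- device_geometry(gap_width = 3)
#' constriction_exit(g)
#' @export
device_geometry <- function(chamber_length = 300, chamber_height = 5,
                            chamber_width = 300, constriction_x = 100,
                            pillar_extent = 20, gap_width = 5,
                            cell_length = 25, saturation_x = 250) {
  g <- list(chamber_length = chamber_length, chamber_height = chamber_height,
            chamber_width = chamber_width, constriction_x = constriction_x,
            pillar_extent = pillar_extent, gap_width = gap_width,
            cell_length = cell_length, saturation_x = saturation_x)
  if (!(constriction_x > 0 && constriction_x + pillar_extent < chamber_length))
    cta_stop("invalid geometry: need 0 < constriction_x < constriction_x + pillar_extent < chamber_length")
  if (gap_width <= 0) cta_stop("gap_width must be > 0")
  if (cell_length <= 0) cta_stop("cell_length must be > 0")
  if (chamber_height <= 0 || chamber_width <= 0) cta_stop("chamber dimensions must be > 0")
  if (saturation_x <= constriction_x + pillar_extent || saturation_x > chamber_length)
    cta_stop("saturation_x must lie between the pillar exit and the chamber end")
  structure(g, class = "cta_geometry")
}

#' Pillar exit position (um from the cell inlet)
#' @param geometry a [device_geometry()] object
#' @export
constriction_exit <- function(geometry) {
  geometry$constriction_x + geometry$pillar_extent
}

#' @export
print.cta_geometry <- function(x, ...) {
  cat(sprintf(
    "chemotaxis chamber: %g um long x %g um wide x %g um high\n",
    x$chamber_length, x$chamber_width, x$chamber_height))
  cat(sprintf("constriction: %g-um gap, pillar x = [%g, %g] um; saturation at %g um\n",
              x$gap_width, x$constriction_x, constriction_exit(x), x$saturation_x))
  invisible(x)
}

#' Classify a position along the migration axis relative to the constriction
#'
#' A position is `before` the constriction when x < constriction_x, `during`
#' when it lies within the pillar extent (inclusive on both edges), and
#' `after` beyond the pillar exit.
#'
#' @param x positions along the migration axis, um (vectorized)
#' @param geometry a [device_geometry()] object
#' @return factor with levels before/during/after
#' @examples
#' classify_position(c(50, 110, 150), device_geometry())
#' @export
classify_position <- function(x, geometry = device_geometry()) {
  if (any(x < 0 | x > geometry$chamber_length))
    cta_stop("position outside the chamber [0, ", geometry$chamber_length, "] um")
  exit_x <- constriction_exit(geometry)
  out <- ifelse(x < geometry$constriction_x, "before",
                ifelse(x <= exit_x, "during", "after"))
  factor(out, levels = c("before", "during", "after"))
}
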