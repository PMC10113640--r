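#' Build a cortical layer map
#'
#' A layer map is an ordered set of contiguous, non-overlapping, half-open
#' depth intervals `[lo, hi)` in micrometres from the pia, each carrying a
#' unique layer label. Depths are always assigned with the half-open
#' convention, so a depth exactly on an internal boundary belongs to the
#' deeper layer.
#'
#' @param labels Character vector of unique layer labels, ordered from the
#'   pia downwards.
#' @param boundaries Numeric vector of interval edges in um, of length
#'   `length(labels) + 1`, strictly increasing, starting at 0.
#' @return A tibble of class `layer_map` with columns `layer`, `depth_lo_um`,
#'   `depth_hi_um`.
#' @examples
#' layer_map(c("L1", "L2/3"), c(0, 150, 600))
#' @export
layer_map <- function(labels, boundaries) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  if (length(boundaries) != length(labels) + 1L) {
    stop("`boundaries` must have one more element than `labels`")
  }
  if (anyDuplicated(labels)) stop("layer labels must be unique")
  if (boundaries[1] != 0) stop("the first interval must start at depth 0")
  if (any(diff(boundaries) <= 0)) stop("`boundaries` must be strictly increasing")
  out <- tibble::tibble(
    layer = labels,
    depth_lo_um = boundaries[-length(boundaries)],
    depth_hi_um = boundaries[-1]
  )
  class(out) <- c("layer_map", class(out))
  out
}

#' Default rat S1 layer boundaries
#'
#' Laminar boundaries for the adult rat primary somatosensory cortex used
#' throughout the package: L1 `[0, 150)`, L2/3 `[150, 600)`, L4 `[600, 950)`,
#' L5 `[950, 1350)`, L6 `[1350, 1600)` um. These are configurable defaults,
#' not measurements; any `layer_map()` can be substituted.
#'
#' @return A `layer_map` tibble.
#' @export
default_layer_map <- function() {
  layer_map(c("L1", "L2/3", "L4", "L5", "L6"), c(0, 150, 600, 950, 1350, 1600))
}

#' Assign cortical depths to layers
#'
#' @param depth_um Numeric vector of depths in um from the pia.
#' @param map A `layer_map`, e.g. [default_layer_map()].
#' @return Character vector of layer labels, same length as `depth_um`.
#'   Depths on an internal boundary go to the deeper layer (half-open
#'   intervals); depths outside the map span are an error.
#' @examples
#' assign_layer(c(0, 150, 1050), default_layer_map())
#' @export
assign_layer <- function(depth_um, map = default_layer_map()) {
  stopifnot(inherits(map, "layer_map"), is.numeric(depth_um))
  lo <- map$depth_lo_um[1]
  hi <- map$depth_hi_um[nrow(map)]
  bad <- depth_um < lo | depth_um >= hi
  if (any(bad)) {
    stop(sprintf("depth %g um outside the layer map span [%g, %g)",
                 depth_um[which(bad)[1]], lo, hi))
  }
  idx <- findInterval(depth_um, c(map$depth_lo_um, hi),
                      rightmost.closed = FALSE, left.open = FALSE)
  map$layer[idx]
}
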