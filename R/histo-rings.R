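#' Concentric-ring profile around the device hole
#'
#' Assigns every nucleus to a concentric ring by the distance from its
#' centroid to the hole boundary (half-open bins of `ring_width_um`; a
#' nucleus exactly on a ring edge belongs to the outer ring), and summarises
#' counts and circularity per ring. Nuclei beyond `max_radius_um` are
#' dropped; a nucleus centroid inside the hole is an error.
#'
#' @param nuclei Tibble from [segment_nuclei()] with `dist_to_hole_um` and
#'   `circularity` columns (distance may also be supplied by `hole`).
#' @param hole Optional hole geometry `list(center_um, half_axes_um)`; when
#'   given, distances are (re)computed from it.
#' @param ring_width_um Ring width, um (default 25).
#' @param max_radius_um Outermost ring edge, um.
#' @return Tibble with one row per ring: `ring`, `ring_lo_um`, `ring_hi_um`,
#'   `n`, `mean_circularity`, `sd_circularity`, `ci95_um` (half-width of the
#'   normal 95% CI of the mean).
#' @export
ring_profile <- function(nuclei, hole = NULL, ring_width_um = 25,
                         max_radius_um = 500) {
  stopifnot(ring_width_um > 0, max_radius_um > 0)
  d <- if (!is.null(hole)) {
    dist_to_ellipse(nuclei$x_um, nuclei$y_um, hole$center_um[1],
                    hole$center_um[2], hole$half_axes_um[1],
                    hole$half_axes_um[2])
  } else {
    nuclei$dist_to_hole_um
  }
  if (anyNA(d)) stop("nucleus distances to the hole are unknown")
  if (any(d < 0)) stop("nucleus centroid inside the device hole")
  keep <- d < max_radius_um
  ring <- floor(d[keep] / ring_width_um)
  circ <- nuclei$circularity[keep]
  n_rings <- ceiling(max_radius_um / ring_width_um)
  purrr::map_dfr(seq_len(n_rings) - 1L, function(r) {
    in_ring <- ring == r
    cc <- circ[in_ring]
    tibble::tibble(
      ring = r + 1L, ring_lo_um = r * ring_width_um,
      ring_hi_um = (r + 1L) * ring_width_um, n = sum(in_ring),
      mean_circularity = if (length(cc)) mean(cc) else NA_real_,
      sd_circularity = if (length(cc) > 1) sd(cc) else NA_real_,
      ci95 = if (length(cc) > 1) 1.96 * sd(cc) / sqrt(length(cc)) else NA_real_
    )
  })
}

#' Circularity-vs-distance slope
#'
#' Least-squares slope of nucleus circularity against distance from the
#' hole boundary, in circularity units per mm.
#'
#' @param nuclei Tibble with `dist_to_hole_um` and `circularity`.
#' @return Slope (units/mm).
#' @export
circularity_distance_slope <- function(nuclei) {
  stopifnot(nrow(nuclei) >= 3)
  unname(coef(lm(circularity ~ I(dist_to_hole_um / 1000), data = nuclei))[2])
}
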