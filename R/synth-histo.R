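#' Specification of a laminar histology phantom
#'
#' Describes a synthetic NeuN-like fluorescence stack around an explanted
#' electrode track: an elliptical device hole (tapering with depth), a
#' nuclei-free kill zone whose radius peaks mid-cortex, a depth-dependent
#' nuclei density with peaks in L4 and L6, and nucleus elongation that
#' increases toward the hole. All depth-dependent quantities are functions
#' of depth in um.
#'
#' Nuclei are placed by a hard-core (minimum-separation) Poisson process:
#' counts are Poisson at the local density, but accepted centroids keep a
#' minimum distance of `2 * nucleus_radius_um + 2 * pixel_size_um`, since
#' nuclei are solid bodies.
#'
#' @param image_shape Integer `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size, um/px.
#' @param density_profile Function depth -> nuclei per mm^2.
#' @param hole_half_axes Function depth -> `c(a_um, b_um)` ellipse half-axes.
#' @param killzone_radius Function depth -> kill-zone radius, um from the
#'   hole centre; must be at least the larger hole half-axis at every depth.
#' @param elongation_gradient Circularity change per mm of distance from the
#'   hole (positive: rounder away from the hole). 0 renders every nucleus as
#'   a perfect circle.
#' @param circ_ref_dist_um Distance at which true circularity reaches 1.
#' @param nucleus_radius_um Equivalent-area nucleus radius, um.
#' @param nucleus_intensity,background_intensity Mean intensities (0-1).
#' @param noise_sd Additive Gaussian pixel noise s.d.
#' @return List of class `histo_phantom`.
#' @export
histo_phantom <- function(image_shape = c(800, 800), pixel_size_um = 1,
                          density_profile = default_density_profile,
                          hole_half_axes = default_hole_half_axes,
                          killzone_radius = default_killzone_radius,
                          elongation_gradient = 0.079,
                          circ_ref_dist_um = 600,
                          nucleus_radius_um = 7,
                          nucleus_intensity = 0.8,
                          background_intensity = 0.12, noise_sd = 0.04) {
  stopifnot(pixel_size_um > 0, nucleus_radius_um > 0)
  structure(
    list(image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
         density_profile = density_profile, hole_half_axes = hole_half_axes,
         killzone_radius = killzone_radius,
         elongation_gradient = elongation_gradient,
         circ_ref_dist_um = circ_ref_dist_um,
         nucleus_radius_um = nucleus_radius_um,
         nucleus_intensity = nucleus_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd),
    class = "histo_phantom"
  )
}

#' Default depth profiles for the histology phantom
#'
#' `default_density_profile()`: bimodal nuclei density with peaks centred in
#' the L4 and L6 intervals of the default layer map, per mm^2.
#' `default_hole_half_axes()`: elliptical hole tapering monotonically with
#' depth (the device narrows toward its tip). `default_killzone_radius()`:
#' kill-zone radius peaking at 600 um depth.
#'
#' @param depth_um Depth from the pia, um.
#' @return Density (per mm^2), half-axes (um), or radius (um).
#' @export
default_density_profile <- function(depth_um) {
  600 + 800 * exp(-((depth_um - 775) / 120)^2) +
    600 * exp(-((depth_um - 1475) / 100)^2)
}

#' @rdname default_density_profile
#' @export
default_hole_half_axes <- function(depth_um) {
  f <- pmin(pmax(depth_um, 0), 1600) / 1600
  c(40 - 32 * f, 15 - 11 * f)
}

#' @rdname default_density_profile
#' @export
default_killzone_radius <- function(depth_um) {
  60 + 140 * exp(-((depth_um - 600) / 250)^2)
}

# Axis ratio q >= 1 such that an area-preserving ellipse (a = r*sqrt(q),
# b = r/sqrt(q)) has the requested circularity (Ramanujan perimeter).
axis_ratio_for_circularity <- function(circ) {
  circ <- pmin(pmax(circ, 0.3), 1)
  vapply(circ, function(cc) {
    if (cc >= 1 - 1e-12) return(1)
    uniroot(function(q) ellipse_circularity(sqrt(q), 1 / sqrt(q)) - cc,
            c(1, 60), tol = 1e-10)$root
  }, numeric(1))
}

# Analytic circularity of an ellipse with semi-axes a, b
# (Ramanujan's second perimeter approximation).
ellipse_circularity <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  p <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * a * b) / p^2
}

# Minimum distance from points to an ellipse boundary centred at (cx, cy)
# with half-axes (a, b), via a dense boundary polygon. Negative inside.
dist_to_ellipse <- function(x, y, cx, cy, a, b, n_vertices = 240) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-1]
  bx <- cx + a * cos(th)
  by <- cy + b * sin(th)
  d <- sqrt(outer(x, bx, `-`)^2 + outer(y, by, `-`)^2)
  dmin <- apply(d, 1, min)
  inside <- ((x - cx) / a)^2 + ((y - cy) / b)^2 < 1
  ifelse(inside, -dmin, dmin)
}

#' Render one synthetic histology slice
#'
#' Produces a grayscale image at a given cortical depth: an elliptical
#' zero-intensity device hole at the image centre, no nuclei within the
#' kill-zone radius of the hole centre, and nuclei outside placed by a
#' hard-core Poisson process at the depth's density, each rendered as an
#' area-preserving ellipse whose circularity follows the elongation gradient
#' (rounder with distance from the hole). Ground truth (centroids, axes,
#' true circularity, distance to the hole boundary, true kill-zone area) is
#' returned with the image.
#'
#' @param phantom A [histo_phantom()].
#' @param depth_um Cortical depth to render, um.
#' @param seed Integer seed.
#' @param tag Optional [slice_tag()] attached to the slice.
#' @return List of class `histo_slice`: `image` (rows x cols matrix in
#'   0..1), `pixel_size_um`, `depth_um`, `tag`, `hole` (centre/half-axes in
#'   um, image coordinates), `killzone_radius_um`,
#'   `killzone_area_um2` (true nuclei-free enclosed area, pi * r^2), and
#'   `truth` (tibble: `x_um`, `y_um`, `axis_ratio`, `theta`,
#'   `dist_to_hole_um`, `circ_true`).
#' @export
render_slice <- function(phantom, depth_um, seed = 1, tag = NULL) {
  stopifnot(inherits(phantom, "histo_phantom"))
  ny <- phantom$image_shape[1]; nx <- phantom$image_shape[2]
  s <- phantom$pixel_size_um
  hole <- phantom$hole_half_axes(depth_um)
  r_kz <- phantom$killzone_radius(depth_um)
  if (r_kz < max(hole)) {
    stop("kill-zone radius smaller than the hole half-axis at this depth")
  }
  dens <- phantom$density_profile(depth_um)
  if (dens < 0) stop("negative nuclei density")
  cx <- nx * s / 2; cy <- ny * s / 2
  r_n <- phantom$nucleus_radius_um
  margin <- 3 * r_n
  d_min <- 2 * r_n + 2 * s

  withr::with_seed(seed, {
    area_mm2 <- (nx * s) * (ny * s) / 1e6
    n_try <- rpois(1, dens * area_mm2)
    xs <- runif(n_try, margin, nx * s - margin)
    ys <- runif(n_try, margin, ny * s - margin)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (i in seq_len(n_try)) {
      if (sqrt((xs[i] - cx)^2 + (ys[i] - cy)^2) < r_kz) next
      if (length(keep_x) &&
          min((keep_x - xs[i])^2 + (keep_y - ys[i])^2) < d_min^2) next
      keep_x <- c(keep_x, xs[i]); keep_y <- c(keep_y, ys[i])
    }
    n_nuc <- length(keep_x)
    theta <- runif(n_nuc, 0, pi)
    inten <- pmin(pmax(rnorm(n_nuc, phantom$nucleus_intensity, 0.03), 0.4), 1)
    noise <- matrix(rnorm(ny * nx, 0, phantom$noise_sd), ny, nx)
  })

  dist_hole <- if (n_nuc) {
    dist_to_ellipse(keep_x, keep_y, cx, cy, hole[1], hole[2])
  } else numeric(0)
  circ_true <- pmin(1, pmax(0.3, 1 + phantom$elongation_gradient *
                              (dist_hole - phantom$circ_ref_dist_um) / 1000))
  q <- axis_ratio_for_circularity(circ_true)
  a_um <- r_n * sqrt(q); b_um <- r_n / sqrt(q)

  img <- matrix(phantom$background_intensity, ny, nx)
  for (i in seq_len(n_nuc)) {
    half <- a_um[i] + s
    col_rng <- max(1, floor((keep_x[i] - half) / s)):min(nx, ceiling((keep_x[i] + half) / s))
    row_rng <- max(1, floor((keep_y[i] - half) / s)):min(ny, ceiling((keep_y[i] + half) / s))
    px <- (col_rng - 0.5) * s - keep_x[i]
    py <- (row_rng - 0.5) * s - keep_y[i]
    u <- outer(py, px, function(yy, xx) xx * cos(theta[i]) + yy * sin(theta[i]))
    v <- outer(py, px, function(yy, xx) -xx * sin(theta[i]) + yy * cos(theta[i]))
    inside <- (u / a_um[i])^2 + (v / b_um[i])^2 <= 1
    img[row_rng, col_rng][inside] <- inten[i]
  }
  img <- pmin(pmax(img + noise, 0), 1)
  # zero-intensity device hole (kept exactly zero, noise-free)
  pxx <- ((seq_len(nx) - 0.5) * s - cx) / hole[1]
  pyy <- ((seq_len(ny) - 0.5) * s - cy) / hole[2]
  hole_mask <- outer(pyy^2, pxx^2, `+`) <= 1
  img[hole_mask] <- 0

  structure(
    list(image = img, pixel_size_um = s, depth_um = depth_um, tag = tag,
         hole = list(center_um = c(cx, cy), half_axes_um = hole),
         killzone_radius_um = r_kz, killzone_area_um2 = pi * r_kz^2,
         nucleus_radius_um = r_n,
         truth = tibble::tibble(x_um = keep_x, y_um = keep_y,
                                axis_ratio = q, theta = theta,
                                dist_to_hole_um = dist_hole,
                                circ_true = circ_true)),
    class = "histo_slice"
  )
}

#' Render a depth-ordered phantom stack
#'
#' Renders serial sections at depths `0, t, 2t, ...` and tags each with its
#' slide and position under the cyclic serial-acquisition scheme, so the
#' stack metadata round-trips through [slice_depth()].
#'
#' @param phantom A [histo_phantom()].
#' @param thickness_um Section thickness, um.
#' @param slides_per_cycle,slices_per_slide Acquisition layout.
#' @param n_slices Number of slices (default one full cycle set,
#'   `slides_per_cycle * slices_per_slide`).
#' @param seed Integer seed (per-slice seeds are derived from it).
#' @return List of class `histo_stack`: `slices` (list of `histo_slice`),
#'   plus the layout parameters.
#' @export
simulate_stack <- function(phantom = histo_phantom(), thickness_um = 20,
                           slides_per_cycle = 10, slices_per_slide = 8,
                           n_slices = slides_per_cycle * slices_per_slide,
                           seed = 1) {
  stopifnot(thickness_um > 0, slides_per_cycle >= 1, slices_per_slide >= 1)
  slice_seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n_slices))
  slices <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    tag <- slice_tag(slide = (i - 1) %% slides_per_cycle + 1,
                     position = (i - 1) %/% slides_per_cycle + 1,
                     thickness_um = thickness_um,
                     slides_per_cycle = slides_per_cycle)
    slices[[i]] <- render_slice(phantom, depth_um = (i - 1) * thickness_um,
                                seed = slice_seeds[i], tag = tag)
  }
  structure(list(slices = slices, thickness_um = thickness_um,
                 slides_per_cycle = as.integer(slides_per_cycle),
                 slices_per_slide = as.integer(slices_per_slide),
                 pixel_size_um = phantom$pixel_size_um),
            class = "histo_stack")
}
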