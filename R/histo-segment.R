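#' Circularity shape descriptor
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, smaller for
#' elongated shapes; values are clipped at 1 (rasterisation can push the
#' raw ratio marginally above it).
#'
#' @param area_um2 Region area (> 0), um^2.
#' @param perimeter_um Region perimeter (> 0), um.
#' @return Circularity in `(0, 1]`.
#' @examples
#' circularity(pi * 5^2, 2 * pi * 5) # exactly 1 for an analytic circle
#' circularity(1, 4)                 # unit square: pi/4
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(area_um2 <= 0) || any(perimeter_um <= 0)) {
    stop("area and perimeter must be positive")
  }
  pmin(1, 4 * pi * area_um2 / perimeter_um^2)
}

# Sub-pixel boundary measurement of one connected component.
# The binary patch is lightly smoothed and traced with marching squares
# (grDevices::contourLines at level 0.5); pixel-edge perimeters would bias
# circularity low. The smoothing scale adapts to the region size: small
# regions need a light touch (heavier smoothing erodes high-curvature tips
# and compresses the circularity scale), large regions need more to fully
# suppress the staircase perimeter. Returns area (um^2) and perimeter (um).
measure_component <- function(patch, pixel_size_um, smooth_sigma = NULL) {
  if (is.null(smooth_sigma)) {
    r_eff <- sqrt(sum(patch > 0) / pi)
    smooth_sigma <- min(2.5, max(0.7, r_eff / 10))
  }
  pad <- max(3L, ceiling(3 * smooth_sigma))
  z <- matrix(0, nrow(patch) + 2 * pad, ncol(patch) + 2 * pad)
  z[pad + seq_len(nrow(patch)), pad + seq_len(ncol(patch))] <- patch
  if (smooth_sigma > 0) z <- gauss_smooth(z, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) return(c(area = NA_real_, perimeter = NA_real_))
  shoelace <- function(cc) {
    x <- cc$x; y <- cc$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  areas <- vapply(cl, shoelace, numeric(1))
  best <- which.max(areas)
  x <- cl[[best]]$x; y <- cl[[best]]$y
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  c(area = areas[best] * pixel_size_um^2, perimeter = per * pixel_size_um)
}

#' Measure a single binary region
#'
#' Sub-pixel area, perimeter and circularity of one connected region,
#' traced on the lightly smoothed marching-squares contour (the measurement
#' used for every segmented nucleus).
#'
#' @param mask Logical or 0/1 matrix containing one region.
#' @param pixel_size_um Pixel size, um/px.
#' @param smooth_sigma Contour smoothing sigma, px; `NULL` (default) adapts
#'   it to the region size.
#' @return Tibble with `area_um2`, `perimeter_um`, `circularity`.
#' @export
measure_region <- function(mask, pixel_size_um = 1, smooth_sigma = NULL) {
  m <- measure_component(mask + 0, pixel_size_um, smooth_sigma = smooth_sigma)
  tibble::tibble(area_um2 = unname(m["area"]),
                 perimeter_um = unname(m["perimeter"]),
                 circularity = circularity(m["area"], m["perimeter"]))
}

#' Segment neuronal nuclei in a classified image
#'
#' Thresholds the classifier's probability map at `prob_threshold`, labels
#' connected components (optionally splitting touching nuclei by watershed
#' on the distance map), removes components below `min_area_um2`, and
#' measures each region on its smoothed sub-pixel contour: centroid, area,
#' perimeter, circularity, and (when the hole geometry is known) distance
#' from the centroid to the hole boundary.
#'
#' @param image Preprocessed intensity matrix, or a `histo_slice` (its
#'   image is used and its hole geometry provides distances).
#' @param classifier A `pixel_classifier` from [train_pixel_classifier()].
#' @param pixel_size_um Pixel calibration, um/px (taken from the slice when
#'   one is supplied; required otherwise).
#' @param min_area_um2 Minimum region area, um^2.
#' @param declump Split touching nuclei with a watershed on the distance
#'   map (off by default).
#' @param prob_threshold Probability cut for the nucleus class.
#' @param hole Optional hole geometry `list(center_um, half_axes_um)`.
#' @return Tibble with one row per nucleus: `label`, `x_um`, `y_um`,
#'   `area_um2`, `perimeter_um`, `circularity`, `dist_to_hole_um`.
#' @export
segment_nuclei <- function(image, classifier, pixel_size_um = NULL,
                           min_area_um2 = 20, declump = FALSE,
                           prob_threshold = 0.5, hole = NULL) {
  if (inherits(image, "histo_slice")) {
    hole <- hole %||% image$hole
    pixel_size_um <- pixel_size_um %||% image$pixel_size_um
    image <- image$image
  }
  if (is.null(pixel_size_um)) stop("`pixel_size_um` calibration is required")
  prob <- predict_pixels(classifier, image)
  mask <- prob >= prob_threshold
  if (!any(mask)) return(empty_nuclei())
  if (declump) {
    dm <- EBImage::distmap(mask)
    labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    labels <- EBImage::imageData(EBImage::bwlabel(mask))
  }
  measure_labelled(labels, pixel_size_um, min_area_um2, hole)
}

# Shared region measurement over a label matrix.
measure_labelled <- function(labels, pixel_size_um, min_area_um2, hole) {
  n_lab <- max(labels)
  if (n_lab == 0) return(empty_nuclei())
  px_area <- pixel_size_um^2
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  out <- vector("list", n_lab)
  min_px <- ceiling(min_area_um2 / px_area)
  split_rows <- split(rows, lab)
  split_cols <- split(cols, lab)
  for (nm in names(split_rows)) {
    r <- split_rows[[nm]]; cc <- split_cols[[nm]]
    if (length(r) < min_px) next
    patch <- matrix(0, diff(range(r)) + 1L, diff(range(cc)) + 1L)
    patch[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- 1
    m <- measure_component(patch, pixel_size_um)
    if (is.na(m["area"]) || m["area"] < min_area_um2) next
    out[[nm]] <- tibble::tibble(
      label = as.integer(nm),
      x_um = (mean(cc) - 0.5) * pixel_size_um,
      y_um = (mean(r) - 0.5) * pixel_size_um,
      area_um2 = unname(m["area"]), perimeter_um = unname(m["perimeter"]),
      circularity = circularity(m["area"], m["perimeter"])
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_nuclei())
  res$dist_to_hole_um <- if (!is.null(hole)) {
    dist_to_ellipse(res$x_um, res$y_um, hole$center_um[1], hole$center_um[2],
                    hole$half_axes_um[1], hole$half_axes_um[2])
  } else NA_real_
  res
}

empty_nuclei <- function() {
  tibble::tibble(label = integer(), x_um = numeric(), y_um = numeric(),
                 area_um2 = numeric(), perimeter_um = numeric(),
                 circularity = numeric(), dist_to_hole_um = numeric())
}

#' Match segmented nuclei to ground truth and score F1
#'
#' Greedy one-to-one matching by centroid distance within `tol_um`.
#'
#' @param nuclei Segmentation tibble from [segment_nuclei()].
#' @param truth Ground-truth tibble with `x_um`, `y_um` (e.g.
#'   `slice$truth`).
#' @param tol_um Match tolerance, um.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `mean_centroid_err_um`.
#' @export
score_segmentation <- function(nuclei, truth, tol_um = 8) {
  if (nrow(truth) == 0 || nrow(nuclei) == 0) {
    tp <- 0L
    errs <- numeric(0)
  } else {
    d <- sqrt(outer(nuclei$x_um, truth$x_um, `-`)^2 +
                outer(nuclei$y_um, truth$y_um, `-`)^2)
    tp <- 0L
    errs <- numeric(0)
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > tol_um) break
      i <- (m - 1L) %% nrow(d) + 1L
      j <- (m - 1L) %/% nrow(d) + 1L
      tp <- tp + 1L
      errs <- c(errs, d[m])
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  fp <- nrow(nuclei) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, mean_centroid_err_um = mean(errs))
}
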