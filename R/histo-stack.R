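#' Run the full histology pipeline over a depth-tracked stack
#'
#' Preprocesses every slice, applies (or first trains) the nuclei pixel
#' classifier, segments nuclei, and estimates the cell-loss area per slice.
#' When no classifier is supplied the stack must carry generator ground
#' truth: roughly `train_frac` of the slices (random depths, seeded) are
#' used to train one, mirroring the annotate-a-few-sections workflow.
#'
#' @param stack A `histo_stack`.
#' @param classifier Optional `pixel_classifier`.
#' @param train_frac Fraction of slices used for training when no
#'   classifier is given.
#' @param blur_sigma,saturation Preprocessing parameters.
#' @param min_area_um2,declump Segmentation parameters.
#' @param seed Seed for training-slice selection and classifier fitting.
#' @return List of class `stack_result`: `nuclei` (tibble over all slices
#'   with `slice`, `depth_mid_um` columns added), `per_slice` (one row per
#'   slice: depth interval and midpoint, nucleus count, density, loss area,
#'   mean circularity), and the fitted `classifier`.
#' @export
process_stack <- function(stack, classifier = NULL, train_frac = 0.05,
                          blur_sigma = 1, saturation = 0.002,
                          min_area_um2 = 20, declump = FALSE, seed = 1) {
  stopifnot(inherits(stack, "histo_stack"))
  slices <- stack$slices
  pre <- lapply(slices, function(sl) {
    preprocess_slice(sl$image, blur_sigma = blur_sigma,
                     saturation = saturation)
  })
  if (is.null(classifier)) {
    if (is.null(slices[[1]]$truth)) {
      stop("no classifier given and the stack has no ground truth to train on")
    }
    pick <- select_training_slices(length(slices), frac = train_frac,
                                   seed = seed)
    classifier <- train_pixel_classifier(
      images = pre[pick], masks = lapply(slices[pick], nucleus_mask),
      seed = seed
    )
  }
  nuclei <- vector("list", length(slices))
  per_slice <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    depth <- slice_depth(sl$tag)
    nuc <- segment_nuclei(pre[[i]], classifier,
                          pixel_size_um = sl$pixel_size_um,
                          min_area_um2 = min_area_um2, declump = declump,
                          hole = sl$hole)
    loss <- tryCatch(cell_loss_area(sl, nuc, method = "auto"),
                     error = function(e) tibble::tibble(loss_area_um2 = NA_real_))
    img_area_mm2 <- prod(dim(sl$image)) * sl$pixel_size_um^2 / 1e6
    acc_mm2 <- img_area_mm2 - dplyr::coalesce(loss$loss_area_um2[1], 0) / 1e6
    nuclei[[i]] <- dplyr::mutate(nuc, slice = i,
                                 depth_mid_um = mean(depth), .before = 1)
    per_slice[[i]] <- tibble::tibble(
      slice = i, depth_lo_um = depth[1], depth_hi_um = depth[2],
      depth_mid_um = mean(depth), n_nuclei = nrow(nuc),
      density_per_mm2 = nrow(nuc) / acc_mm2,
      loss_area_um2 = loss$loss_area_um2[1],
      mean_circularity = if (nrow(nuc)) mean(nuc$circularity) else NA_real_
    )
  }
  structure(list(nuclei = dplyr::bind_rows(nuclei),
                 per_slice = dplyr::bind_rows(per_slice),
                 classifier = classifier),
            class = "stack_result")
}

#' Depth-indexed tissue-response profiles for a processed stack
#'
#' Joins the per-slice records on their depth midpoints, attaches layer
#' labels, and smooths the cell-loss, density, and circularity profiles with
#' a local polynomial (loess) fit, reporting the depth of the smoothed
#' cell-loss maximum.
#'
#' @param result A `stack_result` from [process_stack()].
#' @param map A [layer_map()].
#' @param span Loess span for the smoothed cell-loss and circularity
#'   profiles.
#' @param span_density Loess span for the nuclei-density profile; finer
#'   than `span` because density varies on laminar (~200-300 um) scales
#'   while the loss profile is a single broad peak.
#' @return List of class `stack_profile`: `per_slice` (with `layer`),
#'   `smooth` (tibble: `depth_um`, `loss_area_um2`, `density_per_mm2`,
#'   `mean_circularity`), `loss_peak_um` (argmax of the smoothed loss
#'   profile), `density_peaks_um` (local maxima of the smoothed density).
#' @export
stack_profile <- function(result, map = default_layer_map(), span = 0.5,
                          span_density = 0.25) {
  stopifnot(inherits(result, "stack_result"))
  ps <- result$per_slice
  if (nrow(ps) < 2) stop("need at least 2 depth-tagged slices")
  if (anyDuplicated(ps$depth_lo_um)) stop("duplicate depth tags in the stack")
  ps <- dplyr::mutate(ps, layer = assign_layer(.data$depth_mid_um, map)) |>
    dplyr::arrange(.data$depth_mid_um)
  grid <- seq(min(ps$depth_mid_um), max(ps$depth_mid_um), length.out = 400)
  smooth_col <- function(col, sp) {
    ok <- is.finite(ps[[col]])
    if (sum(ok) < 8) return(rep(NA_real_, length(grid)))
    fit <- loess(stats::reformulate("depth_mid_um", col), data = ps[ok, ],
                 span = sp, degree = 2)
    predict(fit, newdata = data.frame(depth_mid_um = grid))
  }
  smooth <- tibble::tibble(
    depth_um = grid,
    loss_area_um2 = smooth_col("loss_area_um2", span),
    density_per_mm2 = smooth_col("density_per_mm2", span_density),
    mean_circularity = smooth_col("mean_circularity", span)
  )
  loss_peak <- if (all(is.na(smooth$loss_area_um2))) NA_real_ else {
    grid[which.max(smooth$loss_area_um2)]
  }
  dens <- smooth$density_per_mm2
  peaks <- which(diff(sign(diff(dens))) == -2) + 1L
  structure(list(per_slice = ps, smooth = smooth, loss_peak_um = loss_peak,
                 density_peaks_um = grid[peaks]),
            class = "stack_profile")
}
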