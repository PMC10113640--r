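#' Reconstruct the ground-truth nucleus mask of a phantom slice
#'
#' Rasterises the generator's true nucleus ellipses (no noise, no hole) into
#' a logical mask, for training and scoring the pixel classifier.
#'
#' @param slice A `histo_slice` from [render_slice()].
#' @return Logical matrix, `TRUE` on nucleus pixels.
#' @export
nucleus_mask <- function(slice) {
  stopifnot(inherits(slice, "histo_slice"))
  s <- slice$pixel_size_um
  ny <- nrow(slice$image); nx <- ncol(slice$image)
  mask <- matrix(FALSE, ny, nx)
  tr <- slice$truth
  r_n <- slice$nucleus_radius_um
  for (i in seq_len(nrow(tr))) {
    # recover absolute axes from the ratio and the conserved area
    a_um <- sqrt(tr$axis_ratio[i]) * r_n
    b_um <- r_n / sqrt(tr$axis_ratio[i])
    half <- a_um + s
    col_rng <- max(1, floor((tr$x_um[i] - half) / s)):min(nx, ceiling((tr$x_um[i] + half) / s))
    row_rng <- max(1, floor((tr$y_um[i] - half) / s)):min(ny, ceiling((tr$y_um[i] + half) / s))
    px <- (col_rng - 0.5) * s - tr$x_um[i]
    py <- (row_rng - 0.5) * s - tr$y_um[i]
    th <- tr$theta[i]
    u <- outer(py, px, function(yy, xx) xx * cos(th) + yy * sin(th))
    v <- outer(py, px, function(yy, xx) -xx * sin(th) + yy * cos(th))
    mask[row_rng, col_rng] <- mask[row_rng, col_rng] |
      (u / a_um)^2 + (v / b_um)^2 <= 1
  }
  mask
}

#' Train the nuclei pixel classifier
#'
#' Fits a single-hidden-layer perceptron (via \pkg{nnet}) that maps the
#' per-pixel feature stack ([pixel_features()]) to the probability of
#' belonging to a nucleus. Training pixels are subsampled (balanced between
#' classes) from the supplied labelled images; selection and weight
#' initialisation are seeded, so identical seeds give identical classifiers.
#'
#' @param images List of intensity matrices (preprocessed slices).
#' @param masks List of logical matrices, `TRUE` on nucleus pixels; both
#'   classes must be present overall.
#' @param sigmas Feature scales, see [pixel_features()].
#' @param n_per_class Training pixels drawn per class.
#' @param size Hidden units.
#' @param maxit Optimiser iterations.
#' @param seed Integer seed.
#' @return Object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, masks, sigmas = c(1, 2),
                                   n_per_class = 4000, size = 4,
                                   maxit = 200, seed = 1) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  feats <- do.call(rbind, lapply(images, pixel_features, sigmas = sigmas))
  y <- unlist(lapply(masks, as.vector))
  if (length(unique(y)) < 2) {
    stop("training labels must contain both nucleus and background pixels")
  }
  withr::with_seed(seed, {
    pos <- which(y); neg <- which(!y)
    pos <- pos[sample.int(length(pos), min(n_per_class, length(pos)))]
    neg <- neg[sample.int(length(neg), min(n_per_class, length(neg)))]
    idx <- c(pos, neg)
    fit <- nnet::nnet(feats[idx, , drop = FALSE], as.numeric(y[idx]),
                      size = size, decay = 1e-4, maxit = maxit,
                      entropy = TRUE, trace = FALSE)
  })
  structure(list(fit = fit, sigmas = sigmas, features = colnames(feats)),
            class = "pixel_classifier")
}

#' Select a training subset of slices
#'
#' Picks roughly a fraction (default 5%) of the stack's slices at random
#' depths, seeded, as the classifier's training set.
#'
#' @param n_slices Number of slices in the stack.
#' @param frac Fraction to select.
#' @param seed Integer seed.
#' @return Sorted integer indices (at least one).
#' @export
select_training_slices <- function(n_slices, frac = 0.05, seed = 1) {
  n_pick <- max(1L, round(frac * n_slices))
  withr::with_seed(seed, sort(sample.int(n_slices, n_pick)))
}

#' Per-pixel nucleus probability map
#'
#' @param classifier A `pixel_classifier`.
#' @param image Intensity matrix.
#' @return Matrix of probabilities in 0..1, same shape as `image`.
#' @export
predict_pixels <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  p <- predict(classifier$fit, pixel_features(image, classifier$sigmas))
  matrix(p, nrow = nrow(image), ncol = ncol(image))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
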