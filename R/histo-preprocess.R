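#' Preprocess a histology image
#'
#' Standardises a fluorescence slice for pixel classification: grayscale
#' intensities normalised to `[0, 1]` (8-bit quantisation belongs to image
#' I/O, not the analysis), a Gaussian blur, and a linear contrast stretch
#' that saturates a total fraction of pixels (split equally between the two
#' tails) before rescaling to the full intensity range. With
#' `blur_sigma = 0` and `saturation = 0` the image passes through unchanged;
#' a constant image is never altered by the stretch.
#'
#' @param image Numeric matrix with intensities in 0..1.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = no blur).
#' @param saturation Total clipped fraction, in `[0, 0.5)`; default 0.002
#'   (0.2%).
#' @return Matrix in 0..1.
#' @export
preprocess_slice <- function(image, blur_sigma = 1, saturation = 0.002) {
  stopifnot(is.matrix(image), saturation >= 0, saturation < 0.5)
  if (length(image) == 0) stop("empty image")
  img <- pmin(pmax(image, 0), 1)
  if (blur_sigma > 0) {
    img <- gauss_smooth(img, blur_sigma)
  }
  if (saturation > 0) {
    qs <- quantile(img, c(saturation / 2, 1 - saturation / 2), names = FALSE)
    if (qs[2] > qs[1]) {
      img <- (pmin(pmax(img, qs[1]), qs[2]) - qs[1]) / (qs[2] - qs[1])
    }
  }
  img
}

# Separable Gaussian smoothing with edge renormalisation (pure base R;
# kernels are small so banded matrix products are cheap).
gauss_smooth <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  smooth_one <- function(n) {
    A <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= h, k[abs(i - j) + h + 1], 0))
    A / rowSums(A)
  }
  Ar <- smooth_one(nrow(m))
  Ac <- smooth_one(ncol(m))
  Ar %*% m %*% t(Ac)
}

#' Per-pixel feature stack for nuclei classification
#'
#' Builds the documented small feature set used by the pixel classifier: raw
#' intensity, Gaussian smoothings at two scales, and gradient magnitude
#' (central differences).
#'
#' @param image Numeric intensity matrix (0..1).
#' @param sigmas Gaussian scales in pixels.
#' @return Matrix with one row per pixel (column-major order) and named
#'   feature columns.
#' @export
pixel_features <- function(image, sigmas = c(1, 2)) {
  stopifnot(is.matrix(image))
  feats <- list(intensity = as.vector(image))
  for (s in sigmas) {
    feats[[sprintf("gauss_%g", s)]] <- as.vector(gauss_smooth(image, s))
  }
  gx <- image
  gx[, ] <- 0
  gx[, 2:(ncol(image) - 1)] <- (image[, 3:ncol(image)] -
                                  image[, 1:(ncol(image) - 2)]) / 2
  gy <- image
  gy[, ] <- 0
  gy[2:(nrow(image) - 1), ] <- (image[3:nrow(image), ] -
                                  image[1:(nrow(image) - 2), ]) / 2
  feats$gradient <- as.vector(sqrt(gx^2 + gy^2))
  do.call(cbind, feats)
}
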