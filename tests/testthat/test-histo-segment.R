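test_that("circularity matches analytic shapes", {
  r <- 5.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(1, 4), pi / 4)
  # scale invariance
  expect_equal(circularity(pi * 100^2, 2 * pi * 100),
               circularity(pi * 0.1^2, 2 * pi * 0.1))
  # 2:1 ellipse against a quadrature perimeter oracle
  a <- 2; b <- 1
  per <- 4 * a * integrate(function(t) sqrt(1 - (1 - (b / a)^2) * sin(t)^2),
                           0, pi / 2, rel.tol = 1e-12)$value
  expect_equal(circularity(pi * a * b, per), 0.8412, tolerance = 1e-4)
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
})

test_that("rasterised circularity converges to 1 with resolution", {
  errs <- vapply(c(8, 32, 200), function(r) {
    abs(measure_region(disk_mask(r))$circularity - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("region areas are unbiased within 5% for disks >= 5 px", {
  for (r in c(5, 9, 15)) {
    m <- measure_region(disk_mask(r))
    expect_equal(m$area_um2, pi * r^2, tolerance = 0.05)
  }
})

test_that("preprocessing is identity at zero blur and saturation", {
  set.seed(1)
  img <- matrix(sample(0:255, 900, replace = TRUE) / 255, 30, 30)
  expect_equal(preprocess_slice(img, blur_sigma = 0, saturation = 0), img)
  cst <- matrix(0.43, 20, 20)
  out <- preprocess_slice(cst, blur_sigma = 0, saturation = 0.02)
  expect_true(all(out == out[1, 1]))
  expect_error(preprocess_slice(matrix(numeric(0), 0, 0)), "empty")
})

test_that("contrast stretch clips the stated tail fractions of a ramp", {
  n <- 100 * 100
  img <- matrix(seq(0.2, 0.8, length.out = n), 100, 100)
  out <- preprocess_slice(img, blur_sigma = 0, saturation = 0.002)
  expect_lte(abs(sum(out == 0) - 0.001 * n), 1)
  expect_lte(abs(sum(out == 1) - 0.001 * n), 1)
})

test_that("the pixel classifier separates separable intensities", {
  set.seed(3)
  mk_img <- function() {
    lab <- matrix(runif(60 * 60) < 0.3, 60, 60)
    img <- ifelse(lab, 200 + rnorm(3600, 0, 5), 20 + rnorm(3600, 0, 5)) / 255
    list(img = pmin(pmax(img, 0), 1), lab = lab)
  }
  tr <- mk_img(); te <- mk_img()
  cl <- train_pixel_classifier(list(tr$img), list(tr$lab), n_per_class = 800,
                               seed = 2)
  acc <- mean((predict_pixels(cl, te$img) >= 0.5) == te$lab)
  expect_gte(acc, 0.99)
  # probability discrimination between the true classes
  disc <- function(fit) {
    p <- predict_pixels(fit, te$img)
    mean(p[te$lab]) - mean(p[!te$lab])
  }
  expect_gt(disc(cl), 0.5)
  # permutation control: shuffled labels carry no class signal
  shuf <- matrix(sample(tr$lab), nrow(tr$lab))
  cl0 <- train_pixel_classifier(list(tr$img), list(shuf), n_per_class = 800,
                                seed = 2)
  expect_lt(abs(disc(cl0)), 0.3)
  # determinism under a fixed seed
  cl2 <- train_pixel_classifier(list(tr$img), list(tr$lab), n_per_class = 800,
                                seed = 2)
  expect_identical(predict_pixels(cl, te$img), predict_pixels(cl2, te$img))
  expect_error(train_pixel_classifier(list(tr$img),
                                      list(matrix(TRUE, 60, 60))),
               "both")
})

test_that("segmentation recovers non-overlapping disks with subpixel centroids", {
  # 7x7 grid of disks, radius 5 px, on a quiet background
  img <- matrix(0.12, 220, 220)
  centers <- expand.grid(x = seq(20, 200, by = 30), y = seq(20, 200, by = 30))
  for (i in seq_len(nrow(centers))) {
    xx <- outer(rep(1, 220), seq_len(220)) - centers$x[i]
    yy <- outer(seq_len(220), rep(1, 220)) - centers$y[i]
    img[xx^2 + yy^2 <= 25] <- 0.8
  }
  set.seed(4)
  img <- pmin(pmax(img + rnorm(length(img), 0, 0.03), 0), 1)
  truth_mask <- matrix(FALSE, 220, 220)
  for (i in seq_len(nrow(centers))) {
    xx <- outer(rep(1, 220), seq_len(220)) - centers$x[i]
    yy <- outer(seq_len(220), rep(1, 220)) - centers$y[i]
    truth_mask[xx^2 + yy^2 <= 25] <- TRUE
  }
  cl <- train_pixel_classifier(list(img), list(truth_mask), seed = 5)
  nuc <- segment_nuclei(img, cl, pixel_size_um = 1)
  expect_equal(nrow(nuc), nrow(centers))
  sc <- score_segmentation(nuc,
                           tibble::tibble(x_um = centers$x - 0.5,
                                          y_um = centers$y - 0.5))
  expect_equal(sc$f1, 1)
  expect_lt(sc$mean_centroid_err_um, 1)
  # blank image yields no nuclei
  blank <- matrix(0.12, 80, 80)
  expect_equal(nrow(segment_nuclei(blank, cl, pixel_size_um = 1)), 0)
  expect_error(segment_nuclei(img, cl), "calibration")
})

test_that("watershed declumping splits touching disks", {
  img <- matrix(0.1, 60, 90)
  for (cx in c(35, 55)) {
    xx <- outer(rep(1, 60), seq_len(90)) - cx
    yy <- outer(seq_len(60), rep(1, 60 * 90 / 60)) - 30
    img[xx^2 + yy^2 <= 100] <- 0.85
  }
  mask <- img > 0.5
  cl <- train_pixel_classifier(list(img), list(mask), n_per_class = 500,
                               seed = 6)
  merged <- segment_nuclei(img, cl, pixel_size_um = 1, declump = FALSE)
  split <- segment_nuclei(img, cl, pixel_size_um = 1, declump = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
})
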