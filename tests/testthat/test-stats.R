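# Explicit sum-of-squares one-way ANOVA oracle.
anova_oracle <- function(value, group) {
  g <- split(value, group)
  grand <- mean(value)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- length(value) - length(g)
  f <- (ss_b / df1) / (ss_w / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(10)
  d <- tibble::tibble(layer = rep(c("a", "b"), each = 12),
                      y = rnorm(24) + rep(c(0, 1), each = 12))
  res <- layer_anova(d, "y")
  tt <- t.test(y ~ layer, data = d, var.equal = TRUE)
  expect_equal(res$anova$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA matches the brute-force sum-of-squares oracle", {
  set.seed(11)
  d <- tibble::tibble(layer = sample(letters[1:5], 30, replace = TRUE),
                      y = rnorm(30))
  while (min(table(d$layer)) < 2) {
    d <- tibble::tibble(layer = sample(letters[1:5], 30, replace = TRUE),
                        y = rnorm(30))
  }
  res <- layer_anova(d, "y")
  oracle <- anova_oracle(d$y, d$layer)
  expect_equal(res$anova$statistic, oracle$f, tolerance = 1e-8)
  expect_equal(res$anova$p.value, oracle$p, tolerance = 1e-8)
  # Bonferroni adjustment: p_adj = min(1, m p), never below raw p
  m <- choose(5, 2)
  expect_equal(res$pairwise$p.adj,
               pmin(1, m * res$pairwise$p.value))
  expect_true(all(res$pairwise$p.adj >= res$pairwise$p.value))
  expect_true(all(res$pairwise$p.adj <= 1))
  # Tukey alternative runs and returns all pairs
  tk <- layer_anova(d, "y", pairwise = "tukey")
  expect_equal(nrow(tk$pairwise), m)
  expect_error(layer_anova(d[d$layer == d$layer[1], ], "y"), "2 groups")
})

test_that("ANCOVA interaction equals the full-vs-reduced F test", {
  set.seed(12)
  d <- tibble::tibble(layer = rep(c("a", "b", "c"), each = 10),
                      week = rep(1:5, 6),
                      y = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  res <- ancova_time(d, "y")
  full <- lm(y ~ layer * week, data = d)
  reduced <- lm(y ~ layer + week, data = d)
  cmp <- anova(reduced, full)
  expect_equal(res$interaction$statistic, cmp$F[2], tolerance = 1e-8)
  expect_equal(res$interaction$p.value, cmp$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(res$interaction$df1, cmp$Df[2])
  expect_error(ancova_time(d[d$week == 1, ], "y"), "vary")
})

test_that("Kruskal-Wallis agrees with a rank-based oracle", {
  set.seed(13)
  d <- tibble::tibble(layer = rep(c("a", "b"), c(9, 11)), y = rnorm(20))
  res <- nonparam_tests(d, "y")
  # brute-force H without ties
  r <- rank(d$y)
  n <- length(r)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, d$layer, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  expect_equal(res$kruskal$statistic, h, tolerance = 1e-8)
  expect_equal(res$kruskal$p.value,
               pchisq(h, 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_true(all(c("shapiro", "levene") %in% names(res)))
  expect_error(nonparam_tests(tibble::tibble(layer = c("a", "a", "b", "b"),
                                             y = rep(1, 4)), "y"),
               "tied")
})

test_that("shifted distributions are detected with high power", {
  set.seed(14)
  rej <- vapply(1:60, function(i) {
    d <- tibble::tibble(layer = rep(c("a", "b"), each = 50),
                        y = rnorm(100) + rep(c(0, 1), each = 50))
    nonparam_tests(d, "y")$kruskal$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("depth trends recover linear slopes and loess peaks", {
  d <- tibble::tibble(depth_um = seq(50, 1550, by = 100))
  d$y <- 5 + 0.012 * d$depth_um # 12 units per mm
  lin <- suppressWarnings(depth_trend(d, "y", smoother = "linear"))
  expect_equal(lin$slope_per_mm, 12, tolerance = 1e-10)
  # unit consistency: per-mm slope is 1000x the per-um slope
  expect_equal(lin$slope_per_mm,
               1000 * unname(coef(lm(y ~ depth_um, d))[2]), tolerance = 1e-10)
  lo <- depth_trend(d, "y", smoother = "local_poly")
  expect_lt(max(abs(lo$curve$fitted - (5 + 0.012 * lo$curve$depth_um))), 1e-6)
  # range restriction
  lin2 <- suppressWarnings(depth_trend(d, "y", range_um = c(0, 500),
                                       smoother = "linear"))
  expect_equal(lin2$n, 5)
  expect_error(depth_trend(d[1:2, ], "y"), "3 points")
  # peaked profile: loess argmax near the true peak
  d2 <- tibble::tibble(depth_um = seq(0, 1600, by = 40))
  d2$y <- exp(-((d2$depth_um - 1050) / 300)^2)
  lo2 <- depth_trend(d2, "y", smoother = "local_poly", span = 0.4)
  expect_lt(abs(lo2$peak_um - 1050), 100)
})

test_that("piecewise fits recover signed slopes around a breakpoint", {
  d <- tibble::tibble(depth_um = seq(50, 1550, by = 100))
  d$y <- profile_amplitude(amplitude_profile(), d$depth_um)
  fit <- piecewise_depth_fit(d, "y", breakpoint_um = 1050)
  expect_equal(fit$slope_per_mm, c(13.9, -31.6), tolerance = 1e-8)
})

test_that("tidiers expose the fitted statistics as tibbles", {
  set.seed(15)
  d <- tibble::tibble(layer = rep(c("a", "b", "c"), each = 8),
                      week = rep(1:4, 6), y = rnorm(24))
  a <- layer_anova(d, "y")
  expect_s3_class(tidy(a), "tbl_df")
  expect_named(glance(a), c("statistic", "df1", "df2", "p.value"))
  expect_equal(tidy(ancova_time(d, "y"))$term, "layer:time")
  np <- nonparam_tests(d, "y")
  expect_true("recommended" %in% names(glance(np)))
})
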