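#' One-way ANOVA across layers with pairwise comparisons
#'
#' Fits a one-way ANOVA of a metric across layer groups and runs all
#' pairwise two-tailed unpaired (pooled-variance) t-tests with a Bonferroni
#' adjustment (`p_adj = min(1, m * p)` over the `m` comparisons); Tukey's
#' HSD is available as the alternative post-hoc.
#'
#' @param data Tibble with one row per observation.
#' @param metric Name of the metric column (string).
#' @param group Name of the grouping column (default `"layer"`).
#' @param pairwise `"bonferroni"` (pairwise t-tests, default) or `"tukey"`.
#' @return Object of class `layer_anova`: `anova` (tibble: `statistic`,
#'   `df1`, `df2`, `p.value`), `pairwise` (tibble of comparisons), and the
#'   underlying `fit`.
#' @export
layer_anova <- function(data, metric, group = "layer",
                        pairwise = c("bonferroni", "tukey")) {
  pairwise <- match.arg(pairwise)
  df <- data.frame(value = data[[metric]], group = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  sizes <- table(df$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 groups with at least 2 observations each")
  }
  fit <- aov(value ~ group, data = df)
  tab <- anova(fit)
  an <- tibble::tibble(statistic = tab$`F value`[1], df1 = tab$Df[1],
                       df2 = tab$Df[2], p.value = tab$`Pr(>F)`[1])
  levs <- levels(df$group)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  if (pairwise == "bonferroni") {
    m <- length(pairs)
    pw <- purrr::map_dfr(pairs, function(pr) {
      tt <- t.test(df$value[df$group == pr[1]], df$value[df$group == pr[2]],
                   var.equal = TRUE)
      tibble::tibble(group1 = pr[1], group2 = pr[2],
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p.value = tt$p.value,
                     p.adj = min(1, m * tt$p.value))
    })
  } else {
    th <- TukeyHSD(fit)$group
    pw <- tibble::tibble(
      group1 = sub("-.*", "", rownames(th)),
      group2 = sub(".*-", "", rownames(th)),
      estimate = th[, "diff"], p.adj = th[, "p adj"]
    )
  }
  structure(list(anova = an, pairwise = pw, method = pairwise, fit = fit),
            class = "layer_anova")
}

#' ANCOVA of a metric over layers with time as covariate
#'
#' Fits `metric ~ layer + time + layer:time` and reports the interaction
#' F-test (does the temporal slope differ between layers), equivalent to
#' the full-vs-reduced model comparison.
#'
#' @param data Tibble with one row per observation.
#' @param metric Metric column name.
#' @param group Layer column name.
#' @param time Time column name (e.g. week).
#' @return Object of class `ancova_time` with `interaction` (tibble:
#'   `statistic`, `df1`, `df2`, `p.value`) and the `fit`.
#' @export
ancova_time <- function(data, metric, group = "layer", time = "week") {
  df <- data.frame(value = data[[metric]], group = factor(data[[group]]),
                   time = data[[time]])
  df <- df[complete.cases(df), ]
  if (length(unique(df$group)) < 2 || length(unique(df$time)) < 2) {
    stop("both layer and time must vary")
  }
  fit <- lm(value ~ group * time, data = df)
  tab <- anova(fit)
  i <- which(rownames(tab) == "group:time")
  if (tab$Df[i] < 1 || !is.finite(tab$`F value`[i])) {
    stop("rank-deficient design: interaction not estimable")
  }
  structure(
    list(interaction = tibble::tibble(statistic = tab$`F value`[i],
                                      df1 = tab$Df[i],
                                      df2 = tab$Df[nrow(tab)],
                                      p.value = tab$`Pr(>F)`[i]),
         fit = fit),
    class = "ancova_time"
  )
}

#' Non-parametric battery across groups
#'
#' Kruskal-Wallis across groups, pairwise Wilcoxon rank-sum tests
#' (Bonferroni-adjusted), and the assumption checks that gate the
#' parametric path: Shapiro-Wilk normality per group and Levene's test of
#' variance homogeneity.
#'
#' @param data Tibble with one row per observation.
#' @param metric Metric column name.
#' @param group Grouping column name.
#' @return Object of class `nonparam_tests`: `kruskal` (tibble: `statistic`,
#'   `df`, `p.value`), `pairwise`, `shapiro` (per group), `levene`, and
#'   `recommended` (`"parametric"` when no assumption check rejects at
#'   0.05, else `"nonparametric"`).
#' @export
nonparam_tests <- function(data, metric, group = "layer") {
  df <- data.frame(value = data[[metric]], group = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  if (length(unique(df$group)) < 2) stop("need at least 2 groups")
  if (sd(df$value) == 0) stop("degenerate data: all values tied")
  kw <- kruskal.test(df$value, df$group)
  levs <- levels(df$group)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    wt <- suppressWarnings(
      wilcox.test(df$value[df$group == pr[1]], df$value[df$group == pr[2]])
    )
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic), p.value = wt$p.value,
                   p.adj = min(1, m * wt$p.value))
  })
  sh <- purrr::map_dfr(levs, function(l) {
    v <- df$value[df$group == l]
    p <- if (length(v) >= 3 && sd(v) > 0) shapiro.test(v)$p.value else NA_real_
    tibble::tibble(group = l, n = length(v), p.value = p)
  })
  lv <- car::leveneTest(value ~ group, data = df)
  levene <- tibble::tibble(statistic = lv$`F value`[1], df1 = lv$Df[1],
                           df2 = lv$Df[2], p.value = lv$`Pr(>F)`[1])
  normal_ok <- all(sh$p.value > 0.05, na.rm = TRUE)
  var_ok <- levene$p.value > 0.05
  structure(
    list(kruskal = tibble::tibble(statistic = unname(kw$statistic),
                                  df = unname(kw$parameter),
                                  p.value = kw$p.value),
         pairwise = pw, shapiro = sh, levene = levene,
         recommended = if (normal_ok && var_ok) "parametric" else "nonparametric"),
    class = "nonparam_tests"
  )
}

#' Depth trend of a metric
#'
#' Either the least-squares linear slope of a metric against cortical depth
#' over a stated range (reported per mm), or a loess local-polynomial
#' smooth returning the fitted curve and the depth of its maximum.
#'
#' @param data Tibble with a depth column (um) and the metric.
#' @param metric Metric column name.
#' @param depth Depth column name.
#' @param range_um Optional `c(lo, hi)` depth range to fit over (inclusive).
#' @param smoother `"linear"` or `"local_poly"`.
#' @param span Loess span (local_poly).
#' @return For `"linear"`, a tibble `slope_per_mm`, `intercept`, `n`,
#'   `p.value`. For `"local_poly"`, a list of class `depth_trend` with
#'   `curve` (tibble `depth_um`, `fitted`) and `peak_um`.
#' @export
depth_trend <- function(data, metric, depth = "depth_um", range_um = NULL,
                        smoother = c("linear", "local_poly"), span = 0.5) {
  smoother <- match.arg(smoother)
  df <- data.frame(depth = data[[depth]], value = data[[metric]])
  df <- df[complete.cases(df), ]
  if (!is.null(range_um)) {
    df <- df[df$depth >= range_um[1] & df$depth <= range_um[2], ]
  }
  if (nrow(df) < 3) stop("need at least 3 points in the depth range")
  if (smoother == "linear") {
    fit <- lm(value ~ I(depth / 1000), data = df)
    sm <- summary(fit)$coefficients
    tibble::tibble(slope_per_mm = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]), n = nrow(df),
                   p.value = sm[2, 4])
  } else {
    fit <- loess(value ~ depth, data = df, span = span, degree = 2)
    grid <- seq(min(df$depth), max(df$depth), length.out = 400)
    fitted <- predict(fit, newdata = data.frame(depth = grid))
    structure(list(curve = tibble::tibble(depth_um = grid, fitted = fitted),
                   peak_um = grid[which.max(fitted)], span = span),
              class = "depth_trend")
  }
}

#' Piecewise-linear amplitude-depth fit
#'
#' Fits separate least-squares slopes (per mm) to the rising segment
#' (depths up to the breakpoint) and the falling segment (depths from the
#' breakpoint on), the standard summary of an amplitude profile peaking
#' mid-cortex.
#'
#' @param data Tibble with depth and metric columns.
#' @param metric Metric column name.
#' @param depth Depth column name.
#' @param breakpoint_um Depth of the presumed peak, um.
#' @return Tibble with rows `rising` and `falling`: `segment`,
#'   `slope_per_mm`, `n`.
#' @export
piecewise_depth_fit <- function(data, metric, depth = "depth_um",
                                breakpoint_um = 1050) {
  df <- data.frame(depth = data[[depth]], value = data[[metric]])
  df <- df[complete.cases(df), ]
  seg <- function(rows, name) {
    d <- df[rows, ]
    if (nrow(d) < 2) {
      return(tibble::tibble(segment = name, slope_per_mm = NA_real_,
                            n = nrow(d)))
    }
    tibble::tibble(segment = name,
                   slope_per_mm = unname(coef(lm(value ~ I(depth / 1000),
                                                 data = d))[2]),
                   n = nrow(d))
  }
  dplyr::bind_rows(seg(df$depth <= breakpoint_um, "rising"),
                   seg(df$depth >= breakpoint_um, "falling"))
}
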