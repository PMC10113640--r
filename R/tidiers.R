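#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy pairwise comparisons of a layer ANOVA
#'
#' @param x A `layer_anova` object.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons.
#' @export
tidy.layer_anova <- function(x, ...) x$pairwise

#' One-row summary of a layer ANOVA
#'
#' @param x A `layer_anova` object.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df1`, `df2`, `p.value`.
#' @export
glance.layer_anova <- function(x, ...) x$anova

#' Tidy the interaction test of an ANCOVA over time
#'
#' @param x An `ancova_time` object.
#' @param ... Unused.
#' @return Tibble with the interaction F-test.
#' @export
tidy.ancova_time <- function(x, ...) {
  dplyr::mutate(x$interaction, term = "layer:time", .before = 1)
}

#' @rdname tidy.ancova_time
#' @export
glance.ancova_time <- function(x, ...) x$interaction

#' Tidy the pairwise Wilcoxon comparisons of a non-parametric battery
#'
#' @param x A `nonparam_tests` object.
#' @param ... Unused.
#' @return Tibble of pairwise rank-sum comparisons.
#' @export
tidy.nonparam_tests <- function(x, ...) x$pairwise

#' One-row Kruskal-Wallis summary
#'
#' @param x A `nonparam_tests` object.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p.value`, `recommended`.
#' @export
glance.nonparam_tests <- function(x, ...) {
  dplyr::mutate(x$kruskal, recommended = x$recommended)
}

#' @export
print.layer_anova <- function(x, ...) {
  cat("One-way ANOVA across layers\n")
  print(x$anova)
  cat("Pairwise (", x$method, "):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @export
print.ancova_time <- function(x, ...) {
  cat("ANCOVA layer x time interaction\n")
  print(x$interaction)
  invisible(x)
}

#' @export
print.nonparam_tests <- function(x, ...) {
  cat("Kruskal-Wallis (recommended path: ", x$recommended, ")\n", sep = "")
  print(x$kruskal)
  invisible(x)
}
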