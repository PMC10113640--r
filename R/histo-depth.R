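#' Tag a serial cryosection by slide and slice position
#'
#' Serial sections are distributed cyclically across slides: slice 1 goes to
#' slide 1, slice 2 to slide 2, ..., so that consecutive depths land on
#' consecutive slides, and each slide accumulates one slice per cycle.
#'
#' @param slide 1-based slide index within the cycle.
#' @param position 1-based slice position on the slide.
#' @param thickness_um Section thickness, um.
#' @param slides_per_cycle Number of slides in one distribution cycle.
#' @return A list of class `slice_tag`.
#' @export
slice_tag <- function(slide, position, thickness_um = 20,
                      slides_per_cycle = 10) {
  stopifnot(slide >= 1, position >= 1, thickness_um > 0,
            slides_per_cycle >= 1, slide <= slides_per_cycle)
  structure(list(slide = as.integer(slide), position = as.integer(position),
                 thickness_um = thickness_um,
                 slides_per_cycle = as.integer(slides_per_cycle)),
            class = "slice_tag")
}

#' Cortical depth interval of a tagged section
#'
#' Recovers the depth interval a serial section was cut at from its slide
#' identity and slice position. The serial index is
#' `i = (position - 1) * slides_per_cycle + slide`, and the section spans
#' `[(i - 1) * thickness, i * thickness)` um from the pia: the first slice
#' on slide 1 is 0-20 um, the first slice on slide 2 is 20-40 um, and so on.
#'
#' @param tag A [slice_tag()].
#' @return Named numeric vector `c(depth_lo_um, depth_hi_um)` (half-open
#'   interval).
#' @examples
#' slice_depth(slice_tag(1, 1)) # 0-20 um
#' slice_depth(slice_tag(2, 1)) # 20-40 um
#' @export
slice_depth <- function(tag) {
  stopifnot(inherits(tag, "slice_tag"))
  i <- (tag$position - 1L) * tag$slides_per_cycle + tag$slide
  c(depth_lo_um = (i - 1) * tag$thickness_um,
    depth_hi_um = i * tag$thickness_um)
}
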