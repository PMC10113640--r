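#' Write / read a recording session as raw binary plus JSON sidecar
#'
#' The on-disk format is little-endian int16, channel-interleaved
#' (`recording.bin`), with a JSON sidecar (`recording.json`) holding the
#' sampling rate, gain (uV per least-significant bit), channel depths, and
#' week stamp. Ground truth is not serialised.
#'
#' @param session A `recording_session`.
#' @param dir Directory to write into (created if needed).
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns a `recording_session` (with `truth = NULL`).
#' @export
write_recording <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peak <- max(abs(session$traces), 1e-6)
  gain <- peak / 32000
  q <- round(t(session$traces) / gain) # channel-interleaved
  con <- file(file.path(dir, "recording.bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2, endian = "little")
  jsonlite::write_json(
    list(fs = session$fs, gain_uv_per_lsb = gain,
         depths_um = session$depths_um, week = session$week,
         n_channels = ncol(session$traces), n_samples = nrow(session$traces),
         duration_s = session$duration_s),
    file.path(dir, "recording.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "recording.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "integer", size = 2, signed = TRUE,
                 n = meta$n_channels * meta$n_samples, endian = "little")
  traces <- t(matrix(raw, nrow = meta$n_channels)) * meta$gain_uv_per_lsb
  structure(
    list(traces = traces, fs = meta$fs, depths_um = meta$depths_um,
         week = meta$week, duration_s = meta$duration_s, truth = NULL),
    class = "recording_session"
  )
}

#' Write / read a histology stack as TIFF slices plus a JSON manifest
#'
#' Each slice is stored as a 16-bit grayscale TIFF; `manifest.json` records
#' the acquisition layout (slide, position, thickness, slides per cycle),
#' the pixel calibration, and the hole geometry per slice. Generator ground
#' truth is not serialised.
#'
#' @param stack A `histo_stack`.
#' @param dir Directory to write into.
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns
#'   a `histo_stack` (slices without `truth`).
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "histo_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(stack$slices))
  for (i in seq_along(stack$slices)) {
    sl <- stack$slices[[i]]
    fn <- sprintf("slice_%03d.tif", i)
    tiff::writeTIFF(sl$image, file.path(dir, fn), bits.per.sample = 16)
    entries[[i]] <- list(file = fn, slide = sl$tag$slide,
                         position = sl$tag$position,
                         depth_um = sl$depth_um,
                         hole_center_um = sl$hole$center_um,
                         hole_half_axes_um = sl$hole$half_axes_um)
  }
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         thickness_um = stack$thickness_um,
         slides_per_cycle = stack$slides_per_cycle,
         slices_per_slide = stack$slices_per_slide, slices = entries),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  slices <- lapply(seq_len(nrow(meta$slices)), function(i) {
    e <- meta$slices[i, ]
    img <- tiff::readTIFF(file.path(dir, e$file))
    structure(
      list(image = img, pixel_size_um = meta$pixel_size_um,
           depth_um = e$depth_um,
           tag = slice_tag(e$slide, e$position, meta$thickness_um,
                           meta$slides_per_cycle),
           hole = list(center_um = unlist(e$hole_center_um),
                       half_axes_um = unlist(e$hole_half_axes_um)),
           truth = NULL),
      class = "histo_slice"
    )
  })
  structure(list(slices = slices, thickness_um = meta$thickness_um,
                 slides_per_cycle = meta$slides_per_cycle,
                 slices_per_slide = meta$slices_per_slide,
                 pixel_size_um = meta$pixel_size_um),
            class = "histo_stack")
}
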