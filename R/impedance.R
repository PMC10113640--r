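#' Average repeated impedance sweeps in the complex plane
#'
#' Repeated sweeps of the same channel and day are averaged per frequency as
#' the arithmetic mean of the complex impedance (real and imaginary parts
#' averaged jointly), which preserves Nyquist geometry. The repeat index is
#' dropped from the output.
#'
#' @param sweeps Tibble of sweeps (columns `frequency_hz`, `z_real_ohm`,
#'   `z_imag_ohm`, `channel`, `day`, `repeat`), e.g. from [simulate_eis()] or
#'   [read_eis_csv()]. May contain several channels and days.
#' @return Tibble with one row per channel x day x frequency and no `repeat`
#'   column.
#' @export
average_sweeps <- function(sweeps) {
  check_eis(sweeps)
  grids <- sweeps |>
    dplyr::group_by(.data$channel, .data$day, .data$`repeat`) |>
    dplyr::summarise(grid = paste(signif(.data$frequency_hz, 12),
                                  collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1) {
    stop("sweeps to be averaged must share an identical frequency grid")
  }
  sweeps |>
    dplyr::group_by(.data$channel, .data$day, .data$frequency_hz) |>
    dplyr::summarise(z_real_ohm = mean(.data$z_real_ohm),
                     z_imag_ohm = mean(.data$z_imag_ohm), .groups = "drop") |>
    dplyr::arrange(.data$channel, .data$day, .data$frequency_hz)
}

#' Extract impedance magnitude and phase at a probe frequency
#'
#' Returns `|Z|` and the atan2 phase at the grid point nearest to `f0` in
#' log-frequency (default), or log-log interpolated between the bracketing
#' grid points.
#'
#' @param sweep Tibble of (averaged) sweeps; may contain several
#'   channel x day groups.
#' @param f0 Probe frequency, Hz (default 1 kHz); must lie within the grid
#'   range.
#' @param method `"nearest"` (default) or `"interp"`.
#' @return Tibble with columns `channel`, `day`, `frequency_hz` (the grid
#'   point used, or `f0` when interpolating), `mag_ohm`, `phase_deg`.
#' @export
at_frequency <- function(sweep, f0 = 1000, method = c("nearest", "interp")) {
  method <- match.arg(method)
  check_eis(sweep, need_repeat = FALSE)
  sweep |>
    dplyr::group_by(.data$channel, .data$day) |>
    dplyr::group_modify(function(g, key) {
      f <- g$frequency_hz
      if (f0 < min(f) || f0 > max(f)) {
        stop(sprintf("f0 = %g Hz outside the sweep range [%g, %g]",
                     f0, min(f), max(f)))
      }
      z <- complex(real = g$z_real_ohm, imaginary = g$z_imag_ohm)
      if (method == "nearest") {
        i <- which.min(abs(log(f) - log(f0)))
        tibble::tibble(frequency_hz = f[i], mag_ohm = Mod(z[i]),
                       phase_deg = Arg(z[i]) * 180 / pi)
      } else {
        mag <- exp(approx(log(f), log(Mod(z)), xout = log(f0))$y)
        ph <- approx(log(f), Arg(z) * 180 / pi, xout = log(f0))$y
        tibble::tibble(frequency_hz = f0, mag_ohm = mag, phase_deg = ph)
      }
    }) |>
    dplyr::ungroup()
}

#' Percent change between two impedance values
#'
#' @param v_from Baseline value (> 0).
#' @param v_to Final value.
#' @return `100 * (v_to - v_from) / v_from`.
#' @examples
#' percent_change(195.6, 1135.8) # first-week impedance rise, ~480.7%
#' @export
percent_change <- function(v_from, v_to) {
  if (any(v_from <= 0)) stop("`v_from` must be positive")
  100 * (v_to - v_from) / v_from
}

#' Summarise EIS sweeps at 1 kHz
#'
#' Averages repeats in the complex plane and extracts the 1 kHz magnitude and
#' phase per channel and day.
#'
#' @inheritParams average_sweeps
#' @param f0 Probe frequency, Hz.
#' @param method Extraction rule, see [at_frequency()].
#' @return Tibble with columns `channel`, `day`, `mag_1khz_ohm`,
#'   `phase_1khz_deg`.
#' @export
eis_summary <- function(sweeps, f0 = 1000, method = "nearest") {
  average_sweeps(sweeps) |>
    at_frequency(f0 = f0, method = method) |>
    dplyr::transmute(.data$channel, .data$day, mag_1khz_ohm = .data$mag_ohm,
                     phase_1khz_deg = .data$phase_deg)
}

#' Read / write impedance sweeps as CSV
#'
#' The on-disk format has columns `frequency_hz`, `z_real_ohm`, `z_imag_ohm`,
#' `channel`, `day`, `repeat`.
#'
#' @param path File path.
#' @param sweeps Tibble of sweeps.
#' @return `read_eis_csv()` returns the sweep tibble; `write_eis_csv()`
#'   returns `path` invisibly.
#' @export
read_eis_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_eis(tibble::as_tibble(df))
}

#' @rdname read_eis_csv
#' @export
write_eis_csv <- function(sweeps, path) {
  check_eis(sweeps)
  utils::write.csv(sweeps, path, row.names = FALSE)
  invisible(path)
}

check_eis <- function(sweeps, need_repeat = TRUE) {
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm", "channel", "day",
            if (need_repeat) "repeat")
  miss <- setdiff(need, names(sweeps))
  if (length(miss)) {
    stop("missing sweep columns: ", paste(miss, collapse = ", "))
  }
  if (any(sweeps$frequency_hz <= 0)) stop("frequencies must be positive")
  if (!all(is.finite(sweeps$z_real_ohm)) || !all(is.finite(sweeps$z_imag_ohm))) {
    stop("impedance values must be finite")
  }
  tibble::as_tibble(sweeps)
}
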