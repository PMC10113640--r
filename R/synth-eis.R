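#' Equivalent-circuit description for synthetic impedance sweeps
#'
#' A Randles-style interface model: solution resistance `rs_ohm` in series
#' with the parallel combination of a charge-transfer resistance `rct_ohm`
#' and a constant-phase element with admittance `q_s * (j*w)^n`. Degenerate
#' settings are allowed (`rct_ohm = 0` gives a pure resistor `rs_ohm`;
#' `rs_ohm = 0, rct_ohm = Inf, n = 1` gives a pure capacitor of capacitance
#' `q_s`).
#'
#' @param rs_ohm Solution (series) resistance, ohm.
#' @param rct_ohm Charge-transfer resistance, ohm (may be `Inf`).
#' @param q_s Constant-phase-element magnitude, S s^n.
#' @param n CPE exponent in (0, 1]; 1 is an ideal capacitor.
#' @return A list of class `eis_circuit`.
#' @export
eis_circuit <- function(rs_ohm = 15e3, rct_ohm = 2e6, q_s = 3e-9, n = 0.85) {
  stopifnot(rs_ohm >= 0, rct_ohm >= 0, q_s >= 0, n > 0, n <= 1)
  structure(list(rs_ohm = rs_ohm, rct_ohm = rct_ohm, q_s = q_s, n = n),
            class = "eis_circuit")
}

# Complex impedance of the circuit at frequencies f (Hz).
circuit_impedance <- function(circuit, f) {
  w <- 2 * pi * f
  y_cpe <- circuit$q_s * (1i * w)^circuit$n
  y_rct <- if (is.infinite(circuit$rct_ohm)) 0 else 1 / circuit$rct_ohm
  y <- y_rct + y_cpe
  z_par <- ifelse(Mod(y) == 0, complex(real = circuit$rct_ohm), 1 / y)
  circuit$rs_ohm + z_par
}

#' Day-by-day 1 kHz impedance-magnitude schedule
#'
#' Target impedance magnitudes at 1 kHz for post-implantation days 1..7,
#' log-linearly interpolated between the day-1 and day-7 population means of
#' 195.6 and 1,135.8 kOhm, reproducing the ~5.8-fold first-week rise.
#'
#' @param day1_kohm,day7_kohm Endpoint magnitudes at 1 kHz, kOhm.
#' @param days Integer vector of days covered by the schedule.
#' @return Named numeric vector of target magnitudes in ohm.
#' @export
eis_day_schedule <- function(day1_kohm = 195.6, day7_kohm = 1135.8,
                             days = 1:7) {
  tgt <- exp(seq(log(day1_kohm * 1e3), log(day7_kohm * 1e3),
                 length.out = length(days)))
  setNames(tgt, days)
}

#' Default logarithmic EIS frequency grid
#'
#' @param n Number of grid points.
#' @return Log-spaced frequencies from 10 Hz to 100 kHz.
#' @export
eis_frequency_grid <- function(n = 61) 10^seq(1, 5, length.out = n)

#' Simulate an electrochemical impedance sweep
#'
#' Evaluates the equivalent circuit over a frequency grid. When a day
#' schedule is supplied, the interfacial branch of the circuit is rescaled so
#' that the 1 kHz magnitude matches the schedule's target for that day
#' (series resistance unchanged), emulating the first-week impedance rise.
#' Optional multiplicative noise produces distinct repeats.
#'
#' @param day Day index (used to look up the schedule target).
#' @param f_grid Strictly positive, ascending frequency grid, Hz.
#' @param circuit An [eis_circuit()].
#' @param schedule Named target vector from [eis_day_schedule()], or `NULL`
#'   to use the circuit as-is.
#' @param channel Channel id attached to the sweep.
#' @param n_repeats Number of repeated sweeps.
#' @param noise_frac Multiplicative Gaussian noise s.d. on each complex
#'   sample (0 = deterministic).
#' @param seed Integer seed.
#' @return A tibble with columns `frequency_hz`, `z_real_ohm`, `z_imag_ohm`,
#'   `channel`, `day`, `repeat`.
#' @export
simulate_eis <- function(day = 1, f_grid = eis_frequency_grid(),
                         circuit = eis_circuit(),
                         schedule = eis_day_schedule(), channel = 1,
                         n_repeats = 1, noise_frac = 0, seed = 1) {
  if (any(f_grid <= 0)) stop("frequencies must be strictly positive")
  if (is.unsorted(f_grid, strictly = TRUE)) stop("`f_grid` must be ascending")
  z <- circuit_impedance(circuit, f_grid)
  if (!is.null(schedule)) {
    key <- as.character(day)
    if (!key %in% names(schedule)) {
      stop(sprintf("day %s not covered by the schedule", key))
    }
    target <- schedule[[key]]
    zp <- circuit_impedance(circuit, 1000) - circuit$rs_ohm
    # |rs + g * zp| = target, positive root of the quadratic in g
    a <- Mod(zp)^2
    b <- 2 * circuit$rs_ohm * Re(zp)
    cc <- circuit$rs_ohm^2 - target^2
    g <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    z <- circuit$rs_ohm + g * (z - circuit$rs_ohm)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      zr <- z * (1 + rnorm(length(z), sd = noise_frac))
      tibble::tibble(frequency_hz = f_grid, z_real_ohm = Re(zr),
                     z_imag_ohm = Im(zr), channel = channel, day = day,
                     `repeat` = r)
    })
  })
}
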