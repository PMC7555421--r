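DEFAULT_SENSITIVITY <- c(
  "13C" = 0.5, "23Na" = 2, "24Mg" = 10, "44Ca" = 5,
  "55Mn" = 500, "56Fe" = 20, "63Cu" = 100, "64Zn" = 80
)

DEFAULT_BACKGROUND <- c(
  "13C" = 150, "23Na" = 50, "24Mg" = 10, "44Ca" = 20,
  "55Mn" = 5, "56Fe" = 30, "63Cu" = 5, "64Zn" = 10
)

#' Linear multiplicative drift
#'
#' Instrument sensitivity drift as a function of fractional elapsed run
#' time \eqn{f \in [0,1]}: \code{1 + rise * f}. The same factor multiplies
#' every isotope's analyte signal, which is exactly the situation the
#' carbon-13 internal standard is meant to cancel.
#'
#' @param rise Total relative rise over the run (default 0.05).
#' @return A vectorized function of \code{f} with \code{drift(0) == 1}.
#' @export
linear_drift <- function(rise = 0.05) {
  force(rise)
  function(f) 1 + rise * f
}

#' @rdname linear_drift
#' @export
no_drift <- function() function(f) rep_len(1, length(f))

#' Instrument model for line-scan simulation
#'
#' Describes a sequential (peak-hopping) quadrupole ICP-MS coupled to a
#' line-scanning laser. One measurement cycle visits every isotope once, so
#' the cycle time is \code{n_isotopes * dwell_time + settle_overhead}; the
#' along-scan pixel pitch is \code{scan_speed * cycle_time} (9.9 µm with
#' the defaults: 8 isotopes, 20 ms dwell, 20 ms overhead, 55 µm/s).
#'
#' @param scan_speed_um_s Laser scan speed, µm/s; must lie in [50, 60].
#' @param dwell_time_s Per-isotope dwell time, s (default 0.020).
#' @param settle_overhead_s Per-cycle settling overhead, s (default 0.020).
#' @param isotopes Isotope labels acquired per cycle.
#' @param sensitivity Named cps per (µg/g) vector, all > 0.
#' @param background Named gas-blank vector, cps, >= 0.
#' @param noise_model \code{"poisson_gaussian"} (Poisson counting noise at
#'   \code{cps * dwell_time} plus Gaussian electronic noise),
#'   \code{"gaussian"} (purely relative Gaussian noise), or \code{"none"}.
#' @param electronic_sd_cps Electronic noise SD for the Poisson model, cps.
#' @param gaussian_cv Relative SD for the Gaussian model.
#' @param drift Vectorized function of fractional elapsed time with
#'   \code{drift(0) == 1}; multiplies the analyte signal of every isotope.
#' @param blank_cycles_per_line Laser-off cycles before and after each
#'   line (>= 1).
#' @param interline_gap_s Dead time between lines, s.
#' @param line_spacing_um Distance between adjacent lines; defaults to the
#'   along-scan pixel pitch (square pixels).
#' @param seed Integer seed for all stochastic draws.
#'
#' @return An object of class \code{instrument_model} with the derived
#'   \code{cycle_time_s} and \code{pixel_pitch_um} fields.
#'
#' @examples
#' instr <- instrument_model(seed = 1)
#' instr$cycle_time_s     # 0.18
#' instr$pixel_pitch_um   # 9.9
#' @export
instrument_model <- function(scan_speed_um_s = 55,
                             dwell_time_s = 0.020,
                             settle_overhead_s = 0.020,
                             isotopes = elamap_isotopes(),
                             sensitivity = DEFAULT_SENSITIVITY[isotopes],
                             background = DEFAULT_BACKGROUND[isotopes],
                             noise_model = c("poisson_gaussian", "gaussian", "none"),
                             electronic_sd_cps = 2,
                             gaussian_cv = 0.01,
                             drift = no_drift(),
                             blank_cycles_per_line = 3L,
                             interline_gap_s = 1,
                             line_spacing_um = NULL,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (scan_speed_um_s < 50 || scan_speed_um_s > 60) {
    stopf("scan_speed_um_s must lie in [50, 60] um/s (got %.3g)", scan_speed_um_s)
  }
  assert_scalar_number(dwell_time_s, "dwell_time_s", min = 1e-6)
  sensitivity <- sensitivity[isotopes]
  background <- background[isotopes]
  if (anyNA(sensitivity) || any(sensitivity <= 0)) {
    stopf("sensitivity must be > 0 for every isotope")
  }
  if (anyNA(background) || any(background < 0)) {
    stopf("background must be >= 0 for every isotope")
  }
  if (blank_cycles_per_line < 1L) stopf("blank_cycles_per_line must be >= 1")
  if (!is.function(drift) || abs(drift(0) - 1) > 1e-12) {
    stopf("`drift` must be a function with drift(0) == 1")
  }
  cycle_time <- length(isotopes) * dwell_time_s + settle_overhead_s
  pitch <- scan_speed_um_s * cycle_time
  if (is.null(line_spacing_um)) line_spacing_um <- pitch
  structure(list(
    scan_speed_um_s = scan_speed_um_s,
    dwell_time_s = dwell_time_s,
    settle_overhead_s = settle_overhead_s,
    isotopes = isotopes,
    cycle_time_s = cycle_time,
    pixel_pitch_um = pitch,
    sensitivity = sensitivity,
    background = background,
    noise_model = noise_model,
    electronic_sd_cps = electronic_sd_cps,
    gaussian_cv = gaussian_cv,
    drift = drift,
    blank_cycles_per_line = as.integer(blank_cycles_per_line),
    interline_gap_s = interline_gap_s,
    line_spacing_um = line_spacing_um,
    seed = as.integer(seed)
  ), class = "instrument_model")
}

#' Identity instrument
#'
#' Noise-free, drift-free, background-free instrument with unit sensitivity
#' for every isotope: the assembled cps map of a simulated run equals the
#' phantom concentration grid exactly. Used for round-trip verification.
#'
#' @param isotopes Isotope labels.
#' @param ... Passed on to [instrument_model()].
#' @return An \code{instrument_model}.
#' @export
identity_instrument <- function(isotopes = elamap_isotopes(), ...) {
  n <- length(isotopes)
  instrument_model(
    isotopes = isotopes,
    sensitivity = stats::setNames(rep(1, n), isotopes),
    background = stats::setNames(rep(0, n), isotopes),
    noise_model = "none", drift = no_drift(), ...
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(
    "<instrument_model> %g um/s, cycle %.3g s (pitch %.3g um), %d isotopes, noise=%s\n",
    x$scan_speed_um_s, x$cycle_time_s, x$pixel_pitch_um,
    length(x$isotopes), x$noise_model))
  invisible(x)
}
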