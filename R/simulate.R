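#' Simulate a line-scan run over a phantom
#'
#' Rasterizes the phantom with the instrument model: each phantom row
#' becomes one ablation line of \code{blank + width + blank} measurement
#' cycles. Laser-off cycles carry background only; laser-on cycles carry
#' \code{sensitivity * concentration * drift(t) + background}, with noise
#' per the instrument's noise model. The phantom pixel pitch must equal the
#' instrument's along-scan pitch (\code{scan_speed * cycle_time}) so that
#' assembly is an exact inverse.
#'
#' @param ph A [phantom()].
#' @param instrument An [instrument_model()] covering every phantom element.
#' @return A [raw_run()] with a per-line laser log.
#' @export
simulate_linescans <- function(ph, instrument) {
  if (!inherits(ph, "phantom")) stopf("`ph` must be a phantom")
  if (!inherits(instrument, "instrument_model")) {
    stopf("`instrument` must be an instrument_model")
  }
  isotopes <- names(ph$conc)
  missing_iso <- setdiff(isotopes, names(instrument$sensitivity))
  if (length(missing_iso)) {
    stopf("instrument lacks sensitivity for: %s", paste(missing_iso, collapse = ", "))
  }
  if (ph$width < 1L || ph$height < 1L) stopf("empty phantom")
  if (abs(ph$pixel_size_um - instrument$pixel_pitch_um) > 1e-6) {
    stopf(paste0("phantom pixel size (%.6g um) does not match the ",
                 "instrument pitch scan_speed * cycle_time = %.6g um"),
          ph$pixel_size_um, instrument$pixel_pitch_um)
  }
  h <- ph$height; w <- ph$width
  b <- instrument$blank_cycles_per_line
  n_c <- 2L * b + w
  ct <- instrument$cycle_time_s

  line_duration <- n_c * ct
  start_times <- (seq_len(h) - 1) * (line_duration + instrument$interline_gap_s)
  times <- outer(start_times, (seq_len(n_c) - 1) * ct, "+")  # h x n_c
  t_end <- max(times)
  frac <- if (t_end > 0) times / t_end else times * 0
  drift_mat <- matrix(instrument$drift(as.vector(frac)), h, n_c)

  on_cols <- (b + 1L):(b + w)
  dwell <- instrument$dwell_time_s

  intens <- list()
  for (e in isotopes) {
    expected <- matrix(instrument$background[[e]], h, n_c)
    expected[, on_cols] <- instrument$sensitivity[[e]] * ph$conc[[e]] *
      drift_mat[, on_cols] + instrument$background[[e]]
    obs <- with_seed(stream_seed(instrument$seed, 200L + stream_index(e)), {
      switch(instrument$noise_model,
        none = expected,
        gaussian = expected *
          (1 + instrument$gaussian_cv * matrix(stats::rnorm(h * n_c), h, n_c)),
        poisson_gaussian = {
          counts <- matrix(stats::rpois(h * n_c, as.vector(expected) * dwell),
                           h, n_c)
          counts / dwell +
            matrix(stats::rnorm(h * n_c, sd = instrument$electronic_sd_cps),
                   h, n_c)
        })
    })
    intens[[e]] <- pmax(obs, 0)
  }

  lines <- lapply(seq_len(h), function(i) {
    df <- data.frame(cycle_index = 0:(n_c - 1L), time_s = times[i, ])
    for (e in isotopes) df[[e]] <- intens[[e]][i, ]
    df
  })
  laser_log <- data.frame(
    line_index = 0:(h - 1L),
    y_um = (0:(h - 1L)) * instrument$line_spacing_um,
    start_time_s = start_times,
    laser_on_cycle = b,            # 0-based, inclusive
    laser_off_cycle = b + w,       # 0-based, exclusive
    scan_speed_um_s = instrument$scan_speed_um_s
  )
  raw_run(lines, isotopes, cycle_time_s = ct, laser_log = laser_log)
}

DEFAULT_MATRIX_BASELINE <- c(
  "13C" = 1e5, "23Na" = 900, "24Mg" = 180, "44Ca" = 45,
  "55Mn" = 1.0, "56Fe" = 140, "63Cu" = 2.5, "64Zn" = 22
)

DEFAULT_STANDARD_LEVELS <- list(
  "23Na" = c(0, 500, 1000, 2000),
  "24Mg" = c(0, 100, 200, 400),
  "44Ca" = c(0, 25, 50, 100),
  "55Mn" = c(0, 1, 2, 4),
  "56Fe" = c(0, 75, 150, 300),
  "63Cu" = c(0, 5, 50, 200),
  "64Zn" = c(0, 15, 30, 60)
)

#' Simulate matrix-matched calibration standards
#'
#' Emulates standards prepared from homogenized tissue spiked with a
#' multi-element salt solution: each standard is a spatially homogeneous
#' phantom whose concentration is the homogenate's matrix baseline plus the
#' spiked level, scanned with the same instrument model as the samples.
#' Standards are characterized by their \emph{total} element content
#' (baseline + spike), as certified reference materials are; the level-0
#' (unspiked) standard anchors the low end of each curve.
#'
#' @param levels Named list: per element, a vector of spiked concentrations
#'   (µg/g, >= 0); every element needs >= 2 distinct levels, all vectors
#'   the same length. Defaults bracket the expected hepatic ranges.
#' @param replicates Independent replicate runs per level (default 1).
#' @param instrument An [instrument_model()].
#' @param matrix_baseline Named element content of the unspiked
#'   homogenate, µg/g; includes the \code{13C} carbon proxy.
#' @param width,height Standard raster size in pixels (default 32 x 8).
#'
#' @return List of records, one per level x replicate, each with fields
#'   \code{run} (a [raw_run()]), \code{known_conc} (named total µg/g),
#'   \code{level_index} and \code{replicate}.
#' @export
simulate_standards <- function(levels = DEFAULT_STANDARD_LEVELS,
                               replicates = 1L,
                               instrument = instrument_model(),
                               matrix_baseline = DEFAULT_MATRIX_BASELINE,
                               width = 32L, height = 8L) {
  if (!length(levels)) stopf("`levels` must name at least one element")
  lens <- lengths(levels)
  if (length(unique(lens)) != 1L) stopf("all level vectors must have equal length")
  n_levels <- lens[[1]]
  for (e in names(levels)) {
    if (any(levels[[e]] < 0)) stopf("negative spike level for %s", e)
    if (length(unique(levels[[e]])) < 2L) {
      stopf("element %s needs >= 2 distinct levels", e)
    }
  }
  isotopes <- intersect(instrument$isotopes,
                        union("13C", union(names(levels), names(matrix_baseline))))
  out <- list()
  for (k in seq_len(n_levels)) {
    known <- stats::setNames(vapply(isotopes, function(e) {
      base <- if (e %in% names(matrix_baseline)) matrix_baseline[[e]] else 0
      spike <- if (e %in% names(levels)) levels[[e]][k] else 0
      base + spike
    }, numeric(1)), isotopes)
    for (r in seq_len(replicates)) {
      conc <- lapply(known, function(v) matrix(v, height, width))
      ph <- phantom(conc, pixel_size_um = instrument$pixel_pitch_um,
                    preset_name = sprintf("standard_L%d_R%d", k, r))
      instr_kr <- instrument
      instr_kr$seed <- as.integer(stream_seed(instrument$seed, 300L + 17L * k + r))
      out[[length(out) + 1L]] <- list(
        run = simulate_linescans(ph, instr_kr),
        known_conc = known, level_index = k, replicate = r
      )
    }
  }
  out
}
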