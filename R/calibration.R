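#' Calibration curve
#'
#' Per-element ordinary least-squares line relating the mean
#' internal-standard ratio of each matrix-matched standard to its known
#' concentration, with IUPAC-style detection limits
#' (\code{lod = 3 * sd_blank / slope}, \code{loq = 10 * sd_blank / slope}).
#'
#' @param element Isotope label.
#' @param slope Ratio-per-(µg/g); must be > 0 for a usable curve.
#' @param intercept Ratio at zero concentration.
#' @param r_squared Coefficient of determination of the fit.
#' @param lod,loq Detection/quantification limits, µg/g (NA until
#'   [compute_lod()] has been applied).
#' @param level_table Data frame with columns \code{known_ug_g},
#'   \code{mean_ratio}, \code{sd_ratio}, \code{n_pixels}.
#' @return An object of class \code{calibration_curve}.
#' @export
calibration_curve <- function(element, slope, intercept, r_squared,
                              lod = NA_real_, loq = NA_real_,
                              level_table = NULL) {
  if (!is.finite(slope) || slope <= 0) {
    stopf("unusable calibration for %s: slope must be > 0 (got %g)",
          element, slope)
  }
  if (!is.na(lod) && !is.na(loq) && lod > loq) stopf("lod must be <= loq")
  structure(list(element = element, slope = slope, intercept = intercept,
                 r_squared = r_squared, lod = lod, loq = loq,
                 n_levels = if (is.null(level_table)) NA_integer_
                            else length(unique(level_table$known_ug_g)),
                 level_table = level_table),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4g, intercept %.4g, r2 %.5f, LOD %.3g, LOQ %.3g ug/g\n",
              x$element, x$slope, x$intercept, x$r_squared, x$lod, x$loq))
  invisible(x)
}

# Assemble + background-subtract + 13C-normalize one standard run and
# return its mean ratio over valid pixels (plus blank stats in ratio units).
standard_response <- function(run, element) {
  raw <- assemble_map(run, element)
  c13 <- assemble_map(run, "13C")
  bg <- estimate_background(run, element)
  bg13 <- estimate_background(run, "13C")
  raw <- subtract_background(raw, bg[["mean_cps"]])
  c13 <- subtract_background(c13, bg13[["mean_cps"]])
  ratio <- normalize_to_internal_standard(raw, c13)
  v <- ratio$values[is.finite(ratio$values)]
  c13_tissue <- stats::median(c13$values[is.finite(c13$values) & c13$values > 0])
  list(mean_ratio = mean(v), sd_ratio = stats::sd(v), n_pixels = length(v),
       blank_sd_ratio = bg[["sd_cps"]] / c13_tissue)
}

#' Fit a per-element calibration curve from standard runs
#'
#' Each standard run is processed through assembly, background subtraction
#' and carbon-13 normalization; its response is the mean ratio over all
#' valid pixels. The curve is the OLS line of response versus known
#' concentration with a free intercept (the unspiked homogenate anchors
#' the low end). A warning — not an error — is raised when
#' \eqn{r^2 < 0.99}. Detection limits are derived from the blank SD of the
#' lowest-concentration standard via [compute_lod()].
#'
#' @param standards List of records with fields \code{run} (a
#'   [raw_run()]) and \code{known_conc} (named µg/g vector), as returned
#'   by [simulate_standards()].
#' @param element Isotope label to calibrate (not \code{"13C"}).
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(standards, element) {
  if (identical(element, "13C")) {
    stopf("13C is the internal standard and cannot be calibrated against itself")
  }
  if (length(standards) < 2L) stopf("need >= 2 standards")
  known <- vapply(standards, function(s) {
    if (!element %in% names(s$known_conc)) {
      stopf("standard lacks a known concentration for %s", element)
    }
    s$known_conc[[element]]
  }, numeric(1))
  if (length(unique(known)) < 2L) {
    stopf("all standards have identical %s concentration; cannot fit a line",
          element)
  }
  resp <- lapply(standards, function(s) standard_response(s$run, element))
  y <- vapply(resp, `[[`, numeric(1), "mean_ratio")
  fit <- stats::lm(y ~ known)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # r^2 from the residuals directly (summary.lm warns on noiseless fits)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  if (!is.finite(slope) || slope <= 0) {
    stopf("unusable calibration for %s: fitted slope %.4g <= 0", element, slope)
  }
  if (is.finite(r2) && r2 < 0.99) {
    warning(sprintf("calibration for %s has r^2 = %.4f < 0.99", element, r2),
            call. = FALSE)
  }
  lt <- data.frame(
    known_ug_g = known,
    mean_ratio = y,
    sd_ratio = vapply(resp, `[[`, numeric(1), "sd_ratio"),
    n_pixels = vapply(resp, `[[`, numeric(1), "n_pixels")
  )
  curve <- calibration_curve(element, slope, intercept, r2, level_table = lt)
  blank_sd <- resp[[which.min(known)]]$blank_sd_ratio
  lims <- compute_lod(curve, blank_sd)
  curve$lod <- lims[["lod"]]
  curve$loq <- lims[["loq"]]
  curve
}

#' Detection and quantification limits
#'
#' IUPAC-style limits from the blank ratio SD:
#' \code{lod = 3 * blank_sd / slope}, \code{loq = 10 * blank_sd / slope}.
#'
#' @param curve A [calibration_curve()].
#' @param blank_sd_ratio SD of the blank signal in ratio-to-13C units.
#' @return Named vector \code{c(lod, loq)} in µg/g.
#' @export
compute_lod <- function(curve, blank_sd_ratio) {
  if (blank_sd_ratio < 0) stopf("blank_sd_ratio must be >= 0")
  c(lod = 3 * blank_sd_ratio / curve$slope,
    loq = 10 * blank_sd_ratio / curve$slope)
}

#' Convert a ratio map to concentrations
#'
#' Inverts the calibration line: \code{conc = (ratio - intercept) / slope}.
#' Negative results are floored at zero (count recorded in provenance);
#' pixels below the LOD keep their value but are flagged in the map's mask
#' channel.
#'
#' @param ratio_map An [element_map()] with unit \code{ratio_to_13C}.
#' @param curve The matching [calibration_curve()].
#' @return An [element_map()] in µg/g whose \code{mask} flags below-LOD
#'   pixels (\code{TRUE} = below LOD).
#' @export
apply_calibration <- function(ratio_map, curve) {
  if (ratio_map$unit != "ratio_to_13C") {
    stopf("apply_calibration expects a ratio_to_13C map, got unit '%s'",
          ratio_map$unit)
  }
  conc <- (ratio_map$values - curve$intercept) / curve$slope
  n_neg <- sum(conc < 0, na.rm = TRUE)
  conc <- pmax(conc, 0)
  below <- !is.na(conc) & !is.na(curve$lod) & conc < curve$lod
  element_map(ratio_map$element, conc, "ug_per_g", ratio_map$pixel_size_um,
              mask = below,
              provenance = c(ratio_map$provenance,
                             sprintf("calibrated slope=%g intercept=%g negatives_floored=%d",
                                     curve$slope, curve$intercept, n_neg)))
}

#' Serialize / load a calibration curve as JSON
#'
#' @param curve A [calibration_curve()].
#' @param path JSON file path.
#' @return \code{write_calibration} invisibly returns \code{path};
#'   \code{read_calibration} returns a [calibration_curve()].
#' @export
write_calibration <- function(curve, path) {
  jsonlite::write_json(
    list(element = curve$element, slope = curve$slope,
         intercept = curve$intercept, r_squared = curve$r_squared,
         lod = curve$lod, loq = curve$loq, n_levels = curve$n_levels,
         level_table = curve$level_table),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lt <- if (!is.null(x$level_table)) as.data.frame(x$level_table) else NULL
  calibration_curve(x$element, x$slope, x$intercept, x$r_squared,
                    lod = if (is.null(x$lod)) NA_real_ else x$lod,
                    loq = if (is.null(x$loq)) NA_real_ else x$loq,
                    level_table = lt)
}
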