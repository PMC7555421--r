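#' Assemble a 2-D intensity map from a line-scan run
#'
#' Pure reshape of the time series: one map row per ablation line (ordered
#' by the laser log's \code{y_um}), one pixel per laser-on cycle, no
#' resampling or smoothing. Lines with fewer laser-on cycles than the
#' longest are right-padded with \code{NA}. The along-scan pixel size is
#' \code{scan_speed * cycle_time}.
#'
#' @param run A [raw_run()].
#' @param isotope Isotope label present in the run.
#' @return An [element_map()] in cps.
#' @export
assemble_map <- function(run, isotope) {
  if (!inherits(run, "raw_run")) stopf("`run` must be a raw_run")
  if (!isotope %in% run$isotopes) {
    stopf("isotope %s not present in run (has: %s)", isotope,
          paste(run$isotopes, collapse = ", "))
  }
  ord <- order(run$laser_log$y_um)
  widths <- run$laser_log$laser_off_cycle - run$laser_log$laser_on_cycle
  if (any(widths < 1L)) stopf("line %d has zero laser-on cycles",
                              run$laser_log$line_index[which(widths < 1L)[1]])
  w <- max(widths)
  values <- matrix(NA_real_, length(ord), w)
  for (r in seq_along(ord)) {
    i <- ord[r]
    on <- run$laser_log$laser_on_cycle[i]
    off <- run$laser_log$laser_off_cycle[i]
    seg <- run$lines[[i]][[isotope]][(on + 1L):off]   # 0-based log -> R index
    values[r, seq_along(seg)] <- seg
  }
  pitch <- run$laser_log$scan_speed_um_s[1] * run$cycle_time_s
  spacing <- if (length(ord) > 1) diff(sort(run$laser_log$y_um))[1] else pitch
  element_map(isotope, values, "cps", pitch,
              provenance = sprintf("assembled from %d lines; line_spacing_um=%g",
                                   length(ord), spacing))
}

#' Estimate the gas-blank background from laser-off cycles
#'
#' Pools every laser-off cycle of every line and returns the sample mean
#' and SD (n-1 denominator) of the isotope's intensity.
#'
#' @param run A [raw_run()].
#' @param isotope Isotope label.
#' @return Named numeric vector \code{c(mean_cps, sd_cps)}.
#' @export
estimate_background <- function(run, isotope) {
  if (!isotope %in% run$isotopes) stopf("isotope %s not present in run", isotope)
  blanks <- unlist(lapply(seq_along(run$lines), function(i) {
    df <- run$lines[[i]]
    on <- run$laser_log$laser_on_cycle[i]
    off <- run$laser_log$laser_off_cycle[i]
    keep <- df$cycle_index < on | df$cycle_index >= off
    df[[isotope]][keep]
  }))
  if (length(blanks) < 3L) {
    stopf(paste0("only %d laser-off cycles available; background estimation ",
                 "needs >= 3 - acquire longer blank segments"), length(blanks))
  }
  c(mean_cps = mean(blanks), sd_cps = stats::sd(blanks))
}

#' Subtract a constant background from an intensity map
#'
#' Values are floored at zero; the number of clipped pixels is recorded in
#' the map provenance.
#'
#' @param map An [element_map()] in cps.
#' @param background_mean Background level, cps.
#' @return The background-subtracted [element_map()].
#' @export
subtract_background <- function(map, background_mean) {
  if (map$unit != "cps") stopf("background subtraction expects a cps map")
  shifted <- map$values - background_mean
  clipped <- sum(shifted < 0, na.rm = TRUE)
  map$values <- pmax(shifted, 0)
  map$provenance <- c(map$provenance,
                      sprintf("background_subtracted mean=%g clipped=%d",
                              background_mean, clipped))
  map
}

#' Normalize an analyte map to the carbon-13 internal standard
#'
#' Pixelwise ratio analyte / 13C. Carbon ratios out drift in ablation
#' yield and instrument sensitivity that is shared across isotopes. Pixels
#' whose 13C signal falls below a guard threshold (5% of the 13C tissue
#' median) become \code{NA}; their count is recorded in the provenance.
#'
#' @param analyte,c13 Background-subtracted [element_map()]s in cps with
#'   identical shape.
#' @return An [element_map()] with unit \code{ratio_to_13C}.
#' @export
normalize_to_internal_standard <- function(analyte, c13) {
  if (analyte$unit != "cps" || c13$unit != "cps") {
    stopf("normalization expects background-subtracted cps maps")
  }
  if (!identical(dim(analyte$values), dim(c13$values))) {
    stopf("shape mismatch: analyte %s vs 13C %s",
          paste(dim(analyte$values), collapse = "x"),
          paste(dim(c13$values), collapse = "x"))
  }
  eps <- c13_guard_threshold(c13$values)
  low <- !is.na(c13$values) & c13$values < eps
  ratio <- analyte$values / c13$values
  ratio[low] <- NA_real_
  out <- element_map(analyte$element, ratio, "ratio_to_13C",
                     analyte$pixel_size_um,
                     provenance = c(analyte$provenance,
                                    sprintf("normalized_to_13C eps=%g low_c13=%d",
                                            eps, sum(low))))
  out
}

# Guard threshold for the 13C denominator: 5% of the 13C tissue median,
# where "tissue" is approximated as pixels above 5% of the map maximum
# (relative, so it scales with instrument sensitivity).
c13_guard_threshold <- function(c13_values) {
  v <- c13_values[!is.na(c13_values)]
  if (!length(v)) return(Inf)
  tissue <- v[v > 0.05 * max(v)]
  if (!length(tissue)) tissue <- v
  0.05 * stats::median(tissue)
}
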