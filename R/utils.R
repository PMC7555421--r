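#' Canonical isotope labels
#'
#' The isotope menu acquired per measurement cycle, in acquisition order.
#' \code{13C} is the internal standard.
#'
#' @return Character vector of isotope labels.
#' @export
elamap_isotopes <- function() {
  c("13C", "23Na", "24Mg", "44Ca", "55Mn", "56Fe", "63Cu", "64Zn")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stream seed derivation. Stream indices are fixed by the
# canonical isotope order (mask = 0) so adding isotopes later cannot
# reshuffle existing streams.
stream_seed <- function(seed, stream) {
  (as.numeric(seed) + 7919 * stream) %% 2147483647
}

stream_index <- function(isotope) {
  match(isotope, elamap_isotopes())
}

#' Inspect the package's default constants
#'
#' Collects every default the simulation and quantification stages rely on
#' — tissue baselines, instrument sensitivity and background, the
#' homogenate matrix baseline, standard spike levels, and the wet-to-dry
#' conversion — so they can be inspected (and overridden) in one place.
#'
#' @return Named list of default constant sets.
#' @export
elamap_defaults <- function() {
  list(
    tissue_baselines_ug_g = DEFAULT_BASELINES,
    sensitivity_cps_per_ug_g = DEFAULT_SENSITIVITY,
    background_cps = DEFAULT_BACKGROUND,
    matrix_baseline_ug_g = DEFAULT_MATRIX_BASELINE,
    standard_levels_ug_g = DEFAULT_STANDARD_LEVELS,
    wet_to_dry_factor = 3.3,
    diagnostic_threshold_ug_g_dry = 250,
    cu_reference_wt_ug_g = CU_REFERENCE_WT
  )
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stopf("`%s` must be a single finite number >= %s", name, min)
  }
  invisible(x)
}
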