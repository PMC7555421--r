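#' Construct a phantom from explicit concentration grids
#'
#' Low-level constructor for a ground-truth section phantom. Most users
#' should call [make_phantom()]; this constructor exists for hand-built
#' grids (e.g. tiny deterministic fixtures).
#'
#' @param conc Named list of numeric matrices (rows = lines along y,
#'   columns = along-scan pixels), one per isotope label, all the same
#'   shape, all values >= 0.
#' @param pixel_size_um Pixel pitch in µm (square pixels).
#' @param tissue_mask Logical matrix of the same shape; default all
#'   \code{TRUE}. Concentrations must be 0 outside the mask.
#' @param section_thickness_um Cryosection thickness in µm (default 30).
#' @param preset_name,seed Optional provenance fields.
#'
#' @return An object of class \code{phantom}.
#' @export
phantom <- function(conc, pixel_size_um, tissue_mask = NULL,
                    section_thickness_um = 30, preset_name = NA_character_,
                    seed = NA_integer_) {
  if (!is.list(conc) || is.null(names(conc)) || any(!nzchar(names(conc)))) {
    stopf("`conc` must be a named list of matrices")
  }
  dims <- unique(lapply(conc, dim))
  if (length(dims) != 1L || is.null(dims[[1]])) {
    stopf("all concentration grids must be matrices of identical shape")
  }
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (h < 1L || w < 1L) stopf("phantom grid is empty")
  assert_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, h, w)
  if (!is.logical(tissue_mask) || !identical(dim(tissue_mask), c(h, w))) {
    stopf("`tissue_mask` must be a logical matrix matching the grids")
  }
  for (e in names(conc)) {
    if (any(conc[[e]] < 0)) stopf("negative concentration in element %s", e)
    if (any(conc[[e]][!tissue_mask] != 0)) {
      stopf("element %s has nonzero concentration outside the tissue mask", e)
    }
  }
  structure(list(
    width = w, height = h,
    pixel_size_um = pixel_size_um,
    section_thickness_um = section_thickness_um,
    tissue_mask = tissue_mask,
    conc = conc,
    preset_name = preset_name,
    seed = seed
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d px @ %.3g um, %d elements (%s), preset %s\n",
              x$width, x$height, x$pixel_size_um, length(x$conc),
              paste(names(x$conc), collapse = ","), x$preset_name))
  invisible(x)
}

# Mean-zero, unit-SD stationary smooth random field via periodic Gaussian
# smoothing of white noise (FFT convolution; deterministic given RNG state).
smooth_field <- function(height, width, sigma) {
  noise <- matrix(stats::rnorm(height * width), height, width)
  if (sigma <= 0) return(noise)
  dy <- pmin(0:(height - 1), height - (0:(height - 1)))
  dx <- pmin(0:(width - 1), width - (0:(width - 1)))
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    (height * width)
  s <- stats::sd(f)
  if (s < 1e-12) return(matrix(0, height, width))
  (f - mean(f)) / s
}

# Multiplicative between-pixel heterogeneity field: mean 1, coefficient of
# variation `cv`, floored well above zero.
noise_field <- function(height, width, cv) {
  if (cv <= 0) return(matrix(1, height, width))
  pmax(1 + cv * smooth_field(height, width, sigma = 1.5), 0.05)
}

# Single connected, roughly elliptical tissue blob with a randomly
# perturbed boundary (low-order harmonic modulation keeps it star-shaped,
# hence connected).
rough_ellipse_mask <- function(height, width) {
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  amp <- stats::runif(2, 0.02, 0.06)
  phase <- stats::runif(2, 0, 2 * pi)
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), times = width), height, width)
  ex <- (x - cx) / (0.44 * width)
  ey <- (y - cy) / (0.44 * height)
  theta <- atan2(ey, ex)
  rmod <- 1 + amp[1] * cos(2 * theta + phase[1]) +
    amp[2] * cos(3 * theta + phase[2])
  sqrt(ex^2 + ey^2) <= rmod
}

# Pixels within `halfwidth_px` of the edges of a hexagonal tiling with the
# given pitch. Hexagons arise as Voronoi cells of a triangular lattice of
# centers; proximity to a cell edge is (d2 - d1)/2 where d1, d2 are the two
# smallest distances to lattice centers.
hex_rim_mask <- function(height, width, pitch_px, halfwidth_px) {
  row_h <- pitch_px * sqrt(3) / 2
  cxs <- seq(-pitch_px, width + pitch_px, by = pitch_px)
  cys <- seq(-row_h, height + row_h, by = row_h)
  centers <- do.call(rbind, lapply(seq_along(cys), function(i) {
    off <- if (i %% 2 == 0) pitch_px / 2 else 0
    cbind(cxs + off, cys[i])
  }))
  px <- rep(seq_len(width) - 0.5, each = height)
  py <- rep(seq_len(height) - 0.5, times = width)
  d2mat <- outer(px, centers[, 1], "-")^2 + outer(py, centers[, 2], "-")^2
  near2 <- t(apply(d2mat, 1L, function(d) sqrt(sort.int(d, partial = 2)[1:2])))
  rim <- (near2[, 2] - near2[, 1]) / 2 < halfwidth_px
  matrix(rim, height, width)
}

#' Generate a ground-truth liver-section phantom
#'
#' Builds per-element concentration grids with the spatial texture seen in
#' LA-ICP-MS liver images: copper relatively homogeneous (a smooth random
#' field with the preset mean and between-pixel SD, rescaled so the
#' tissue-mask mean matches the preset mean exactly), iron elevated along
#' the rims of a hexagonal lobule tiling, manganese in irregular
#' low-frequency zones, magnesium negatively coupled to copper, zinc scaled
#' by the preset factor, and sodium/calcium/carbon at baseline. All fields
#' are zero outside the single connected tissue blob.
#'
#' @param preset A [phantom_preset()] or a preset name.
#' @param width,height Grid size in pixels (>= 8 each).
#' @param pixel_size_um Pixel pitch in µm; the default 9.9 matches the
#'   default instrument (55 µm/s scan speed x 0.18 s cycle).
#' @param seed Integer seed; all element fields draw from named
#'   sub-streams so the phantom is fully reproducible.
#' @param hex_pitch_um Lobule (hexagon) pitch in µm (default 250).
#' @param rim_width_um Full width of the iron-enriched rim in µm
#'   (default 30).
#'
#' @return A [phantom()] whose \code{fe_rim_mask} field marks the
#'   rim pixels used for the iron texture (within the tissue mask).
#'
#' @examples
#' ph <- make_phantom("wildtype_9wk", 32, 32, seed = 1, hex_pitch_um = 120)
#' mean(ph$conc[["63Cu"]][ph$tissue_mask])
#' @export
make_phantom <- function(preset, width, height, pixel_size_um = 9.9,
                         seed = 1L, hex_pitch_um = 250, rim_width_um = 30) {
  if (is.character(preset)) preset <- phantom_preset(preset)
  if (!inherits(preset, "phantom_preset")) {
    stopf("`preset` must be a phantom_preset or preset name")
  }
  if (width < 8L || height < 8L) stopf("grid must be at least 8x8 pixels")
  assert_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  pitch_px <- hex_pitch_um / pixel_size_um
  if (pitch_px > min(width, height)) {
    stopf(paste0("grid (%dx%d px @ %.3g um) is too small to contain one ",
                 "hexagonal lobule of pitch %.3g um; enlarge the grid or ",
                 "reduce `hex_pitch_um`"),
          width, height, pixel_size_um, hex_pitch_um)
  }
  bl <- preset$baselines
  cv <- preset$pixel_cv

  mask <- with_seed(stream_seed(seed, 0L), rough_ellipse_mask(height, width))
  rim <- with_seed(stream_seed(seed, 100L),
                   hex_rim_mask(height, width, pitch_px,
                                (rim_width_um / 2) / pixel_size_um))

  field <- function(iso, expr) with_seed(stream_seed(seed, stream_index(iso)), expr)

  # Copper: smooth homogeneous field, exact tissue mean.
  cu <- field("63Cu", preset$cu_mean +
                preset$cu_sd_between_pixels * smooth_field(height, width, 3))
  cu <- pmax(cu, 0)
  cu <- cu * (preset$cu_mean / mean(cu[mask]))

  # Magnesium: baseline plus negative coupling to copper (relative to the
  # wild-type reference level), with its own mild heterogeneity.
  mg <- field("24Mg", (bl[["24Mg"]] +
                         preset$mg_coupling * (cu - CU_REFERENCE_WT)) *
                noise_field(height, width, cv))
  mg <- pmax(mg, 0)

  fe <- field("56Fe", bl[["56Fe"]] *
                (1 + (preset$fe_rim_contrast - 1) * rim) *
                noise_field(height, width, cv))

  amp <- (preset$mn_zonal_contrast - 1) / (preset$mn_zonal_contrast + 1)
  mn <- field("55Mn", {
    z <- smooth_field(height, width, 8)
    zmax <- max(abs(z)); if (zmax < 1e-12) zmax <- 1
    bl[["55Mn"]] * (1 + amp * z / zmax) * noise_field(height, width, cv)
  })

  zn <- field("64Zn", bl[["64Zn"]] * preset$zn_scale * noise_field(height, width, cv))
  na <- field("23Na", bl[["23Na"]] * noise_field(height, width, cv))
  ca <- field("44Ca", bl[["44Ca"]] * noise_field(height, width, cv))
  # Carbon proxy: near-uniform by assumption (internal standard).
  c13 <- field("13C", bl[["13C"]] * noise_field(height, width, 0.2 * cv))

  conc <- list("13C" = c13, "23Na" = na, "24Mg" = mg, "44Ca" = ca,
               "55Mn" = mn, "56Fe" = fe, "63Cu" = cu, "64Zn" = zn)
  conc <- lapply(conc, function(m) { m[!mask] <- 0; pmax(m, 0) })

  # Flooring at 0 cannot move the Cu mean here (fields are far from 0), but
  # re-force exactness so the invariant is unconditional.
  sc <- preset$cu_mean / mean(conc[["63Cu"]][mask])
  conc[["63Cu"]][mask] <- conc[["63Cu"]][mask] * sc

  ph <- phantom(conc, pixel_size_um, tissue_mask = mask,
                preset_name = preset$name, seed = as.integer(seed))
  ph$fe_rim_mask <- rim & mask
  ph$hex_pitch_um <- hex_pitch_um
  ph$rim_width_um <- rim_width_um
  ph
}

#' Write a phantom's ground truth to disk
#'
#' Writes one map-grid file per element (see [write_map()]) plus a JSON
#' sidecar with preset name, seed, pixel size and section thickness, and the
#' tissue mask as a 0/1 grid.
#'
#' @param ph A [phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in names(ph$conc)) {
    m <- element_map(e, ph$conc[[e]], "ug_per_g", ph$pixel_size_um,
                     provenance = sprintf("phantom preset=%s seed=%s",
                                          ph$preset_name, ph$seed))
    write_map(m, file.path(dir, paste0(gsub("[^0-9A-Za-z]", "", e), "_truth.map")))
  }
  mask_map <- element_map("tissue_mask", ph$tissue_mask * 1, "cps",
                          ph$pixel_size_um, provenance = "0/1 tissue mask")
  write_map(mask_map, file.path(dir, "tissue_mask.map"))
  jsonlite::write_json(
    list(preset = ph$preset_name, seed = ph$seed,
         pixel_size_um = ph$pixel_size_um,
         section_thickness_um = ph$section_thickness_um,
         width = ph$width, height = ph$height),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
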