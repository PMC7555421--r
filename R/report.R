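#' Segment the tissue from the carbon-13 map
#'
#' Tissue delineation uses the internal-standard channel, never the
#' analyte: Otsu's threshold on the 13C intensity histogram, then the
#' largest connected component, with holes filled.
#'
#' @param c13_map An [element_map()] of 13C (any cps-like scale).
#' @return Logical matrix: \code{TRUE} on tissue.
#' @export
segment_tissue <- function(c13_map) {
  v <- c13_map$values
  finite <- is.finite(v)
  if (!any(finite)) stopf("no tissue detected: 13C map is empty")
  rng <- range(v[finite])
  if (diff(rng) < 1e-12) {
    stopf("no tissue detected: 13C map is uniform (no tissue/background contrast)")
  }
  norm <- (v - rng[1]) / diff(rng)
  norm[!finite] <- 0
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  if (!any(mask)) stopf("no tissue detected: nothing above the Otsu threshold")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  matrix(as.logical(mask), nrow(v), ncol(v))
}

#' Summarize a concentration map over a tissue mask
#'
#' Statistics are computed over masked, non-\code{NA} pixels only; the SD
#' uses the n-1 denominator and quantiles are the 5th/95th percentiles.
#'
#' @param conc_map An [element_map()] in µg/g (its \code{mask} channel, if
#'   present, flags below-LOD pixels).
#' @param mask Logical tissue mask.
#' @return Named list: \code{mean}, \code{sd}, \code{median}, \code{p5},
#'   \code{p95}, \code{n}, \code{below_lod_fraction}.
#' @export
summarize_map <- function(conc_map, mask) {
  sel <- mask & !is.na(conc_map$values)
  v <- conc_map$values[sel]
  if (!length(v)) stopf("no valid pixels for %s inside the mask", conc_map$element)
  q <- unname(stats::quantile(v, c(0.05, 0.5, 0.95), type = 7))
  blf <- if (is.null(conc_map$mask)) NA_real_ else mean(conc_map$mask[sel])
  list(mean = mean(v), sd = stats::sd(v), median = q[2], p5 = q[1], p95 = q[3],
       n = length(v), below_lod_fraction = blf)
}

#' Hepatic copper diagnostic rule
#'
#' Wilson-disease work-ups flag livers whose copper content exceeds
#' 250 µg/g \emph{dry} weight. LA-ICP-MS sections are measured wet, so the
#' rule takes an explicit wet-to-dry conversion factor (default 3.3, a
#' documented convention: liver is roughly 70% water) and never converts
#' silently.
#'
#' @param mean_cu_wet Tissue-mean copper, µg/g wet tissue.
#' @param wet_to_dry_factor Multiplicative wet-to-dry factor.
#' @param threshold_ug_g_dry Decision threshold, µg/g dry weight.
#' @return \code{TRUE} when \code{mean_cu_wet * wet_to_dry_factor}
#'   exceeds the threshold.
#' @examples
#' diagnostic_flag(2.09)           # wild-type level: FALSE
#' diagnostic_flag(112.72)         # knockout level: TRUE
#' @export
diagnostic_flag <- function(mean_cu_wet, wet_to_dry_factor = 3.3,
                            threshold_ug_g_dry = 250) {
  assert_scalar_number(mean_cu_wet, "mean_cu_wet", min = 0)
  (mean_cu_wet * wet_to_dry_factor) > threshold_ug_g_dry
}

#' Per-section quantification report
#'
#' Bundles tissue-masked summary statistics for every calibrated element,
#' pixelwise Pearson correlations between copper and each other element
#' (the spatial co-variation behind the Cu/Mg/Zn findings), the hepatic
#' copper diagnostic, and the list of channels skipped with reasons.
#'
#' @param conc_maps Named list of [element_map()]s in µg/g.
#' @param mask Logical tissue mask.
#' @param skipped Named character vector of channel -> reason.
#' @param name Section label.
#' @param wet_to_dry_factor,threshold_ug_g_dry See [diagnostic_flag()].
#' @return An object of class \code{section_report}.
#' @export
section_report <- function(conc_maps, mask, skipped = character(),
                           name = NA_character_, wet_to_dry_factor = 3.3,
                           threshold_ug_g_dry = 250) {
  stats_list <- lapply(conc_maps, summarize_map, mask = mask)
  elements <- do.call(rbind, lapply(names(stats_list), function(e) {
    s <- stats_list[[e]]
    data.frame(element = e, mean = s$mean, sd = s$sd, median = s$median,
               p5 = s$p5, p95 = s$p95, n = s$n,
               below_lod_fraction = s$below_lod_fraction)
  }))
  if (!is.null(elements)) {
    stopifnot(all(elements$p5 <= elements$median + 1e-12),
              all(elements$median <= elements$p95 + 1e-12))
  }
  cu_cor <- NULL
  if ("63Cu" %in% names(conc_maps)) {
    cu_v <- conc_maps[["63Cu"]]$values
    others <- setdiff(names(conc_maps), "63Cu")
    cu_cor <- stats::setNames(vapply(others, function(e) {
      v <- conc_maps[[e]]$values
      sel <- mask & !is.na(cu_v) & !is.na(v)
      if (sum(sel) < 3 || stats::sd(v[sel]) == 0 || stats::sd(cu_v[sel]) == 0) {
        return(NA_real_)
      }
      stats::cor(cu_v[sel], v[sel])
    }, numeric(1)), others)
  }
  diag <- NULL
  if ("63Cu" %in% names(conc_maps)) {
    cu_mean <- stats_list[["63Cu"]]$mean
    diag <- list(flag = diagnostic_flag(cu_mean, wet_to_dry_factor,
                                        threshold_ug_g_dry),
                 mean_cu_wet_ug_g = cu_mean,
                 mean_cu_dry_equivalent_ug_g = cu_mean * wet_to_dry_factor,
                 threshold_ug_g_dry = threshold_ug_g_dry,
                 wet_to_dry_factor = wet_to_dry_factor)
  }
  structure(list(
    name = name,
    elements = elements,
    tissue_pixel_count = sum(mask),
    pixel_size_um = if (length(conc_maps)) conc_maps[[1]]$pixel_size_um else NA_real_,
    cu_correlations = cu_cor,
    diagnostic = diag,
    skipped = skipped
  ), class = "section_report")
}

#' @export
print.section_report <- function(x, ...) {
  cat(sprintf("<section_report> %s: %d tissue px @ %.3g um\n",
              x$name, x$tissue_pixel_count, x$pixel_size_um))
  df <- x$elements
  df[-1] <- lapply(df[-1], signif, digits = 4)
  print(df, row.names = FALSE)
  if (!is.null(x$diagnostic)) {
    cat(sprintf("Cu: %.4g ug/g wet (~%.4g ug/g dry at factor %.2g) -> %s (threshold %g ug/g dry)\n",
                x$diagnostic$mean_cu_wet_ug_g,
                x$diagnostic$mean_cu_dry_equivalent_ug_g,
                x$diagnostic$wet_to_dry_factor,
                if (x$diagnostic$flag) "COPPER OVERLOAD" else "within normal range",
                x$diagnostic$threshold_ug_g_dry))
  }
  if (length(x$skipped)) {
    cat("skipped:", paste(sprintf("%s (%s)", names(x$skipped), x$skipped),
                          collapse = "; "), "\n")
  }
  invisible(x)
}

#' Compare two groups of section reports
#'
#' Descriptive comparison (no inferential statistics): per element, the
#' group means of the section means, their fold change (group B over
#' group A) and difference, plus the group-averaged within-section
#' Cu-to-element pixel correlations.
#'
#' @param reports_a,reports_b Lists of [section_report()]s.
#' @param label_a,label_b Group labels.
#' @return An object of class \code{group_comparison}: list with a
#'   per-element data frame (\code{mean_a}, \code{mean_b},
#'   \code{fold_change_b_over_a}, \code{difference_b_minus_a}) and the
#'   averaged Cu correlations per group.
#' @export
compare_groups <- function(reports_a, reports_b, label_a = "A", label_b = "B") {
  if (inherits(reports_a, "section_report")) reports_a <- list(reports_a)
  if (inherits(reports_b, "section_report")) reports_b <- list(reports_b)
  group_means <- function(reports) {
    tabs <- lapply(reports, function(r) r$elements[, c("element", "mean")])
    agg <- stats::aggregate(mean ~ element, data = do.call(rbind, tabs), FUN = mean)
    stats::setNames(agg$mean, agg$element)
  }
  ma <- group_means(reports_a); mb <- group_means(reports_b)
  common <- intersect(names(ma), names(mb))
  tab <- data.frame(
    element = common,
    mean_a = unname(ma[common]),
    mean_b = unname(mb[common]),
    fold_change_b_over_a = unname(mb[common] / ma[common]),
    difference_b_minus_a = unname(mb[common] - ma[common])
  )
  group_cors <- function(reports) {
    mats <- lapply(reports, function(r) r$cu_correlations)
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (!length(mats)) return(NULL)
    els <- Reduce(intersect, lapply(mats, names))
    stats::setNames(vapply(els, function(e) {
      mean(vapply(mats, `[[`, numeric(1), e), na.rm = TRUE)
    }, numeric(1)), els)
  }
  structure(list(labels = c(label_a, label_b), table = tab,
                 cu_correlations_a = group_cors(reports_a),
                 cu_correlations_b = group_cors(reports_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  df <- x$table
  df[-1] <- lapply(df[-1], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

DEFAULT_ELEMENT_HUES <- c(
  "13C" = "#AAAAAA", "23Na" = "#4477AA", "24Mg" = "#66CCEE",
  "44Ca" = "#FFFFFF", "55Mn" = "#AA3377", "56Fe" = "#EE6677",
  "63Cu" = "#CCBB44", "64Zn" = "#228833"
)

#' Render a false-color element map
#'
#' Writes a PNG with a single-hue sequential palette (black through the
#' element hue to white), scaled linearly from 0 to the masked 99th
#' percentile by default (values above the upper limit are clipped). A
#' vertical color bar is embedded on the right edge, and a JSON legend
#' sidecar (\code{<path>.legend.json}) documents the limits, unit and
#' clip count. \code{NA} pixels and, if a mask is given, off-tissue pixels
#' render in a reserved neutral gray. Output bytes are deterministic for
#' fixed input and configuration.
#'
#' @param map An [element_map()].
#' @param path Output PNG path.
#' @param mask Optional logical tissue mask.
#' @param limits Length-2 numeric color limits; default
#'   \code{c(0, p99)} computed over masked finite values.
#' @param hue Peak hue (defaults to a per-element choice).
#' @param scale Integer pixel magnification (default 4).
#' @return Invisibly, a list with \code{path}, \code{limits} and
#'   \code{n_clipped}.
#' @export
render_map <- function(map, path, mask = NULL, limits = NULL, hue = NULL,
                       scale = 4L) {
  v <- map$values
  sel <- if (is.null(mask)) is.finite(v) else (mask & is.finite(v))
  if (!any(sel)) stopf("nothing to render: no finite pixels selected")
  if (is.null(limits)) {
    hi <- unname(stats::quantile(v[sel], 0.99, type = 7))
    if (hi <= 0) hi <- max(v[sel], 1e-12)
    limits <- c(0, hi)
  }
  if (is.null(hue)) {
    hue <- if (map$element %in% names(DEFAULT_ELEMENT_HUES)) {
      DEFAULT_ELEMENT_HUES[[map$element]]
    } else "#CCBB44"
  }
  pal <- grDevices::colorRampPalette(c("#000000", hue, "#FFFFFF"))(256)
  rgb_pal <- grDevices::col2rgb(pal) / 255
  neutral <- c(0.5, 0.5, 0.5)

  norm <- (v - limits[1]) / (limits[2] - limits[1])
  n_clipped <- sum(norm > 1, na.rm = TRUE)
  norm <- pmin(pmax(norm, 0), 1)
  idx <- 1L + as.integer(round(norm * 255))
  h <- nrow(v); w <- ncol(v)
  img <- array(0, c(h, w, 3))
  use <- is.finite(v) & (if (is.null(mask)) TRUE else mask)
  for (ch in 1:3) {
    chan <- matrix(neutral[ch], h, w)
    chan[use] <- rgb_pal[ch, idx[use]]
    img[, , ch] <- chan
  }
  # color bar strip: 1-px separator + 3-px gradient column, top = max
  bar_idx <- rev(as.integer(round(seq(1, 256, length.out = h))))
  strip <- array(0, c(h, 4, 3))
  for (ch in 1:3) {
    strip[, 1, ch] <- neutral[ch]
    strip[, 2:4, ch] <- matrix(rgb_pal[ch, bar_idx], h, 3)
  }
  full <- array(0, c(h, w + 4, 3))
  full[, 1:w, ] <- img
  full[, (w + 1):(w + 4), ] <- strip
  if (scale > 1L) {
    full <- full[rep(seq_len(nrow(full)), each = scale),
                 rep(seq_len(ncol(full)), each = scale), , drop = FALSE]
  }
  png::writePNG(full, path)
  jsonlite::write_json(
    list(element = map$element, unit = map$unit, limits = limits,
         n_clipped = n_clipped, hue = hue,
         note = "linear scale; values above the upper limit are clipped; gray = missing/off-tissue"),
    paste0(path, ".legend.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(path = path, limits = limits, n_clipped = n_clipped))
}
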