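#' Time-resolved raw run
#'
#' Container for an ordered set of ablation-line time series plus the laser
#' log that situates each line on the section. Cycle indices are 0-based;
#' \code{laser_on_cycle} is inclusive and \code{laser_off_cycle} exclusive,
#' so the laser-on cycles of a line are those with
#' \code{laser_on_cycle <= cycle_index < laser_off_cycle}.
#'
#' @param lines List of data frames, one per line, with columns
#'   \code{cycle_index}, \code{time_s} and one intensity column (cps) per
#'   isotope, identical isotope sets in identical order across lines.
#' @param isotopes Isotope labels in acquisition order.
#' @param cycle_time_s Seconds per full isotope sweep.
#' @param laser_log Data frame with columns \code{line_index},
#'   \code{y_um}, \code{start_time_s}, \code{laser_on_cycle},
#'   \code{laser_off_cycle}, \code{scan_speed_um_s}; one row per line.
#' @param acquisition_start Optional timestamp string.
#'
#' @return An object of class \code{raw_run}.
#' @export
raw_run <- function(lines, isotopes, cycle_time_s, laser_log,
                    acquisition_start = NULL) {
  if (!length(lines)) stopf("a raw run needs at least one line")
  log_cols <- c("line_index", "y_um", "start_time_s", "laser_on_cycle",
                "laser_off_cycle", "scan_speed_um_s")
  if (is.null(laser_log) || !all(log_cols %in% names(laser_log))) {
    stopf("laser log is missing or lacks columns: %s",
          paste(setdiff(log_cols, names(laser_log)), collapse = ", "))
  }
  if (nrow(laser_log) != length(lines)) {
    stopf("laser log has %d rows but the run has %d lines",
          nrow(laser_log), length(lines))
  }
  for (i in seq_along(lines)) {
    df <- lines[[i]]
    missing_iso <- setdiff(isotopes, names(df))
    extra_iso <- setdiff(setdiff(names(df), c("cycle_index", "time_s")), isotopes)
    if (length(missing_iso) || length(extra_iso)) {
      stopf("line %d has a ragged isotope set (missing: %s; extra: %s)",
            i - 1L, paste(missing_iso, collapse = ","),
            paste(extra_iso, collapse = ","))
    }
    for (e in isotopes) {
      neg <- which(df[[e]] < 0)
      if (length(neg)) {
        stopf("negative intensity for %s in line %d at cycle %d",
              e, i - 1L, df$cycle_index[neg[1]])
      }
    }
    on <- laser_log$laser_on_cycle[i]; off <- laser_log$laser_off_cycle[i]
    if (!(on < off)) stopf("line %d: laser_on_cycle must be < laser_off_cycle", i - 1L)
    if (off > nrow(df)) {
      stopf("line %d: laser_off_cycle = %d exceeds the %d cycles recorded",
            i - 1L, off, nrow(df))
    }
  }
  structure(list(
    lines = lines, isotopes = isotopes, cycle_time_s = cycle_time_s,
    laser_log = laser_log, acquisition_start = acquisition_start
  ), class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("<raw_run> %d lines x <=%d cycles, isotopes: %s\n",
              length(x$lines), max(vapply(x$lines, nrow, integer(1))),
              paste(x$isotopes, collapse = ",")))
  invisible(x)
}

#' Write / read a raw run directory
#'
#' On-disk dialect: one \code{line_NNN.csv} per ablation line (columns
#' \code{cycle_index}, \code{time_s}, then one column per isotope, comma
#' separated, "." decimal, UTF-8), a \code{laser_log.csv}, and a
#' \code{run.json} sidecar carrying the cycle time and isotope order. Round
#' trips are lossless at full double precision.
#'
#' @param run A [raw_run()].
#' @param path Run directory (created by \code{write_run}).
#' @return \code{write_run} invisibly returns \code{path}; \code{read_run}
#'   returns a validated [raw_run()].
#' @export
write_run <- function(run, path) {
  if (!inherits(run, "raw_run")) stopf("`run` must be a raw_run")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(run$lines)) {
    utils::write.csv(format_full(run$lines[[i]]),
                     file.path(path, sprintf("line_%03d.csv", i - 1L)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(format_full(run$laser_log),
                   file.path(path, "laser_log.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(cycle_time_s = run$cycle_time_s, isotopes = run$isotopes,
               n_lines = length(run$lines))
  if (!is.null(run$acquisition_start)) meta$acquisition_start <- run$acquisition_start
  jsonlite::write_json(meta, file.path(path, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Serialize doubles via their shortest exact decimal representation.
format_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g") else col
  })
  df
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  if (!dir.exists(path)) stopf("run directory not found: %s", path)
  log_path <- file.path(path, "laser_log.csv")
  if (!file.exists(log_path)) stopf("missing laser log: %s", log_path)
  laser_log <- utils::read.csv(log_path, check.names = FALSE)
  line_files <- sort(list.files(path, pattern = "^line_[0-9]+\\.csv$",
                                full.names = TRUE))
  if (!length(line_files)) stopf("no line_NNN.csv files in %s", path)
  lines <- lapply(line_files, utils::read.csv, check.names = FALSE)
  meta_path <- file.path(path, "run.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    isotopes <- meta$isotopes
    cycle_time <- meta$cycle_time_s
    acq <- meta$acquisition_start
  } else {
    isotopes <- setdiff(names(lines[[1]]), c("cycle_index", "time_s"))
    ts <- lines[[1]]$time_s
    cycle_time <- if (length(ts) > 1) ts[2] - ts[1] else NA_real_
    acq <- NULL
  }
  raw_run(lines, isotopes, cycle_time_s = cycle_time, laser_log = laser_log,
          acquisition_start = acq)
}

MAP_UNITS <- c("cps", "ratio_to_13C", "ug_per_g")

#' 2-D element map
#'
#' A rectangular per-isotope pixel grid with a declared unit — raw
#' intensities (\code{cps}), internal-standard ratios
#' (\code{ratio_to_13C}), or calibrated concentrations (\code{ug_per_g}).
#' Grids are row-major with the origin top-left: rows are ablation lines
#' (y increases downward), columns follow the scan direction. \code{NA}
#' marks pixels invalidated downstream (off-tissue, internal standard too
#' low); a unit is mandatory so cps and µg/g can never be confused.
#'
#' @param element Isotope label (e.g. \code{"63Cu"}).
#' @param values Numeric matrix.
#' @param unit One of \code{"cps"}, \code{"ratio_to_13C"},
#'   \code{"ug_per_g"}.
#' @param pixel_size_um Along-scan pixel pitch, µm.
#' @param mask Optional logical matrix (e.g. below-LOD flags).
#' @param provenance Free-text provenance strings.
#' @return An object of class \code{element_map}.
#' @export
element_map <- function(element, values, unit, pixel_size_um,
                        mask = NULL, provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (length(unit) != 1L || !unit %in% MAP_UNITS) {
    stopf("`unit` must be one of: %s", paste(MAP_UNITS, collapse = ", "))
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  if (!is.null(mask) && !identical(dim(mask), dim(values))) {
    stopf("`mask` shape differs from `values`")
  }
  structure(list(element = element, values = values, unit = unit,
                 pixel_size_um = pixel_size_um, mask = mask,
                 provenance = as.character(provenance)),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s, %dx%d px @ %.3g um, unit %s (%d NA)\n",
              x$element, nrow(x$values), ncol(x$values), x$pixel_size_um,
              x$unit, sum(is.na(x$values))))
  invisible(x)
}

#' Write / read a map grid file
#'
#' Plain-text grid: commented header lines (\code{# key: value}) carrying
#' element, unit and pixel size (plus provenance), then one
#' comma-separated row of values per image row; \code{NA} encodes missing
#' pixels. Files without a unit header are rejected. Round trips preserve
#' full double precision and \code{NA} positions.
#'
#' @param map An [element_map()].
#' @param path File path.
#' @return \code{write_map} invisibly returns \code{path}; \code{read_map}
#'   returns an [element_map()].
#' @export
write_map <- function(map, path) {
  if (!inherits(map, "element_map")) stopf("`map` must be an element_map")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# element: %s", map$element),
    sprintf("# unit: %s", map$unit),
    sprintf("# pixel_size_um: %s", formatC(map$pixel_size_um, digits = 17, format = "g")),
    sprintf("# provenance: %s", map$provenance)
  ), con)
  body <- apply(map$values, 1L, function(r) {
    paste(ifelse(is.na(r), "NA", formatC(r, digits = 17, format = "g")),
          collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  all_lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", all_lines, value = TRUE)
  body <- all_lines[!grepl("^#", all_lines)]
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    sub(sprintf("^# %s:\\s*", key), "", m)
  }
  unit <- get_field("unit")
  if (length(unit) != 1L || !unit %in% MAP_UNITS) {
    stopf("map file %s lacks a valid '# unit:' header (refusing unitless maps)",
          path)
  }
  element <- get_field("element")
  if (length(element) != 1L) stopf("map file %s lacks an element header", path)
  psz <- as.numeric(get_field("pixel_size_um"))
  if (length(psz) != 1L || is.na(psz)) {
    stopf("map file %s lacks a pixel_size_um header", path)
  }
  rows <- lapply(strsplit(body, ","), function(x) {
    suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  })
  if (length(unique(lengths(rows))) != 1L) stopf("ragged rows in map file %s", path)
  values <- do.call(rbind, rows)
  element_map(element, values, unit, psz, provenance = get_field("provenance"))
}
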