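# Shared fixtures and the independent assembly oracle.

# Straight-line re-implementation of map assembly with explicit nested
# loops, kept deliberately independent of assemble_map()'s vectorized path.
assemble_oracle <- function(run, isotope) {
  ord <- order(run$laser_log$y_um)
  widths <- run$laser_log$laser_off_cycle - run$laser_log$laser_on_cycle
  w <- max(widths)
  out <- matrix(NA_real_, length(ord), w)
  for (r in seq_along(ord)) {
    i <- ord[r]
    on <- run$laser_log$laser_on_cycle[i]
    off <- run$laser_log$laser_off_cycle[i]
    df <- run$lines[[i]]
    col <- 0L
    for (cyc in seq_len(nrow(df))) {
      ci <- df$cycle_index[cyc]
      if (ci >= on && ci < off) {
        col <- col + 1L
        out[r, col] <- df[[isotope]][cyc]
      }
    }
  }
  out
}

# Hand-built raw run: one data frame per line, arbitrary intensities per
# isotope (list of matrices line x cycle), uniform laser window.
manual_run <- function(intens, on, off, cycle_time = 0.1, scan_speed = 55,
                       y_um = NULL) {
  isotopes <- names(intens)
  n_lines <- nrow(intens[[1]])
  n_c <- ncol(intens[[1]])
  if (is.null(y_um)) y_um <- (seq_len(n_lines) - 1) * 10
  lines <- lapply(seq_len(n_lines), function(i) {
    df <- data.frame(cycle_index = 0:(n_c - 1L),
                     time_s = (i - 1) * n_c * cycle_time +
                       (0:(n_c - 1L)) * cycle_time)
    for (e in isotopes) df[[e]] <- intens[[e]][i, ]
    df
  })
  log <- data.frame(line_index = 0:(n_lines - 1L), y_um = y_um,
                    start_time_s = (seq_len(n_lines) - 1) * n_c * cycle_time,
                    laser_on_cycle = on, laser_off_cycle = off,
                    scan_speed_um_s = scan_speed)
  raw_run(lines, isotopes, cycle_time_s = cycle_time, laser_log = log)
}

# Single-element phantom on the pitch of a matching instrument.
tiny_phantom <- function(values, instrument, element = "63Cu") {
  phantom(setNames(list(values), element),
          pixel_size_um = instrument$pixel_pitch_um)
}

# Instrument carrying one analyte channel only (plus optional 13C).
mini_instrument <- function(isotopes, sensitivity, background = NULL,
                            noise_model = "none", ...) {
  if (is.null(background)) background <- setNames(rep(0, length(isotopes)), isotopes)
  instrument_model(isotopes = isotopes, sensitivity = sensitivity,
                   background = background, noise_model = noise_model, ...)
}

# Full section pipeline -> tissue-mean concentrations for a preset/seed;
# shared by recovery and ordering tests.
pipeline_means <- function(preset, seed, elements = c("24Mg", "63Cu", "64Zn"),
                           width = 64, height = 64) {
  instr <- instrument_model(seed = seed, drift = linear_drift(0.05))
  ph <- make_phantom(preset, width, height, seed = seed)
  run <- simulate_linescans(ph, instr)
  std_instr <- instr
  std_instr$seed <- as.integer(seed + 99991)
  std <- simulate_standards(instrument = std_instr)
  curves <- lapply(setNames(nm = elements), fit_calibration, standards = std)
  q <- quantify_section(run, curves, name = preset)
  list(means = setNames(q$report$elements$mean, q$report$elements$element),
       report = q$report, mask = q$mask, phantom = ph, conc_maps = q$conc_maps)
}
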