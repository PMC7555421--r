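test_that("assembly reshapes a simulated two-line run into the expected map", {
  instr <- mini_instrument("63Cu", c("63Cu" = 100))
  ph <- tiny_phantom(matrix(c(1, 3, 2, 4), 2, 2), instr)
  m <- assemble_map(simulate_linescans(ph, instr), "63Cu")
  expect_equal(m$values, matrix(c(100, 300, 200, 400), 2, 2))
  expect_equal(m$unit, "cps")
})

test_that("along-scan pixel size is scan speed times cycle time", {
  instr <- instrument_model(scan_speed_um_s = 50, seed = 1)  # 8 isotopes -> 0.18 s
  expect_equal(instr$cycle_time_s, 0.18)
  ph <- make_phantom("wildtype_9wk", 32, 32, seed = 1,
                     pixel_size_um = instr$pixel_pitch_um, hex_pitch_um = 120)
  m <- assemble_map(simulate_linescans(ph, instr), "63Cu")
  expect_equal(m$pixel_size_um, 9.0)
})

test_that("degenerate runs assemble and validate correctly", {
  one <- manual_run(list("63Cu" = matrix(c(3, 42, 5), 1, 3)), on = 1, off = 2)
  expect_equal(assemble_map(one, "63Cu")$values, matrix(42, 1, 1))
  expect_error(assemble_map(one, "64Zn"), "not present")
  # unequal laser-on lengths: shorter lines are right-padded with NA
  intens <- list("63Cu" = matrix(1:12, 2, 6))
  run <- manual_run(intens, on = 1, off = 5)
  run$laser_log$laser_off_cycle[2] <- 3
  run <- raw_run(run$lines, run$isotopes, run$cycle_time_s, run$laser_log)
  m <- assemble_map(run, "63Cu")
  expect_equal(dim(m$values), c(2L, 4L))
  expect_true(all(is.na(m$values[2, 3:4])))
})

test_that("assembly agrees exactly with a brute-force loop oracle on small runs", {
  set.seed(42)
  for (trial in 1:12) {
    n_lines <- sample(1:4, 1); n_c <- sample(3:6, 1)
    on <- sample(0:(n_c - 2), 1); off <- sample((on + 1):n_c, 1)
    intens <- list("13C" = matrix(round(runif(n_lines * n_c) * 1000), n_lines, n_c),
                   "63Cu" = matrix(round(runif(n_lines * n_c) * 100), n_lines, n_c))
    run <- manual_run(intens, on = on, off = off,
                      y_um = sample(seq_len(n_lines)) * 10)  # shuffled line order
    for (iso in c("13C", "63Cu")) {
      expect_identical(assemble_map(run, iso)$values, assemble_oracle(run, iso))
    }
  }
})

test_that("background estimation pools laser-off cycles with an n-1 SD", {
  intens <- list("63Cu" = matrix(c(10, 99, 10, 10), 1, 4))
  run <- manual_run(intens, on = 1, off = 2)
  expect_equal(estimate_background(run, "63Cu"),
               c(mean_cps = 10, sd_cps = 0))
  intens2 <- list("63Cu" = matrix(c(8, 99, 10, 12), 1, 4))
  run2 <- manual_run(intens2, on = 1, off = 2)
  expect_equal(estimate_background(run2, "63Cu"),
               c(mean_cps = 10, sd_cps = 2))
  # a run whose lines are laser-on throughout has no blanks to pool
  all_on <- manual_run(list("63Cu" = matrix(1, 2, 1)), on = 0, off = 1)
  expect_error(estimate_background(all_on, "63Cu"), "longer blank segments")
})

test_that("background subtraction floors at zero and counts clipped pixels", {
  m <- element_map("63Cu", matrix(100), "cps", 9.9)
  expect_equal(subtract_background(m, 10)$values, matrix(90))
  low <- subtract_background(element_map("63Cu", matrix(5), "cps", 9.9), 10)
  expect_equal(low$values, matrix(0))
  expect_match(low$provenance[length(low$provenance)], "clipped=1")
  expect_error(subtract_background(
    element_map("63Cu", matrix(1), "ratio_to_13C", 9.9), 1), "cps map")
})

test_that("blank sections are background-free after subtraction, across seeds", {
  resid_z <- sapply(1:20, function(s) {
    instr <- mini_instrument("63Cu", c("63Cu" = 100),
                             background = c("63Cu" = 50),
                             noise_model = "poisson_gaussian", seed = s)
    ph <- tiny_phantom(matrix(0, 8, 8), instr)
    run <- simulate_linescans(ph, instr)
    bg <- estimate_background(run, "63Cu")
    m <- assemble_map(run, "63Cu")
    # unfloored residual in units of the per-pixel noise SD
    n <- length(m$values)
    (mean(m$values) - bg[["mean_cps"]]) / (bg[["sd_cps"]] / sqrt(n))
    })
  # residual mean is zero within noise (z-scores ~ N(0,1))
  expect_lt(abs(mean(resid_z)), 1)
  expect_lt(max(abs(resid_z)), 5)
})

test_that("internal-standard normalization divides pixelwise with a low-13C guard", {
  a <- element_map("63Cu", matrix(c(10, 20, 30, 40), 2, 2), "cps", 9.9)
  c13 <- element_map("13C", matrix(c(10, 20, 30, 40), 2, 2), "cps", 9.9)
  r <- normalize_to_internal_standard(a, c13)
  expect_equal(r$values, matrix(1, 2, 2))
  expect_equal(r$unit, "ratio_to_13C")
  zero <- element_map("63Cu", matrix(0, 2, 2), "cps", 9.9)
  expect_equal(normalize_to_internal_standard(zero, c13)$values, matrix(0, 2, 2))
  # pixels with 13C below 5% of the tissue median become NA
  weak <- element_map("13C", matrix(c(1000, 1000, 1000, 0.1), 2, 2), "cps", 9.9)
  r2 <- normalize_to_internal_standard(a, weak)
  expect_true(is.na(r2$values[2, 2]))
  expect_equal(sum(is.na(r2$values)), 1L)
  bad <- element_map("13C", matrix(1, 1, 3), "cps", 9.9)
  expect_error(normalize_to_internal_standard(a, bad), "shape mismatch")
})

test_that("every assembly-stage operation conserves the map shape", {
  instr <- instrument_model(seed = 8)
  ph <- make_phantom("wildtype_13wk", 24, 16, seed = 8,
                     pixel_size_um = instr$pixel_pitch_um, hex_pitch_um = 100)
  run <- simulate_linescans(ph, instr)
  m <- assemble_map(run, "63Cu")
  c13 <- assemble_map(run, "13C")
  expect_equal(dim(m$values), c(16L, 24L))
  m2 <- subtract_background(m, estimate_background(run, "63Cu")[["mean_cps"]])
  c13b <- subtract_background(c13, estimate_background(run, "13C")[["mean_cps"]])
  r <- normalize_to_internal_standard(m2, c13b)
  expect_equal(dim(m2$values), dim(m$values))
  expect_equal(dim(r$values), dim(m$values))
})

test_that("shared multiplicative drift cancels under 13C normalization and persists without it", {
  ratio_and_raw <- function(drift) {
    instr <- instrument_model(seed = 3, noise_model = "none", drift = drift)
    ph <- make_phantom("atp7b_ko", 32, 32, seed = 3,
                       pixel_size_um = instr$pixel_pitch_um, hex_pitch_um = 120)
    run <- simulate_linescans(ph, instr)
    bg <- estimate_background(run, "63Cu")[["mean_cps"]]
    bg13 <- estimate_background(run, "13C")[["mean_cps"]]
    cu <- subtract_background(assemble_map(run, "63Cu"), bg)
    c13 <- subtract_background(assemble_map(run, "13C"), bg13)
    list(ratio = normalize_to_internal_standard(cu, c13)$values,
         raw = cu$values)
  }
  with_drift <- ratio_and_raw(linear_drift(0.05))
  no_drift_r <- ratio_and_raw(no_drift())
  rel <- abs(with_drift$ratio - no_drift_r$ratio) / abs(no_drift_r$ratio)
  expect_lt(max(rel, na.rm = TRUE), 1e-6)
  raw_rel <- abs(with_drift$raw - no_drift_r$raw) / abs(no_drift_r$raw)
  expect_gt(max(raw_rel, na.rm = TRUE), 0.01)   # un-normalized maps keep the drift
})
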