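test_that("presets encode the genotype contrasts", {
  wt <- lapply(c("wildtype_9wk", "wildtype_13wk", "wildtype_36wk"), phantom_preset)
  ko <- phantom_preset("atp7b_ko")
  for (p in wt) {
    expect_gt(ko$cu_mean, p$cu_mean)
    expect_gt(ko$zn_scale, p$zn_scale)
  }
  expect_lt(ko$mg_coupling, 0)
  expect_error(phantom_preset("wildtype_99wk"), "unknown preset")
  expect_error(phantom_preset("atp7b_ko", shininess = 2), "unknown preset field")
})

test_that("phantom copper means hit the preset values exactly and fields respect the mask", {
  for (nm in c("atp7b_ko", "wildtype_36wk")) {
    ph <- make_phantom(nm, 64, 64, seed = 11)
    truth <- phantom_preset(nm)$cu_mean
    expect_equal(mean(ph$conc[["63Cu"]][ph$tissue_mask]), truth,
                 tolerance = 1e-10)
    for (e in names(ph$conc)) {
      expect_true(all(ph$conc[[e]] >= 0))
      expect_true(all(ph$conc[[e]][!ph$tissue_mask] == 0))
    }
  }
})

test_that("knockout phantoms carry more copper and zinc but less magnesium than wild type, every seed", {
  for (seed in 1:5) {
    ko <- make_phantom("atp7b_ko", 48, 48, seed = seed)
    msk_mean <- function(ph, e) mean(ph$conc[[e]][ph$tissue_mask])
    for (wt_name in c("wildtype_9wk", "wildtype_13wk", "wildtype_36wk")) {
      wt <- make_phantom(wt_name, 48, 48, seed = seed)
      expect_gt(msk_mean(ko, "63Cu"), msk_mean(wt, "63Cu"))
      expect_lt(msk_mean(ko, "24Mg"), msk_mean(wt, "24Mg"))
      expect_gt(msk_mean(ko, "64Zn") / msk_mean(wt, "64Zn"), 1)
    }
  }
})

test_that("magnesium decouples from copper when the coupling slope is zero", {
  pr <- phantom_preset("atp7b_ko", mg_coupling = 0)
  rs <- sapply(1:8, function(s) {
    ph <- make_phantom(pr, 48, 48, seed = s)
    cor(ph$conc[["63Cu"]][ph$tissue_mask], ph$conc[["24Mg"]][ph$tissue_mask])
  })
  expect_lt(max(abs(rs)), 0.25)      # sampling error around zero
  expect_lt(abs(mean(rs)), 0.1)
  # the default negative coupling produces a consistently negative
  # correlation (modest in size: magnesium's own heterogeneity remains)
  rneg <- sapply(1:5, function(s) {
    ph <- make_phantom("atp7b_ko", 48, 48, seed = s)
    cor(ph$conc[["63Cu"]][ph$tissue_mask], ph$conc[["24Mg"]][ph$tissue_mask])
  })
  expect_true(all(rneg < -0.05))
})

test_that("iron rim structure follows the requested lobule contrast", {
  # noiseless phantom: rim/interior ratio equals the preset contrast
  pr <- phantom_preset("wildtype_9wk", pixel_cv = 0)
  ph <- make_phantom(pr, 64, 64, seed = 4)
  rim <- ph$fe_rim_mask
  interior <- ph$tissue_mask & !rim
  ratio <- mean(ph$conc[["56Fe"]][rim]) / mean(ph$conc[["56Fe"]][interior])
  expect_equal(ratio, pr$fe_rim_contrast, tolerance = 0.05)
  # contrast 1: no rim structure
  pr1 <- phantom_preset("wildtype_9wk", fe_rim_contrast = 1)
  ph1 <- make_phantom(pr1, 64, 64, seed = 4)
  rim1 <- ph1$fe_rim_mask; int1 <- ph1$tissue_mask & !rim1
  expect_equal(mean(ph1$conc[["56Fe"]][rim1]) / mean(ph1$conc[["56Fe"]][int1]),
               1, tolerance = 0.05)
})

test_that("grids too small for one lobule hexagon are rejected", {
  expect_error(make_phantom("wildtype_9wk", 10, 10, seed = 1),
               "too small to contain one hexagonal lobule")
  expect_error(make_phantom("wildtype_9wk", 4, 64, seed = 1), "at least 8x8")
})

test_that("phantom and run generation are deterministic in the seed", {
  ph1 <- make_phantom("atp7b_ko", 32, 32, seed = 5, hex_pitch_um = 120)
  ph2 <- make_phantom("atp7b_ko", 32, 32, seed = 5, hex_pitch_um = 120)
  ph3 <- make_phantom("atp7b_ko", 32, 32, seed = 6, hex_pitch_um = 120)
  expect_identical(ph1, ph2)
  expect_false(identical(ph1$conc[["63Cu"]], ph3$conc[["63Cu"]]))

  instr <- instrument_model(seed = 9)
  r1 <- simulate_linescans(ph1, instr)
  r2 <- simulate_linescans(ph2, instr)
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_run(r1, d1); write_run(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the signal equation reproduces hand-computed intensities", {
  instr <- mini_instrument("63Cu", c("63Cu" = 100))
  ph <- tiny_phantom(matrix(c(1, 3, 2, 4), 2, 2), instr)
  run <- simulate_linescans(ph, instr)
  b <- instr$blank_cycles_per_line
  on_cols <- (b + 1):(b + 2)
  expect_equal(run$lines[[1]][["63Cu"]][on_cols], c(100, 200))
  expect_equal(run$lines[[2]][["63Cu"]][on_cols], c(300, 400))
  # laser-off cycles carry only background (zero here)
  expect_equal(run$lines[[1]][["63Cu"]][1:b], rep(0, b))
})

test_that("a blank phantom yields pure background on every cycle", {
  instr <- mini_instrument("63Cu", c("63Cu" = 100),
                           background = c("63Cu" = 7))
  ph <- tiny_phantom(matrix(0, 3, 4), instr)
  run <- simulate_linescans(ph, instr)
  for (ln in run$lines) expect_true(all(ln[["63Cu"]] == 7))
})

test_that("noiseless standards respond affinely with slope = sensitivity", {
  instr <- instrument_model(noise_model = "none", seed = 2)
  std <- simulate_standards(levels = list("63Cu" = c(0, 50, 100)),
                            instrument = instr, width = 8, height = 4)
  known <- sapply(std, function(s) s$known_conc[["63Cu"]])
  resp <- sapply(std, function(s) {
    i <- s$run$laser_log$laser_on_cycle[1] + 1
    j <- s$run$laser_log$laser_off_cycle[1]
    mean(sapply(s$run$lines, function(ln) mean(ln[["63Cu"]][i:j])))
  })
  fit <- lm(resp ~ known)
  # raw cps respond with the instrument's cps-per-(ug/g) sensitivity
  # (13C normalization happens downstream of this contract)
  expect_equal(unname(coef(fit)[2]), instr$sensitivity[["63Cu"]],
               tolerance = 1e-9)
  expect_error(simulate_standards(levels = list("63Cu" = c(-1, 10))),
               "negative spike")
  expect_error(simulate_standards(levels = list("63Cu" = c(5, 5))),
               ">= 2 distinct levels")
})

test_that("standard simulation is deterministic across repeated calls", {
  instr <- instrument_model(seed = 21)
  s1 <- simulate_standards(levels = list("63Cu" = c(0, 10)), replicates = 3,
                           instrument = instr, width = 6, height = 4)
  s2 <- simulate_standards(levels = list("63Cu" = c(0, 10)), replicates = 3,
                           instrument = instr, width = 6, height = 4)
  expect_identical(s1, s2)
  # replicates differ from one another (independent noise draws)
  expect_false(identical(s1[[1]]$run$lines, s1[[2]]$run$lines))
})
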