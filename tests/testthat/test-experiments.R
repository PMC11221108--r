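test_that("the named case table matches the frozen simulation grids", {
  cases <- scenario_cases()
  expect_setequal(cases$case, c("H_Ntot", "H_Tmeas", "H_fs", "H_SDD", "B_UP",
                                "B_DW", "B_UPDW", "B_Amp", "B_Freq",
                                "B_AmpFreq"))
  h <- cases[cases$case == "H_Ntot", ]
  expect_equal(h$n_tot[[1]], c(1e4, 1e5, 1e6))
  expect_equal(h$tmeas_min[[1]], 15)
  expect_equal(h$fs[[1]], 20)
  expect_equal(h$sdd[[1]], c(1, 4))
  expect_equal(cases$tmeas_min[cases$case == "H_Tmeas"][[1]], c(5, 10, 15))
  expect_equal(cases$fs[cases$case == "H_fs"][[1]], c(5, 10, 20))
  expect_equal(cases$sdd[cases$case == "H_SDD"][[1]], 1:6)
  b <- cases[cases$case == "B_AmpFreq", ]
  expect_equal(c(b$amp_up, b$freq_up, b$amp_dw, b$freq_dw), c(1, 0.2, 0.5, 1))
  bf <- cases[cases$case == "B_Freq", ]
  expect_equal(c(bf$amp_up, bf$freq_up, bf$amp_dw, bf$freq_dw), c(1, 0.2, 1, 1))
  expect_true(all(cases$amp_up[cases$case %in% c("B_UP", "B_UPDW")] == 1))
  expect_true(is.na(cases$amp_dw[cases$case == "B_UP"]))
  expect_true(is.na(cases$amp_up[cases$case == "B_DW"]))
})

test_that("configurations honour overrides and reject unknown cases", {
  cfg <- scenario_config("B_DW", n_tot = 1e6, sdd = 1, tmeas = 120)
  expect_equal(cfg$n_tot, 1e6)
  expect_equal(cfg$sdd, 1)
  expect_equal(cfg$tmeas, 120)
  expect_equal(cfg$amp_dw, 0.01)
  expect_true(is.na(cfg$amp_up))
  expect_equal(cfg$dt, 0.02)
  expect_equal(scenario_config("H_Ntot")$dt, 0.008)
  expect_error(scenario_config("H_Nope"), "unknown case")
})

test_that("phase locking puts the deep layer in or out of phase with the
           superficial layer", {
  for (mode in c("in_phase", "out_of_phase")) {
    cfg <- scenario_config("B_UPDW", seed = 9, phase_mode = mode)
    perts <- fnirsim:::config_perturbations(cfg)
    ph <- vapply(perts, function(p) p$phase, numeric(1))
    names(ph) <- vapply(perts, function(p) paste(p$layer, p$species),
                        character(1))
    off <- if (mode == "in_phase") 0 else pi
    expect_equal((ph[["DW O2Hb"]] - ph[["UP O2Hb"]]) %% (2 * pi), off)
    expect_equal((ph[["DW HHb"]] - ph[["UP HHb"]]) %% (2 * pi), off)
  }
})

test_that("a zero-perturbation run shows no significant peaks", {
  cfg <- scenario_config("H_Ntot", seed = 4, n_tot = 1e5, sdd = 4,
                         tmeas = 120, wavelengths = 690, amp_up = 0)
  res <- run_case(cfg)
  expect_false(any(res$significant))
  expect_false(any(res$second_significant))
})

test_that("scenario runs are reproducible from the master seed", {
  cfg <- scenario_config("H_Ntot", seed = 6, n_tot = c(1e4, 1e5), sdd = 4,
                         tmeas = 30, wavelengths = 690)
  r1 <- run_case(cfg)
  r2 <- run_case(cfg)
  expect_identical(r1, r2)
  r3 <- run_case(scenario_config("H_Ntot", seed = 7, n_tot = c(1e4, 1e5),
                                 sdd = 4, tmeas = 30, wavelengths = 690))
  expect_false(identical(r1$peak_psd, r3$peak_psd))
})

test_that("scaling reports recover exact synthetic power laws", {
  fake <- tibble::tibble(
    sdd = 4, wavelength = 690, n_tot = c(1e4, 1e5, 1e6),
    peak_psd = 2 * c(1e4, 1e5, 1e6)^2,
    epsilon = rep(5, 3),
    contrast = 0.4 * c(1e4, 1e5, 1e6))
  rep <- scaling_report(fake, "n_tot")
  expect_equal(rep$exponent[rep$metric == "peak_psd"], 2)
  expect_equal(rep$r_squared[rep$metric == "peak_psd"], 1)
  expect_equal(rep$exponent[rep$metric == "contrast"], 1)
  expect_equal(rep$max_dev_pct[rep$metric == "epsilon"], 0)
})

test_that("gate profiles report every gate plus the CW channel with exact
           bookkeeping", {
  cfg <- scenario_config("B_UP", seed = 2, n_tot = 1e5, sdd = 1, tmeas = 60,
                         fs = 5)
  prof <- gate_contrast_profile(cfg)
  expect_equal(nrow(prof), 11)
  expect_equal(prof$gate, c(as.character(1:10), "CW"))
  expect_equal(prof$baseline_mean_counts[11],
               sum(prof$baseline_mean_counts[1:10]))
  expect_equal(prof$baseline_mean_counts[11], 1e5, tolerance = 1e-10)
  # superficial perturbation is visible in the populated early gates
  expect_true(prof$significant[1])
  # empty late gates at short SDD carry only Poisson noise
  expect_true(all(prof$baseline_mean_counts[7:10] < 10))
  expect_false(any(prof$significant[8:10]))
})
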