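test_that("baseline totals are Poisson-calibrated and zero-expectation bins
           stay empty", {
  dtof <- small_homog_dtof(n_tot = 1e4, tmeas = 100, fs = 20, amp = 0)
  totals <- rowSums(dtof$counts)
  n <- length(totals)
  expect_equal(n, 2000)
  # sample mean of per-frame totals within 3 standard errors of the budget
  expect_lt(abs(mean(totals) - 1e4), 3 * sqrt(1e4 / n))
  # per-bin variance/mean across frames near 1 where expectations are decent
  lam <- dtof$baseline_expect
  sel <- which(lam >= 10)
  vm <- apply(dtof$counts[, sel], 2, stats::var) / colMeans(dtof$counts[, sel])
  expect_true(all(vm > 0.9 & vm < 1.1))
  # bins with zero expectation never fire
  expect_true(all(dtof$counts[, lam == 0] == 0))
})

test_that("synthesis is reproducible from the seed", {
  a <- small_homog_dtof(n_tot = 1e4, tmeas = 10, fs = 20, seed = 42)
  hemo <- make_hemo_series(
    hemo_baseline(), list(perturbation_spec(0.01, 1, layer = "WHOLE")),
    10, 20, seed = 42)
  op <- slab_forward_operator(baseline_props_690(), slab_geometry(), 4,
                              grid_20ps, 690)
  b <- synthesize_dtof_series(
    hemo, list("690" = op),
    acquisition_settings(1e4, 10, 20, 4, 690, seed = 42))[["690"]]
  c <- synthesize_dtof_series(
    hemo, list("690" = op),
    acquisition_settings(1e4, 10, 20, 4, 690, seed = 43))[["690"]]
  expect_identical(b$counts, b$counts)
  expect_false(identical(b$counts, c$counts))
  expect_true(is.integer(b$counts) || all(b$counts == round(b$counts)))
})

test_that("homogeneous fast path equals direct slab re-evaluation pre-noise", {
  props <- baseline_props_690()
  op <- slab_forward_operator(props, slab_geometry(), 4, grid_20ps, 690)
  mua_frames <- props$mua * (1 + c(-0.01, 0, 0.007))
  E <- fnirsim:::forward_expectation(op, mua_frames)
  for (i in seq_along(mua_frames)) {
    direct <- slab_td_reflectance(
      optical_properties(mua_frames[i], props$musp, props$n),
      slab_geometry(), 4, grid_20ps)$value
    keep <- direct > 0
    expect_lt(max(abs(E[i, keep] / direct[keep] - 1)), 1e-10)
  }
})

test_that("bilayer node interpolation reproduces direct evaluation off-grid", {
  props <- baseline_props_690()
  op <- bilayer_forward_operator(props, props, bilayer_geometry(), 4,
                                 grid_20ps, 690)
  mua_up <- props$mua * 1.0042       # deliberately between nodes
  mua_dw <- props$mua * 0.9937
  E <- fnirsim:::forward_expectation(op, mua_up, mua_dw)
  direct <- bilayer_td_reflectance(
    optical_properties(mua_up, props$musp, props$n),
    optical_properties(mua_dw, props$musp, props$n),
    bilayer_geometry(), 4, grid_20ps)$value
  keep <- direct >= 1e-6 * max(direct) & op$positive
  expect_lt(max(abs(E[1, keep] / direct[keep] - 1)), 5e-4)
})

test_that("IRF convolution is identity for a delta and preserves area", {
  # strongly absorbing medium: the curve fully decays inside the window, so
  # no convolved mass is lost to truncation
  curve <- slab_td_reflectance(test_props(0.3), slab_geometry(), 3, grid_20ps)
  delta <- c(1, rep(0, nrow(curve) - 1))
  expect_equal(convolve_irf(curve, delta)$value, curve$value, tolerance = 1e-12)
  irf <- gaussian_irf(grid_20ps, fwhm = 0.1)
  out <- convolve_irf(curve, irf)
  expect_equal(sum(out$value), sum(curve$value), tolerance = 1e-10)
  # independent direct-summation oracle
  direct <- sapply(seq_len(nrow(curve)), function(i)
    sum(irf$value[1:i] * curve$value[i:1]))
  expect_equal(out$value, direct, tolerance = 1e-8)
  expect_error(convolve_irf(curve, irf$value * 2), "unit area")
  expect_error(convolve_irf(curve, irf$value[-1]), "grids")
})

test_that("gate sums conserve counts exactly and empty input stays empty", {
  dtof <- small_homog_dtof(n_tot = 1e4, tmeas = 10, fs = 20)
  gated <- gate_counts(dtof, default_gates())
  expect_identical(rowSums(gated$counts), rowSums(dtof$counts))
  one_gate <- gate_counts(dtof, gate_set(c(0, 5)))
  expect_equal(as.vector(one_gate$counts), rowSums(dtof$counts),
               ignore_attr = TRUE)
  cw <- integrate_to_cw(dtof)
  expect_identical(cw$intensity, rowSums(dtof$counts))
  zero <- dtof
  zero$counts[] <- 0L
  expect_true(all(gate_counts(zero, default_gates())$counts == 0))
  expect_error(gate_counts(dtof, gate_set(c(0, 6))), "outside")
})

test_that("a 1% absorption oscillation modulates CW intensity by the
           pathlength-predicted fraction", {
  dtof <- small_homog_dtof(n_tot = 1e6, tmeas = 60, fs = 20, amp = 0.01,
                           seed = 2)
  cw <- integrate_to_cw(dtof)
  x <- detrend_poly(cw$intensity, 3)
  n <- length(x)
  # realized amplitude of the 1 Hz component
  amp_hat <- 2 * Mod(stats::fft(x)[1 + 60]) / n   # 1 Hz bin for 60 s at 20 Hz
  props <- baseline_props_690()
  base_curve <- slab_td_reflectance(props, slab_geometry(), 4, grid_20ps, 690)
  L <- mean_photon_pathlength(base_curve)
  # first-order MBLL: relative amplitude = <L> * amplitude of dmua
  hemo <- make_hemo_series(
    hemo_baseline(), list(perturbation_spec(0.01, 1, layer = "WHOLE")),
    60, 20, seed = 2)
  mua <- hemo_to_mua_series(hemo, 690)$mua
  dmua_amp <- (max(mua) - min(mua)) / 2
  expect_equal(amp_hat / mean(cw$intensity), L * dmua_amp, tolerance = 0.1)
})
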