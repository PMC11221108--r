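test_that("homogeneous baseline fit recovers generating parameters from a
           noiseless curve", {
  props <- baseline_props_690()
  curve <- slab_td_reflectance(props, slab_geometry(), 4, grid_20ps)
  counts <- curve$value * 1e6 / sum(curve$value)
  fit <- fit_homogeneous_baseline(counts, grid_20ps, 4)
  expect_true(fit$converged)
  expect_lt(abs(fit$mua / props$mua - 1), 0.005)
  expect_lt(abs(fit$musp / props$musp - 1), 0.005)
  # init at truth: immediate convergence to the same parameters
  fit0 <- fit_homogeneous_baseline(counts, grid_20ps, 4,
                                   init = list(mua = props$mua,
                                               musp = props$musp))
  expect_true(fit0$converged)
  expect_lt(abs(fit0$mua / props$mua - 1), 1e-4)
  expect_lt(abs(fit0$musp / props$musp - 1), 1e-4)
  g <- glance(fit)
  expect_true(g$converged)
})

test_that("baseline fit on Poisson-averaged data recovers parameters within
           1%", {
  dtof <- small_homog_dtof(n_tot = 1e6, tmeas = 100, fs = 20, amp = 0,
                           seed = 8)
  fit <- fit_homogeneous_baseline(colMeans(dtof$counts), grid_20ps, 4)
  props <- baseline_props_690()
  expect_lt(abs(fit$mua / props$mua - 1), 0.01)
  expect_lt(abs(fit$musp / props$musp - 1), 0.01)
})

test_that("partial pathlengths satisfy the total-pathlength identity and the
           depth ordering", {
  plop <- bilayer_op_690(4)
  v <- 29.9792458 / 1.4
  keep <- plop$valid &
    plop$baseline$value >= 1e-6 * max(plop$baseline$value)
  total <- (plop$L_up + plop$L_dw)[keep]
  expect_lt(max(abs(total / (v * plop$time[keep]) - 1)), 0.005)
  # deep pathlength accumulates with detection time
  ldw <- plop$L_dw[keep]
  expect_true(all(diff(ldw) > -1e-3 * max(ldw)))
})

test_that("first-gate photons at short SDD have negligible deep pathlength", {
  plop <- bilayer_op_690(1)
  expect_lt(plop$L_gate[1, "dw"] / plop$L_gate[1, "up"], 0.02)
})

test_that("the finite-difference step passes the consistency check", {
  p <- baseline_props_690()
  expect_s3_class(
    tmpp_pathlengths(p, p, bilayer_geometry(), 2, grid_20ps, validate = TRUE),
    "pathlength_operator")
})

test_that("TMPP inversion recovers imposed layer absorption changes from
           noiseless gated data", {
  plop <- bilayer_op_690(4)
  props <- baseline_props_690()
  dmu <- c(up = 8e-4, dw = -5e-4)
  pert <- bilayer_td_reflectance(
    optical_properties(props$mua + dmu[["up"]], props$musp, props$n),
    optical_properties(props$mua + dmu[["dw"]], props$musp, props$n),
    bilayer_geometry(), 4, grid_20ps)
  scale <- 1e6 / sum(plop$baseline$value)
  gates <- default_gates()
  bin_gate <- findInterval(grid_20ps$centers, c(gates$t_start, 5))
  n_base <- sapply(seq_len(10), function(g)
    sum(plop$baseline$value[bin_gate == g]) * scale)
  n_pert <- sapply(seq_len(10), function(g)
    sum(pert$value[bin_gate == g]) * scale)
  # frames alternating baseline/perturbed so the measurement mean is baseline-
  # centred; solve manually against the operator's gate pathlengths
  usable <- n_base >= 10
  A <- plop$L_gate[usable, ]
  y <- log(n_base[usable] / n_pert[usable])
  w <- n_pert[usable]
  M <- t(A) %*% (A * w)
  sol <- solve(M, t(A) %*% (w * y))
  expect_lt(abs(sol[1] / dmu[["up"]] - 1), 0.02)
  expect_lt(abs(sol[2] / dmu[["dw"]] - 1), 0.05)
})

test_that("TMPP inversion of an unperturbed noisy series is unbiased", {
  props <- baseline_props_690()
  hemo <- make_hemo_series(hemo_baseline(), list(), 60, 5, seed = 21,
                           layers = c("UP", "DW"))
  op <- bilayer_forward_operator(props, props, bilayer_geometry(), 4,
                                 grid_20ps, 690,
                                 perturbed = c(up = FALSE, dw = FALSE))
  dtof <- synthesize_dtof_series(
    hemo, list("690" = op),
    acquisition_settings(1e5, 60, 5, 4, 690, seed = 21))[["690"]]
  plop <- bilayer_op_690(4)
  dmua <- tmpp_invert(gate_counts(dtof), plop)
  for (col in c("dmua_up", "dmua_dw")) {
    se <- stats::sd(dmua[[col]]) / sqrt(nrow(dmua))
    expect_lt(abs(mean(dmua[[col]])), 3 * se)
  }
  expect_true(all(c(1, 2) %in% attr(dmua, "usable_gates")))
})

test_that("CW modified Beer-Lambert inverts its own forward identity", {
  flat <- tibble::tibble(frame = 0:9, time = 0:9, intensity = rep(250, 10))
  expect_equal(cw_mbll(flat, 20)$dmua, rep(0, 10))
  L <- 25
  delta <- c(0, 1e-3, -2e-3, 5e-4)
  out <- cw_mbll(1000 * exp(-delta * L), L)
  # the mean-intensity baseline shifts all changes by a common constant
  expect_equal(out$dmua, delta + log(mean(exp(-delta * L))) / L,
               tolerance = 1e-10)
  # non-positive frames are flagged and excluded
  bad <- cw_mbll(c(100, 0, 101), 10)
  expect_identical(attr(bad, "n_excluded"), 1L)
  expect_true(is.na(bad$dmua[2]))
})

test_that("chromophore unmixing round-trips exactly and flags singular
           systems", {
  tab <- extinction_table()
  truth <- cbind(do2hb = c(1, -0.5, 0), dhhb = c(0.2, 0.4, 0))
  e690 <- tab[tab$wavelength == 690, ]
  e830 <- tab[tab$wavelength == 830, ]
  dmua <- cbind(truth[, 1] * e690$o2hb + truth[, 2] * e690$hhb,
                truth[, 1] * e830$o2hb + truth[, 2] * e830$hhb)
  hb <- unmix_chromophores(dmua, c(690, 830), tab)
  expect_equal(hb$do2hb, truth[, "do2hb"], tolerance = 1e-10)
  expect_equal(hb$dhhb, truth[, "dhhb"], tolerance = 1e-10)
  expect_equal(unname(as.matrix(hb)[3, ]), c(0, 0))
  singular <- tibble::tibble(wavelength = c(690, 830),
                             o2hb = c(1, 2), hhb = c(2, 4))
  expect_error(unmix_chromophores(dmua, c(690, 830), singular), "singular")
})

test_that("photon-mean pathlength grows with source-detector distance", {
  props <- baseline_props_690()
  L1 <- mean_photon_pathlength(
    slab_td_reflectance(props, slab_geometry(), 1, grid_20ps))
  L4 <- mean_photon_pathlength(
    slab_td_reflectance(props, slab_geometry(), 4, grid_20ps))
  expect_gt(L4, L1)
  expect_gt(L1, 1)      # several cm even at short separation
})
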