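#' Homogeneous-model baseline fit of a time-averaged DTOF
#'
#' Recovers the baseline absorption and reduced scattering coefficients by
#' least-squares fitting of the homogeneous slab model (amplitude, `mua`,
#' `musp`) to a time-averaged DTOF, using Levenberg-Marquardt minimization of
#' log-count residuals over bins with adequate counts.
#'
#' @param mean_dtof Numeric vector: time-averaged DTOF counts on `grid`.
#' @param grid [time_grid()] of the DTOF.
#' @param sdd Source-detector distance (cm).
#' @param geom [slab_geometry()] used as the homogeneous model.
#' @param n Refractive index.
#' @param init Named list with starting values `mua`, `musp` (1/cm).
#' @param min_counts Bins with fewer mean counts are excluded from the fit.
#' @return An object of class `baseline_fit` with elements `mua`, `musp`,
#'   `amplitude`, `converged`, `deviance`, `n_bins_fit`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' grid <- time_grid(0, 5, 0.02)
#' curve <- slab_td_reflectance(optical_properties(0.11, 10, 1.4),
#'                              slab_geometry(), 4, grid)
#' fit <- fit_homogeneous_baseline(curve$value * 1e6 / sum(curve$value),
#'                                 grid, sdd = 4)
#' @export
fit_homogeneous_baseline <- function(mean_dtof, grid, sdd,
                                     geom = slab_geometry(), n = 1.4,
                                     init = list(mua = 0.1, musp = 10),
                                     min_counts = 10) {
  stopifnot(inherits(grid, "time_grid"), length(mean_dtof) == grid$n_bins)
  sel <- which(mean_dtof >= min_counts)
  if (length(sel) < 10)
    stop("fewer than 10 bins above `min_counts`; not enough signal to fit")
  ly <- log(mean_dtof[sel])
  resid_fn <- function(par) {
    props <- optical_properties(exp(par[2]), exp(par[3]), n)
    model <- slab_flux_density(grid$centers[sel], props$mua, props$musp, n,
                               geom$thickness, sdd) * grid$dt
    par[1] + log(model) - ly
  }
  start <- c(log_amp = 0, log_mua = log(init$mua), log_musp = log(init$musp))
  # center the amplitude start so LM only refines shape
  start[1] <- mean(ly) - mean(log(slab_flux_density(
    grid$centers[sel], init$mua, init$musp, n, geom$thickness, sdd) * grid$dt))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("Levenberg-Marquardt did not converge: ", fit$message)
  structure(list(mua = exp(fit$par[[2]]), musp = exp(fit$par[[3]]),
                 amplitude = exp(fit$par[[1]]), converged = converged,
                 deviance = fit$deviance, n_bins_fit = length(sel),
                 niter = fit$niter, message = fit$message),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf(
    "<baseline_fit> mua = %.5g 1/cm, musp = %.5g 1/cm (%s, %d bins, dev %.3g)\n",
    x$mua, x$musp, if (x$converged) "converged" else "NOT converged",
    x$n_bins_fit, x$deviance))
  invisible(x)
}

#' @method tidy baseline_fit
#' @export
tidy.baseline_fit <- function(x, ...) {
  tibble::tibble(term = c("mua", "musp", "amplitude"),
                 estimate = c(x$mua, x$musp, x$amplitude))
}

#' @method glance baseline_fit
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble::tibble(mua = x$mua, musp = x$musp, deviance = x$deviance,
                 converged = x$converged, nobs = x$n_bins_fit)
}

#' Time-dependent mean partial pathlengths of a bilayer medium
#'
#' Computes the per-layer time-dependent mean partial pathlength
#' `L_j(t) = -d ln R(t) / d mua_j` at the baseline optical properties by
#' central finite differences of the bilayer forward solution, together with
#' its gate-aggregated form `<L_j>_g` weighted by the baseline curve. In a
#' medium with matched refractive indices the partial pathlengths satisfy the
#' total-pathlength identity `L_up(t) + L_dw(t) = v t`.
#'
#' @param props_up,props_dw Baseline [optical_properties()] per layer.
#' @param geom [bilayer_geometry()].
#' @param sdd Source-detector distance (cm).
#' @param grid [time_grid()].
#' @param delta_mua Finite-difference step (1/cm). The default 5e-4 balances
#'   log-cancellation noise at low-count bins against finite-difference
#'   curvature (both far below the 0.5% level of the total-pathlength
#'   identity); the doubled-step consistency check guards the choice.
#' @param gates [gate_set()] for the aggregated pathlengths.
#' @param validate If `TRUE`, re-evaluates with a doubled step and errors if
#'   the two estimates disagree by more than 2% of the total pathlength `v t`
#'   on well-populated bins (curvature or cancellation in the finite
#'   difference).
#' @return An object of class `pathlength_operator`: per-bin `L_up`, `L_dw`
#'   (cm), the validity mask, the baseline curve, the gate table and the
#'   gate-aggregated pathlength matrix `L_gate` (gates x 2).
#' @examples
#' props <- optical_properties(0.1136, 10, 1.4)
#' op <- tmpp_pathlengths(props, props, bilayer_geometry(), sdd = 4,
#'                        grid = time_grid(0, 5, 0.02))
#' @export
tmpp_pathlengths <- function(props_up, props_dw, geom = bilayer_geometry(),
                             sdd, grid, delta_mua = 5e-4,
                             gates = default_gates(), validate = FALSE) {
  eval_log <- function(du, dd) {
    pu <- optical_properties(props_up$mua + du, props_up$musp, props_up$n)
    pd <- optical_properties(props_dw$mua + dd, props_dw$musp, props_dw$n)
    v <- bilayer_td_reflectance(pu, pd, geom, sdd, grid)$value
    out <- rep(NA_real_, length(v))
    out[v > 0] <- log(v[v > 0])
    out
  }
  baseline <- bilayer_td_reflectance(props_up, props_dw, geom, sdd, grid)
  fd <- function(step) {
    list(up = (eval_log(-step, 0) - eval_log(step, 0)) / (2 * step),
         dw = (eval_log(0, -step) - eval_log(0, step)) / (2 * step))
  }
  L <- fd(delta_mua)
  valid <- is.finite(L$up) & is.finite(L$dw) & baseline$value > 0
  if (validate) {
    L2 <- fd(2 * delta_mua)
    chk <- valid & baseline$value >= 1e-6 * max(baseline$value)
    scale <- light_speed(props_up$n) * grid$centers[chk]
    rel <- c(abs(L2$up[chk] - L$up[chk]) / scale,
             abs(L2$dw[chk] - L$dw[chk]) / scale)
    if (max(rel) > 0.02)
      stop(sprintf(paste0("finite-difference step failed the consistency ",
                          "check (max relative shift %.3g when doubling the ",
                          "step); adjust `delta_mua`"), max(rel)))
  }
  L_up <- ifelse(valid, pmax(L$up, 0), NA_real_)
  L_dw <- ifelse(valid, pmax(L$dw, 0), NA_real_)

  bin_gate <- findInterval(grid$centers,
                           c(gates$t_start, gates$t_end[nrow(gates)]))
  bin_gate[grid$centers >= gates$t_end[nrow(gates)]] <- 0L
  L_gate <- matrix(NA_real_, nrow(gates), 2,
                   dimnames = list(NULL, c("up", "dw")))
  for (g in seq_len(nrow(gates))) {
    sel <- which(bin_gate == g & valid)
    if (length(sel) == 0) next
    w <- baseline$value[sel]
    L_gate[g, ] <- c(sum(w * L_up[sel]), sum(w * L_dw[sel])) / sum(w)
  }
  structure(list(time = grid$centers, dt = grid$dt, L_up = L_up, L_dw = L_dw,
                 valid = valid, baseline = baseline, gates = gates,
                 L_gate = L_gate, v = light_speed(props_up$n),
                 delta_mua = delta_mua, sdd = sdd),
            class = "pathlength_operator")
}

#' @export
print.pathlength_operator <- function(x, ...) {
  cat(sprintf(
    "<pathlength_operator> %d bins, %d gates, sdd = %g cm, delta_mua = %g\n",
    length(x$time), nrow(x$gates), x$sdd, x$delta_mua))
  invisible(x)
}

#' Retrieve per-layer absorption changes from gated counts (TMPP inversion)
#'
#' Inverts `R(t) = R0(t) exp(-sum_j dmua_j L_j(t))` in its gated form: for each
#' frame, the weighted least-squares solution of
#' `ln(N_g0 / N_g) = sum_j dmua_j <L_j>_g` over usable gates, with weights
#' `N_g` (the delta-method inverse variance of `ln N_g` under Poisson counts)
#' and `N_g0` the whole-measurement mean gate counts. Gates whose mean counts
#' fall below `min_gate_counts` are excluded; zero-count gates enter the
#' logarithm with a +0.5 continuity correction. Passing per-bin gates (one bin
#' per gate) recovers the per-time-channel form of the method.
#'
#' @param gated A `gated_counts` object from [gate_counts()].
#' @param operator A `pathlength_operator` built on the same gates.
#' @param min_gate_counts Exclusion threshold on whole-measurement mean gate
#'   counts (default 10, keeping the log transform well-behaved).
#' @return A tibble `frame, time, dmua_up, dmua_dw, se_up, se_dw` (1/cm) with
#'   attributes `usable_gates` and `wavelength`.
#' @examples
#' # dmua <- tmpp_invert(gate_counts(dtof), operator)
#' @export
tmpp_invert <- function(gated, operator, min_gate_counts = 10) {
  stopifnot(inherits(gated, "gated_counts"),
            inherits(operator, "pathlength_operator"))
  if (!isTRUE(all.equal(as.data.frame(gated$gates),
                        as.data.frame(operator$gates))))
    stop("gated counts and pathlength operator use different gate sets")
  N0 <- colMeans(gated$counts)
  usable <- which(N0 >= min_gate_counts & is.finite(operator$L_gate[, 1]))
  if (length(usable) < 2)
    stop("fewer than 2 usable gates above `min_gate_counts`")
  A <- operator$L_gate[usable, , drop = FALSE]
  if (abs(stats::cor(A[, 1], A[, 2])) > 1 - 1e-10 || any(colSums(A^2) == 0))
    stop("gate pathlength columns are collinear; layers not separable")
  counts <- gated$counts[, usable, drop = FALSE]
  W <- counts + 0.5 * (counts == 0)
  Y <- log(rep(N0[usable], each = nrow(counts))) - log(W)
  dim(Y) <- dim(W)
  # per-frame 2x2 weighted normal equations, vectorized across frames
  M11 <- as.vector(W %*% (A[, 1]^2))
  M12 <- as.vector(W %*% (A[, 1] * A[, 2]))
  M22 <- as.vector(W %*% (A[, 2]^2))
  WY <- W * Y
  b1 <- as.vector(WY %*% A[, 1])
  b2 <- as.vector(WY %*% A[, 2])
  det <- M11 * M22 - M12^2
  if (any(det <= 0)) stop("singular design in TMPP inversion")
  dmua_up <- (M22 * b1 - M12 * b2) / det
  dmua_dw <- (M11 * b2 - M12 * b1) / det
  n <- nrow(counts)
  out <- tibble::tibble(frame = seq.int(0, n - 1),
                        time = seq.int(0, n - 1) / gated$fs,
                        dmua_up = dmua_up, dmua_dw = dmua_dw,
                        se_up = sqrt(M22 / det), se_dw = sqrt(M11 / det))
  structure(out, usable_gates = usable, wavelength = gated$wavelength,
            fs = gated$fs, class = class(out))
}

#' Photon-mean total pathlength of a baseline curve
#'
#' The count-weighted mean time of flight times the speed of light in the
#' medium: `<L> = v * sum(R t) / sum(R)`. Used as the pathlength scale of the
#' CW modified Beer-Lambert inversion, keeping it self-consistent with the
#' simulated physics instead of importing literature differential-pathlength
#' factors.
#'
#' @param curve A `reflectance_curve` (noiseless baseline).
#' @param n Refractive index of the medium.
#' @return Mean pathlength (cm).
#' @examples
#' curve <- slab_td_reflectance(optical_properties(0.11, 10, 1.4),
#'                              slab_geometry(), 4, time_grid(0, 5, 0.02))
#' mean_photon_pathlength(curve)
#' @export
mean_photon_pathlength <- function(curve, n = 1.4) {
  stopifnot(inherits(curve, "reflectance_curve"))
  light_speed(n) * sum(curve$value * curve$time) / sum(curve$value)
}

#' CW modified Beer-Lambert absorption changes
#'
#' `dmua(t) = -ln(I(t) / I0) / L`, with the baseline `I0` taken as the average
#' intensity over the entire measurement and `L` the photon-mean total
#' pathlength. Non-positive intensity frames are flagged and excluded (NA).
#'
#' @param intensity A tibble from [integrate_to_cw()] (columns `frame`, `time`,
#'   `intensity`) or a numeric vector.
#' @param pathlength Mean pathlength (cm), e.g. [mean_photon_pathlength()].
#' @return A tibble `frame, time, dmua` with attribute `n_excluded`.
#' @examples
#' cw_mbll(tibble::tibble(frame = 0:3, time = 0:3,
#'                        intensity = c(100, 99, 101, 100)), pathlength = 25)
#' @export
cw_mbll <- function(intensity, pathlength) {
  stopifnot(pathlength > 0)
  if (is.numeric(intensity)) {
    intensity <- tibble::tibble(frame = seq_along(intensity) - 1,
                                time = NA_real_, intensity = intensity)
  }
  ok <- intensity$intensity > 0
  i0 <- mean(intensity$intensity[ok])
  dmua <- rep(NA_real_, nrow(intensity))
  dmua[ok] <- -log(intensity$intensity[ok] / i0) / pathlength
  structure(tibble::tibble(frame = intensity$frame, time = intensity$time,
                           dmua = dmua),
            n_excluded = sum(!ok), pathlength = pathlength,
            class = c("tbl_df", "tbl", "data.frame"))
}

#' Unmix absorption changes into hemoglobin concentration changes
#'
#' Solves the 2x2 Beer's-law system per frame:
#' `dmua(lambda) = e_O2Hb(lambda) dO2Hb + e_HHb(lambda) dHHb`.
#'
#' @param dmua A matrix or data frame with one column of absorption changes
#'   (1/cm) per wavelength, in the order of `wavelengths`.
#' @param wavelengths The two wavelengths (nm), present in `table`.
#' @param table Extinction factors from [extinction_table()].
#' @return A tibble `do2hb, dhhb` (uM) with attribute `condition` (the
#'   condition number of the extinction matrix).
#' @examples
#' unmix_chromophores(cbind(c(0.001, 0), c(0.0005, 0)), c(690, 830))
#' @export
unmix_chromophores <- function(dmua, wavelengths = c(690, 830),
                               table = extinction_table()) {
  dmua <- as.matrix(dmua)
  stopifnot(ncol(dmua) == 2, length(wavelengths) == 2)
  rows <- lapply(wavelengths, function(wl) {
    r <- table[table$wavelength == wl, ]
    if (nrow(r) != 1) stop("wavelength ", wl, " nm not in extinction table")
    c(r$o2hb, r$hhb)
  })
  E <- do.call(rbind, rows)
  cond <- kappa(E, exact = TRUE)
  if (cond > 1e8) stop("extinction matrix is singular or near-singular ",
                       "(condition number ", format(cond), ")")
  sol <- t(solve(E, t(dmua)))
  structure(tibble::tibble(do2hb = sol[, 1], dhhb = sol[, 2]),
            condition = cond, class = c("tbl_df", "tbl", "data.frame"))
}
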