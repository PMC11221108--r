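#' Acquisition settings for a synthetic fNIRS measurement
#'
#' @param n_tot_avg Average total photon count per DTOF frame at baseline
#'   optical properties (the photon budget), `> 0`.
#' @param tmeas Measurement length (s).
#' @param fs Sampling rate (Hz); `tmeas * fs` must be an integer.
#' @param sdd Source-detector distance (cm).
#' @param wavelengths Wavelengths (nm).
#' @param seed Integer master seed; one independent noise sub-stream is derived
#'   per (wavelength, SDD).
#' @return An object of class `acquisition_settings`.
#' @examples
#' acquisition_settings(1e6, tmeas = 900, fs = 20, sdd = 4)
#' @export
acquisition_settings <- function(n_tot_avg, tmeas, fs, sdd,
                                 wavelengths = c(690, 830), seed = 1) {
  stopifnot(n_tot_avg > 0, fs > 0, tmeas > 0, sdd > 0)
  if (abs(round(tmeas * fs) - tmeas * fs) > 1e-9)
    stop("`tmeas * fs` must be an integer number of frames")
  structure(list(n_tot_avg = n_tot_avg, tmeas = tmeas, fs = fs, sdd = sdd,
                 wavelengths = wavelengths, seed = seed,
                 n_frames = as.integer(round(tmeas * fs))),
            class = "acquisition_settings")
}

#' Forward operator for per-frame expectation curves
#'
#' A forward operator maps a frame-by-frame absorption trajectory to noiseless
#' per-bin expectation curves. For the homogeneous slab the exact absorption
#' factorization `R(t; mua) = R(t; 0) exp(-mua v t)` is used, so each frame
#' costs one exponential per bin. For the bilayer cylinder the solution is
#' precomputed on a small rectangular grid of `(mua_up, mua_dw)` nodes spanning
#' `span_frac` around baseline (nodes only along perturbed dimensions) and
#' interpolated bilinearly in `log R` per time bin; the TMPP inversion never
#' uses this grid, so retrieval is not circular.
#'
#' @param props Baseline [optical_properties()] (slab), or the UP layer for
#'   the bilayer operator.
#' @param geom [slab_geometry()] or [bilayer_geometry()].
#' @param sdd Source-detector distance (cm).
#' @param grid [time_grid()].
#' @param wavelength Wavelength tag (nm).
#' @return A `forward_operator` object used by [synthesize_dtof_series()].
#' @examples
#' op <- slab_forward_operator(optical_properties(0.11, 10, 1.4),
#'                             slab_geometry(), sdd = 4, time_grid(0, 5, 0.008))
#' @export
slab_forward_operator <- function(props, geom = slab_geometry(), sdd, grid,
                                  wavelength = NA_real_) {
  baseline <- slab_td_reflectance(props, geom, sdd, grid, wavelength)
  structure(list(type = "slab", props = props, geom = geom, sdd = sdd,
                 grid = grid, wavelength = wavelength,
                 baseline = baseline, v = light_speed(props$n)),
            class = "forward_operator")
}

#' @rdname slab_forward_operator
#' @param props_up,props_dw Baseline [optical_properties()] per layer.
#' @param perturbed Named logical vector: which of `up`, `dw` carry absorption
#'   changes (grid nodes are laid out only along perturbed dimensions).
#' @param span_frac Half-width of the node grid as a fraction of the baseline
#'   absorption (default 0.015, comfortably enclosing 1% oscillations).
#' @param n_nodes Nodes per perturbed dimension (default 5).
#' @export
bilayer_forward_operator <- function(props_up, props_dw,
                                     geom = bilayer_geometry(), sdd, grid,
                                     wavelength = NA_real_,
                                     perturbed = c(up = TRUE, dw = TRUE),
                                     span_frac = 0.015, n_nodes = 5) {
  stopifnot(n_nodes >= 2 || !any(perturbed))
  node_axis <- function(mua, on) {
    if (on) mua * (1 + seq(-span_frac, span_frac, length.out = n_nodes)) else mua
  }
  mua_up_nodes <- node_axis(props_up$mua, isTRUE(perturbed[["up"]]))
  mua_dw_nodes <- node_axis(props_dw$mua, isTRUE(perturbed[["dw"]]))
  curves <- vector("list", length(mua_up_nodes) * length(mua_dw_nodes))
  dim(curves) <- c(length(mua_up_nodes), length(mua_dw_nodes))
  for (i in seq_along(mua_up_nodes)) {
    for (j in seq_along(mua_dw_nodes)) {
      pu <- optical_properties(mua_up_nodes[i], props_up$musp, props_up$n)
      pd <- optical_properties(mua_dw_nodes[j], props_dw$musp, props_dw$n)
      curves[[i, j]] <- bilayer_td_reflectance(pu, pd, geom, sdd, grid,
                                               wavelength)$value
    }
  }
  baseline_values <- bilayer_td_reflectance(props_up, props_dw, geom, sdd, grid,
                                            wavelength)$value
  # bins usable for log interpolation: positive at every node
  positive <- Reduce(`&`, lapply(curves, function(v) v > 0))
  log_curves <- lapply(curves, function(v) {
    out <- rep(-Inf, length(v))
    out[positive] <- log(v[positive])
    out
  })
  dim(log_curves) <- dim(curves)
  structure(list(type = "bilayer", props_up = props_up, props_dw = props_dw,
                 geom = geom, sdd = sdd, grid = grid, wavelength = wavelength,
                 baseline = new_reflectance_curve(grid, baseline_values,
                                                  wavelength, sdd),
                 v = light_speed(props_up$n),
                 mua_up_nodes = mua_up_nodes, mua_dw_nodes = mua_dw_nodes,
                 log_curves = log_curves, positive = positive),
            class = "forward_operator")
}

# Per-frame noiseless expectation curves (frames x bins), unnormalized (same
# units as the baseline curve). mua_up / mua_dw are per-frame absorption
# trajectories; for the slab operator only mua_up is used (whole medium).
forward_expectation <- function(op, mua_up, mua_dw = NULL) {
  if (op$type == "slab") {
    dmua <- mua_up - op$props$mua
    E <- exp(outer(dmua, -op$v * op$grid$centers))
    E * rep(op$baseline$value, each = length(dmua))
  } else {
    interp_bilinear_log(op, mua_up,
                        if (is.null(mua_dw)) rep(op$props_dw$mua, length(mua_up))
                        else mua_dw)
  }
}

interp_axis <- function(nodes, x) {
  if (length(nodes) == 1) {
    if (any(abs(x - nodes) > 1e-12 * max(abs(nodes), 1)))
      stop("absorption trajectory varies along a dimension the operator ",
           "declared unperturbed")
    return(list(lo = rep(1L, length(x)), w = rep(0, length(x))))
  }
  if (any(x < min(nodes) - 1e-12) || any(x > max(nodes) + 1e-12))
    stop("absorption trajectory leaves the precomputed node span; ",
         "increase `span_frac`")
  i <- pmin(pmax(findInterval(x, nodes), 1L), length(nodes) - 1L)
  list(lo = i, w = (x - nodes[i]) / (nodes[i + 1L] - nodes[i]))
}

interp_bilinear_log <- function(op, mua_up, mua_dw) {
  ax_u <- interp_axis(op$mua_up_nodes, mua_up)
  ax_d <- interp_axis(op$mua_dw_nodes, mua_dw)
  n_u <- length(op$mua_up_nodes)
  n_d <- length(op$mua_dw_nodes)
  n_frames <- length(mua_up)
  # weight matrix (frames x nodes), 4 non-zero entries per row
  W <- matrix(0, n_frames, n_u * n_d)
  idx <- function(i, j) (j - 1L) * n_u + i
  rows <- seq_len(n_frames)
  hi_u <- pmin(ax_u$lo + 1L, n_u)
  hi_d <- pmin(ax_d$lo + 1L, n_d)
  W[cbind(rows, idx(ax_u$lo, ax_d$lo))] <-
    W[cbind(rows, idx(ax_u$lo, ax_d$lo))] + (1 - ax_u$w) * (1 - ax_d$w)
  W[cbind(rows, idx(hi_u, ax_d$lo))] <-
    W[cbind(rows, idx(hi_u, ax_d$lo))] + ax_u$w * (1 - ax_d$w)
  W[cbind(rows, idx(ax_u$lo, hi_d))] <-
    W[cbind(rows, idx(ax_u$lo, hi_d))] + (1 - ax_u$w) * ax_d$w
  W[cbind(rows, idx(hi_u, hi_d))] <-
    W[cbind(rows, idx(hi_u, hi_d))] + ax_u$w * ax_d$w
  L <- do.call(rbind, lapply(seq_len(n_u * n_d), function(k) op$log_curves[[k]]))
  L[!is.finite(L)] <- 0 # masked bins, zeroed below
  E <- exp(W %*% L)
  E[, !op$positive] <- 0
  E
}

#' Synthesize a Poisson-noise DTOF series
#'
#' Turns a hemoglobin trajectory into measured photon-count histograms. For
#' each wavelength the forward operator supplies the per-frame noiseless curve;
#' a single scale factor, fixed so the curve at baseline (time-averaged)
#' optical properties integrates to `n_tot_avg`, converts it to per-bin count
#' expectations, and every bin of every frame receives an independent Poisson
#' draw. The shared scale factor makes detected totals track absorption
#' changes, which is what creates the CW signal.
#'
#' @param hemo A `hemo_series` from [make_hemo_series()]; its layers must match
#'   the operator type (`WHOLE` for slab, `UP`/`DW` for bilayer).
#' @param operators Named list of `forward_operator` objects keyed by
#'   wavelength (names like `"690"`), or a single operator.
#' @param settings [acquisition_settings()]; `fs * tmeas` must equal the number
#'   of frames in `hemo`, and `sdd` must match the operators.
#' @param table Extinction factors from [extinction_table()].
#' @return A named list of `dtof_series` objects (one per wavelength); each
#'   holds the integer count matrix (frames x bins), the time grid, the scale
#'   factor and the derived noise seed.
#' @examples
#' hemo <- make_hemo_series(hemo_baseline(),
#'                          list(perturbation_spec(0.01, 1, layer = "WHOLE")),
#'                          tmeas = 10, fs = 20, seed = 1)
#' op <- slab_forward_operator(optical_properties(0.1136, 10, 1.4),
#'                             slab_geometry(), 4, time_grid(0, 5, 0.02), 690)
#' dtof <- synthesize_dtof_series(hemo, list("690" = op),
#'                                acquisition_settings(1e5, 10, 20, 4, 690))
#' @export
synthesize_dtof_series <- function(hemo, operators, settings,
                                   table = extinction_table()) {
  stopifnot(inherits(hemo, "hemo_series"),
            inherits(settings, "acquisition_settings"))
  if (inherits(operators, "forward_operator")) {
    operators <- stats::setNames(list(operators),
                                 format(operators$wavelength))
  }
  layers <- unique(hemo$layer)
  n_frames <- length(unique(hemo$frame))
  if (n_frames != settings$n_frames)
    stop("hemo series frame count does not match settings")

  out <- purrr::imap(operators, function(op, wl_name) {
    wl <- as.numeric(wl_name)
    if (op$type == "slab") {
      stopifnot(identical(layers, "WHOLE"))
      h <- hemo[hemo$layer == "WHOLE", ]
      mua_up <- hemoglobin_to_mua(h$o2hb, h$hhb, wl, table)
      mua_dw <- NULL
    } else {
      stopifnot(all(c("UP", "DW") %in% layers))
      hu <- hemo[hemo$layer == "UP", ]
      hd <- hemo[hemo$layer == "DW", ]
      mua_up <- hemoglobin_to_mua(hu$o2hb, hu$hhb, wl, table)
      mua_dw <- hemoglobin_to_mua(hd$o2hb, hd$hhb, wl, table)
    }
    E <- forward_expectation(op, mua_up, mua_dw)
    scale <- settings$n_tot_avg / sum(op$baseline$value)
    E <- E * scale
    if (any(!is.finite(E))) stop("non-finite count expectations")
    noise_seed <- derive_seed(settings$seed,
                              paste("dtof", wl_name, settings$sdd))
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(noise_seed)
    counts <- matrix(stats::rpois(length(E), E), nrow = nrow(E))
    restore_rng(old)
    structure(list(counts = counts, time = op$grid$centers, dt = op$grid$dt,
                   fs = attr(hemo, "fs"), wavelength = wl, sdd = settings$sdd,
                   n_tot_avg = settings$n_tot_avg, scale = scale,
                   baseline_expect = op$baseline$value * scale,
                   seed = noise_seed),
              class = "dtof_series")
  })
  out
}

#' @export
print.dtof_series <- function(x, ...) {
  cat(sprintf(
    "<dtof_series> %d frames x %d bins, fs = %g Hz, sdd = %g cm, %g nm, Ntot = %g\n",
    nrow(x$counts), ncol(x$counts), x$fs, x$sdd, x$wavelength, x$n_tot_avg))
  invisible(x)
}

#' @method as_tibble dtof_series
#' @export
as_tibble.dtof_series <- function(x, ...) {
  tibble::tibble(frame = rep(seq_len(nrow(x$counts)) - 1L, ncol(x$counts)),
                 time = rep(x$time, each = nrow(x$counts)),
                 counts = as.vector(x$counts))
}

#' Convolve a reflectance curve with an instrument response function
#'
#' Discrete causal convolution with a unit-area kernel on the same time grid.
#' A delta kernel (all mass in the first bin) returns the input unchanged; any
#' unit-area kernel preserves the curve integral.
#'
#' @param curve A `reflectance_curve`.
#' @param irf Numeric vector of kernel bin weights on the same grid as `curve`
#'   (non-negative, summing to 1), or a `reflectance_curve` on the same grid.
#' @return A `reflectance_curve` of the convolved values.
#' @examples
#' grid <- time_grid(0, 5, 0.02)
#' curve <- slab_td_reflectance(optical_properties(0.1, 10, 1.4),
#'                              slab_geometry(), 3, grid)
#' irf <- gaussian_irf(grid, fwhm = 0.1)
#' smeared <- convolve_irf(curve, irf)
#' @export
convolve_irf <- function(curve, irf) {
  stopifnot(inherits(curve, "reflectance_curve"))
  if (inherits(irf, "reflectance_curve")) {
    if (!isTRUE(all.equal(irf$time, curve$time)) ||
        attr(irf, "dt") != attr(curve, "dt"))
      stop("IRF and curve are on different time grids")
    irf <- irf$value
  }
  if (length(irf) != nrow(curve))
    stop("IRF and curve are on different time grids")
  if (any(irf < 0)) stop("IRF must be non-negative")
  if (abs(sum(irf) - 1) > 1e-8) stop("IRF must be normalized to unit area")
  n <- length(irf)
  # causal linear convolution via zero-padded FFT, truncated to the window
  m <- stats::nextn(2L * n, 2)
  conv <- Re(stats::fft(stats::fft(c(curve$value, rep(0, m - n))) *
                          stats::fft(c(irf, rep(0, m - n))), inverse = TRUE)) / m
  out <- curve
  out$value <- pmax(conv[seq_len(n)], 0)
  out
}

#' @rdname convolve_irf
#' @param grid [time_grid()].
#' @param fwhm Full width at half maximum of the Gaussian kernel (ns).
#' @param t0 Kernel center (ns) relative to the window start.
#' @export
gaussian_irf <- function(grid, fwhm, t0 = 4 * fwhm) {
  stopifnot(inherits(grid, "time_grid"), fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(grid$centers - grid$t_start - t0)^2 / (2 * sigma^2))
  new_reflectance_curve(grid, w / sum(w))
}

#' Time gates over a DTOF window
#'
#' Builds an ordered set of non-overlapping, contiguous, half-open time windows
#' `[start, end)`. The default reproduces ten 500-ps gates covering 0 to 5 ns.
#'
#' @param breaks Increasing vector of gate edges (ns); gate `g` is
#'   `[breaks[g], breaks[g+1])`.
#' @return A tibble `gate, t_start, t_end` of class `gate_set`.
#' @examples
#' default_gates()
#' @export
gate_set <- function(breaks = seq(0, 5, by = 0.5)) {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  out <- tibble::tibble(gate = seq_len(length(breaks) - 1L),
                        t_start = breaks[-length(breaks)],
                        t_end = breaks[-1])
  structure(out, class = c("gate_set", class(out)))
}

#' @rdname gate_set
#' @export
default_gates <- function() gate_set()

#' Sum DTOF counts within time gates
#'
#' @param dtof A `dtof_series`.
#' @param gates A [gate_set()] lying within the DTOF window.
#' @return An object of class `gated_counts`: integer matrix `counts`
#'   (frames x gates) plus the gate table, baseline per-gate expectations and
#'   acquisition metadata. When the gates tile the full window, per-frame gate
#'   sums equal per-frame DTOF totals exactly.
#' @examples
#' # gate_counts(dtof, default_gates())
#' @export
gate_counts <- function(dtof, gates = default_gates()) {
  stopifnot(inherits(dtof, "dtof_series"), inherits(gates, "gate_set"))
  lo <- dtof$time[1] - dtof$dt / 2
  hi <- dtof$time[length(dtof$time)] + dtof$dt / 2
  if (min(gates$t_start) < lo - 1e-9 || max(gates$t_end) > hi + 1e-9)
    stop("gates extend outside the DTOF time window")
  bin_gate <- findInterval(dtof$time, c(gates$t_start, gates$t_end[nrow(gates)]),
                           left.open = FALSE, rightmost.closed = FALSE)
  bin_gate[dtof$time >= gates$t_end[nrow(gates)]] <- 0L
  G <- matrix(0L, nrow(dtof$counts), nrow(gates))
  base_g <- numeric(nrow(gates))
  for (g in seq_len(nrow(gates))) {
    sel <- which(bin_gate == g)
    G[, g] <- if (length(sel) == 1) dtof$counts[, sel]
              else as.integer(rowSums(dtof$counts[, sel, drop = FALSE]))
    base_g[g] <- sum(dtof$baseline_expect[sel])
  }
  structure(list(counts = G, gates = gates, baseline_expect = base_g,
                 fs = dtof$fs, wavelength = dtof$wavelength, sdd = dtof$sdd,
                 n_tot_avg = dtof$n_tot_avg),
            class = "gated_counts")
}

#' @export
print.gated_counts <- function(x, ...) {
  cat(sprintf("<gated_counts> %d frames x %d gates, fs = %g Hz, sdd = %g cm\n",
              nrow(x$counts), ncol(x$counts), x$fs, x$sdd))
  invisible(x)
}

#' Integrate a DTOF series to a CW intensity time series
#'
#' Per-frame total photon counts, the synthetic continuous-wave signal.
#'
#' @param dtof A `dtof_series`.
#' @return A tibble `frame, time, intensity` with attribute `fs`.
#' @examples
#' # integrate_to_cw(dtof)
#' @export
integrate_to_cw <- function(dtof) {
  stopifnot(inherits(dtof, "dtof_series"))
  n <- nrow(dtof$counts)
  out <- tibble::tibble(frame = seq.int(0, n - 1),
                        time = seq.int(0, n - 1) / dtof$fs,
                        intensity = rowSums(dtof$counts))
  structure(out, fs = dtof$fs, class = class(out))
}
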