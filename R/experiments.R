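#' Named simulation cases
#'
#' The frozen grid of named simulation cases: four homogeneous-medium sweeps
#' (`H_Ntot`, `H_Tmeas`, `H_fs`, `H_SDD`) exploring the photon budget,
#' measurement length, sampling rate and source-detector distance, and six
#' bilayer cases (`B_UP` ... `B_AmpFreq`) imposing oscillations in the
#' superficial and/or deep layer. Amplitudes are percent of baseline
#' concentration; frequencies in Hz; `tmeas` in minutes.
#'
#' @return A tibble with one row per case; list-columns hold the swept values.
#' @examples
#' scenario_cases()
#' @export
scenario_cases <- function() {
  tibble::tribble(
    ~case,       ~geometry,     ~n_tot,            ~tmeas_min,   ~fs,          ~sdd,          ~amp_up, ~freq_up, ~amp_dw, ~freq_dw, ~sweep,
    "H_Ntot",    "homogeneous", c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       1,        NA,      NA,       "n_tot",
    "H_Tmeas",   "homogeneous", 1e6,               c(5, 10, 15), 20,           c(1, 4),       1,       1,        NA,      NA,       "tmeas",
    "H_fs",      "homogeneous", 1e6,               15,           c(5, 10, 20), c(1, 4),       1,       1,        NA,      NA,       "fs",
    "H_SDD",     "homogeneous", 1e6,               15,           20,           1:6,           1,       1,        NA,      NA,       "sdd",
    "B_UP",      "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       1,        NA,      NA,       "n_tot",
    "B_DW",      "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       NA,      NA,       1,       1,        "n_tot",
    "B_UPDW",    "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       1,        1,       1,        "n_tot",
    "B_Amp",     "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       1,        0.5,     1,        "n_tot",
    "B_Freq",    "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       0.2,      1,       1,        "n_tot",
    "B_AmpFreq", "bilayer",     c(1e4, 1e5, 1e6),  15,           20,           c(1, 4),       1,       0.2,      0.5,     1,        "n_tot"
  )
}

#' Build a scenario configuration
#'
#' Assembles everything one simulation case needs: medium geometry and
#' baselines, perturbation specifications, acquisition grids and analysis
#' settings. Named cases start from [scenario_cases()]; any grid component can
#' be overridden (e.g. a single `n_tot`, or a shorter `tmeas` for a scaled-down
#' run).
#'
#' @param case A case id from [scenario_cases()].
#' @param seed Master seed; perturbation phases and Poisson noise streams are
#'   derived from it.
#' @param n_tot,tmeas,fs,sdd Optional overrides of the swept grids (`tmeas` in
#'   seconds).
#' @param amp_up,amp_dw Optional overrides of the perturbation amplitudes, in
#'   percent of baseline (0 disables a layer's perturbation; for homogeneous
#'   cases `amp_up` drives the whole-medium oscillation).
#' @param freq_up,freq_dw Optional overrides of the perturbation frequencies
#'   (Hz).
#' @param wavelengths Wavelengths (nm), default `c(690, 830)`.
#' @param phase_mode `"random"` (independent random phase per layer/species),
#'   `"in_phase"` or `"out_of_phase"` (deep-layer phase locked to the
#'   superficial phase, offset 0 or pi).
#' @param dt Time resolution of the forward grid (ns); defaults to 0.008 for
#'   homogeneous and 0.02 for bilayer cases.
#' @param threshold Peak significance threshold (dB), default 15.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config("H_Ntot", seed = 7)
#' scenario_config("B_DW", n_tot = 1e6, sdd = 1)
#' @export
scenario_config <- function(case, seed = 1, n_tot = NULL, tmeas = NULL,
                            fs = NULL, sdd = NULL, wavelengths = c(690, 830),
                            phase_mode = c("random", "in_phase", "out_of_phase"),
                            dt = NULL, threshold = 15,
                            amp_up = NULL, amp_dw = NULL,
                            freq_up = NULL, freq_dw = NULL) {
  cases <- scenario_cases()
  if (!case %in% cases$case)
    stop("unknown case `", case, "`; see scenario_cases()")
  row <- cases[cases$case == case, ]
  phase_mode <- match.arg(phase_mode)
  geometry <- row$geometry
  cfg <- list(
    case = case, geometry = geometry,
    n_tot = n_tot %||% row$n_tot[[1]],
    tmeas = tmeas %||% (row$tmeas_min[[1]] * 60),
    fs = fs %||% row$fs[[1]],
    sdd = sdd %||% row$sdd[[1]],
    sweep = row$sweep,
    amp_up = (amp_up %||% row$amp_up) / 100,
    freq_up = freq_up %||% row$freq_up,
    amp_dw = (amp_dw %||% row$amp_dw) / 100,
    freq_dw = freq_dw %||% row$freq_dw,
    wavelengths = wavelengths, seed = seed, phase_mode = phase_mode,
    dt = dt %||% if (geometry == "homogeneous") 0.008 else 0.02,
    threshold = threshold,
    baseline = hemo_baseline(), scattering = scattering_law(),
    table = extinction_table(), n_index = 1.4,
    slab = slab_geometry(5), bilayer = bilayer_geometry(10, 1, 4)
  )
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (%s): Ntot {%s}, Tmeas {%s} s, fs {%s} Hz, SDD {%s} cm\n",
              x$case, x$geometry, paste(x$n_tot, collapse = ", "),
              paste(x$tmeas, collapse = ", "), paste(x$fs, collapse = ", "),
              paste(x$sdd, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Perturbation specs for a configuration; resolves in-/out-of-phase locking
# into explicit phases (the deep layer copies the superficial phase, shifted
# by pi when out of phase).
config_perturbations <- function(config) {
  layer_specs <- function(amp, freq, layer, phases = NULL) {
    if (is.na(amp) || amp == 0) return(list())
    purrr::map(c("O2Hb", "HHb"), function(sp) {
      ph <- if (is.null(phases)) "random" else phases[[sp]]
      perturbation_spec(amp, freq, phase = ph, layer = layer, species = sp)
    })
  }
  if (config$geometry == "homogeneous") {
    return(layer_specs(config$amp_up, config$freq_up, "WHOLE"))
  }
  if (config$phase_mode == "random") {
    return(c(layer_specs(config$amp_up, config$freq_up, "UP"),
             layer_specs(config$amp_dw, config$freq_dw, "DW")))
  }
  # locked phases: draw the superficial phase the way make_hemo_series would
  draw <- function(layer, sp, freq) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(derive_seed(config$seed, paste("phase", layer, sp, freq)))
    stats::runif(1, 0, 2 * pi)
  }
  up_ph <- list(O2Hb = draw("UP", "O2Hb", config$freq_up),
                HHb = draw("UP", "HHb", config$freq_up))
  off <- if (config$phase_mode == "in_phase") 0 else pi
  dw_ph <- lapply(up_ph, function(p) (p + off) %% (2 * pi))
  c(layer_specs(config$amp_up, config$freq_up, "UP", up_ph),
    layer_specs(config$amp_dw, config$freq_dw, "DW", dw_ph))
}

config_layers <- function(config) {
  if (config$geometry == "homogeneous") "WHOLE" else c("UP", "DW")
}

# first imposed frequency (reporting target); 1 Hz for unperturbed configs
config_target_freq <- function(config) {
  f <- c(config$freq_up, config$freq_dw)
  a <- c(config$amp_up, config$amp_dw)
  f <- f[!is.na(f) & !is.na(a) & a > 0]
  if (length(f) == 0) 1 else f[1]
}

config_baseline_props <- function(config, wavelength) {
  mua <- hemoglobin_to_mua(config$baseline$o2hb, config$baseline$hhb,
                           wavelength, config$table)
  optical_properties(mua, scattering_at(config$scattering, wavelength),
                     config$n_index)
}

# Cached forward operator for one (wavelength, sdd); bilayer node grids span
# only the perturbed dimensions.
config_operator <- function(config, wavelength, sdd, cache = NULL) {
  key <- paste(config$geometry, wavelength, sdd)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  grid <- time_grid(0, 5, config$dt)
  props <- config_baseline_props(config, wavelength)
  op <- if (config$geometry == "homogeneous") {
    slab_forward_operator(props, config$slab, sdd, grid, wavelength)
  } else {
    bilayer_forward_operator(
      props, props, config$bilayer, sdd, grid, wavelength,
      perturbed = c(up = isTRUE(config$amp_up > 0),
                    dw = isTRUE(config$amp_dw > 0)))
  }
  if (!is.null(cache)) cache[[key]] <- op
  op
}

#' Run a scenario and tabulate CW spectral metrics
#'
#' Executes the full pipeline (hemodynamics, forward model, Poisson DTOF
#' synthesis, CW integration, detrending, periodogram, noise floor, contrast)
#' for every point of the configuration grid (swept parameter x SDD x
#' wavelength) and returns one record per point.
#'
#' @param config A [scenario_config()].
#' @param detrend_order Polynomial detrending order (default 3).
#' @return A `result table` tibble: one row per (sweep value, SDD, wavelength)
#'   with the 1-Hz (target) peak PSD, noise floor `epsilon`, contrast in dB,
#'   second-harmonic contrast, significance flags and provenance (seed, frame
#'   count).
#' @examples
#' cfg <- scenario_config("H_Ntot", n_tot = c(1e4, 1e5), sdd = 4,
#'                        tmeas = 60, wavelengths = 690)
#' run_case(cfg)
#' @export
run_case <- function(config, detrend_order = 3) {
  stopifnot(inherits(config, "scenario_config"))
  cache <- new.env(parent = emptyenv())
  perts <- config_perturbations(config)
  f0 <- config_target_freq(config)
  grid_tbl <- tidyr::expand_grid(
    n_tot = config$n_tot, tmeas = config$tmeas, fs = config$fs,
    sdd = config$sdd, wavelength = config$wavelengths)
  rows <- purrr::pmap(grid_tbl, function(n_tot, tmeas, fs, sdd, wavelength) {
    hemo <- make_hemo_series(config$baseline, perts, tmeas, fs,
                             seed = config$seed,
                             layers = config_layers(config))
    op <- config_operator(config, wavelength, sdd, cache)
    settings <- acquisition_settings(n_tot, tmeas, fs, sdd, wavelength,
                                     seed = config$seed)
    dtof <- synthesize_dtof_series(hemo, stats::setNames(list(op),
                                                         format(wavelength)),
                                   settings, config$table)[[1]]
    cw <- integrate_to_cw(dtof)
    spec <- periodogram_psd(detrend_poly(cw$intensity, detrend_order), fs)
    eps <- noise_floor(spec)
    pk <- peak_report(spec, f0, config$threshold, eps)
    second <- if (2 * f0 <= fs / 2) {
      second_harmonic_check(spec, f0, config$threshold, eps)
    } else NULL
    tibble::tibble(
      case = config$case, n_tot = n_tot, tmeas = tmeas, fs = fs, sdd = sdd,
      wavelength = wavelength, target_frequency = f0,
      peak_psd = pk$psd, epsilon = as.numeric(eps),
      contrast = pk$contrast, contrast_db = pk$contrast_db,
      significant = pk$significant,
      second_contrast_db = if (is.null(second)) NA_real_
                           else second$contrast_db,
      second_significant = if (is.null(second)) NA else second$significant,
      n_frames = nrow(cw), seed = config$seed)
  })
  out <- purrr::list_rbind(rows)
  structure(out, sweep = config$sweep, class = class(out))
}

#' Power-law scaling fits and invariance checks over a parameter sweep
#'
#' Fits `metric = prefactor * value^exponent` in log-log space for the peak
#' PSD, the noise floor and the peak contrast against the swept parameter,
#' separately per (SDD, wavelength), and reports each metric's maximum
#' relative deviation from its mean across the sweep (the band used to assert
#' invariance is typically 3%).
#'
#' @param results A result table from [run_case()].
#' @param param The swept column: `"n_tot"`, `"tmeas"`, `"fs"` or `"sdd"`.
#' @return A tibble `sdd, wavelength, metric, exponent, prefactor, r_squared,
#'   max_dev_pct` (with `sdd` absent when it is the swept parameter).
#' @examples
#' cfg <- scenario_config("H_Ntot", n_tot = c(1e4, 1e5, 1e6), sdd = 4,
#'                        tmeas = 60, wavelengths = 690)
#' scaling_report(run_case(cfg), "n_tot")
#' @export
scaling_report <- function(results, param = attr(results, "sweep")) {
  stopifnot(param %in% c("n_tot", "tmeas", "fs", "sdd"),
            param %in% names(results))
  group_cols <- setdiff(c("sdd", "wavelength"), param)
  long <- results |>
    dplyr::select(dplyr::all_of(c(group_cols, param,
                                  "peak_psd", "epsilon", "contrast"))) |>
    tidyr::pivot_longer(c("peak_psd", "epsilon", "contrast"),
                        names_to = "metric", values_to = "value")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "metric")))) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      fit = list(fit_power_law(.data[[param]][seq_len(dplyr::n())],
                               .data$value)),
      max_dev_pct = 100 * max(abs(.data$value - mean(.data$value))) /
        mean(.data$value),
      .groups = "drop") |>
    dplyr::mutate(exponent = purrr::map_dbl(.data$fit, "exponent"),
                  prefactor = purrr::map_dbl(.data$fit, "prefactor"),
                  r_squared = purrr::map_dbl(.data$fit, "r_squared")) |>
    dplyr::select(-"fit")
}

#' Per-gate spectral contrast profile of a bilayer case
#'
#' Synthesizes the bilayer measurement, slices each DTOF into time gates,
#' computes the periodogram contrast of each gate's photon-count series at the
#' target frequency, and appends the CW (full-integral) channel.
#'
#' @param config A bilayer [scenario_config()]; its `n_tot` and `sdd` entries
#'   should be scalars (override them in [scenario_config()]).
#' @param wavelength Reporting wavelength (nm), default 690.
#' @param gates [gate_set()], default ten 500-ps gates over 0-5 ns.
#' @param f0 Target frequency (Hz), default the configuration's imposed
#'   frequency.
#' @param detrend_order Polynomial detrending order.
#' @return A tibble with one row per gate plus a `"CW"` row: `gate`,
#'   `baseline_mean_counts`, `peak_psd`, `epsilon`, `contrast_db`,
#'   `significant`.
#' @examples
#' cfg <- scenario_config("B_UP", n_tot = 1e6, sdd = 1, tmeas = 60)
#' # gate_contrast_profile(cfg)
#' @export
gate_contrast_profile <- function(config, wavelength = 690,
                                  gates = default_gates(),
                                  f0 = config_target_freq(config),
                                  detrend_order = 3) {
  stopifnot(inherits(config, "scenario_config"),
            config$geometry == "bilayer",
            length(config$n_tot) == 1, length(config$sdd) == 1,
            length(config$fs) == 1, length(config$tmeas) == 1)
  perts <- config_perturbations(config)
  hemo <- make_hemo_series(config$baseline, perts, config$tmeas, config$fs,
                           seed = config$seed, layers = c("UP", "DW"))
  op <- config_operator(config, wavelength, config$sdd)
  settings <- acquisition_settings(config$n_tot, config$tmeas, config$fs,
                                   config$sdd, wavelength, seed = config$seed)
  dtof <- synthesize_dtof_series(hemo, stats::setNames(list(op),
                                                       format(wavelength)),
                                 settings, config$table)[[1]]
  gated <- gate_counts(dtof, gates)
  gate_rows <- purrr::map(seq_len(nrow(gates)), function(g) {
    x <- gated$counts[, g]
    if (all(x == x[1])) {
      return(tibble::tibble(gate = as.character(g),
                            baseline_mean_counts = gated$baseline_expect[g],
                            peak_psd = NA_real_, epsilon = NA_real_,
                            contrast_db = NA_real_, significant = FALSE))
    }
    spec <- periodogram_psd(detrend_poly(x, detrend_order), config$fs)
    eps <- noise_floor(spec)
    pk <- peak_report(spec, f0, config$threshold, eps)
    tibble::tibble(gate = as.character(g),
                   baseline_mean_counts = gated$baseline_expect[g],
                   peak_psd = pk$psd, epsilon = as.numeric(eps),
                   contrast_db = pk$contrast_db, significant = pk$significant)
  })
  cw <- integrate_to_cw(dtof)
  spec <- periodogram_psd(detrend_poly(cw$intensity, detrend_order), config$fs)
  eps <- noise_floor(spec)
  pk <- peak_report(spec, f0, config$threshold, eps)
  out <- dplyr::bind_rows(
    purrr::list_rbind(gate_rows),
    tibble::tibble(gate = "CW", baseline_mean_counts = sum(gated$baseline_expect),
                   peak_psd = pk$psd, epsilon = as.numeric(eps),
                   contrast_db = pk$contrast_db, significant = pk$significant))
  out$case <- config$case
  out$sdd <- config$sdd
  out$n_tot <- config$n_tot
  out$wavelength <- wavelength
  out$target_frequency <- f0
  out
}

#' Depth-resolved hemoglobin retrieval of a bilayer case (TMPP)
#'
#' Runs the full TMPP retrieval pipeline on one bilayer scenario point: DTOF
#' synthesis at both wavelengths, homogeneous-model baseline fit on the
#' time-averaged DTOF, finite-difference pathlength operator, per-frame gated
#' inversion of the layered absorption changes, chromophore unmixing and
#' spectral peak reports per (layer, species) at every imposed frequency.
#'
#' @param config A bilayer [scenario_config()] with scalar `n_tot` and `sdd`.
#' @param gates [gate_set()] used for inversion.
#' @param fit_baseline If `TRUE` (default), the pathlength operator uses
#'   baseline optical properties recovered by [fit_homogeneous_baseline()]
#'   from the synthetic data; if `FALSE` the known true baselines are used.
#' @param detrend_order Polynomial detrending order.
#' @param min_gate_counts Gate exclusion threshold for [tmpp_invert()].
#' @return A list with elements `hemoglobin` (tibble `frame, time, layer,
#'   do2hb, dhhb`), `spectra` (tibble `layer, species, frequency, psd`),
#'   `peaks` (tibble `layer, species, target_frequency, contrast_db,
#'   significant`) and `baseline_fits`.
#' @examples
#' cfg <- scenario_config("B_DW", n_tot = 1e5, sdd = 4, tmeas = 120)
#' # run_tmpp_case(cfg)
#' @export
run_tmpp_case <- function(config, gates = default_gates(), fit_baseline = TRUE,
                          detrend_order = 3, min_gate_counts = 10) {
  stopifnot(inherits(config, "scenario_config"),
            config$geometry == "bilayer",
            length(config$n_tot) == 1, length(config$sdd) == 1,
            length(config$fs) == 1, length(config$tmeas) == 1,
            length(config$wavelengths) == 2)
  perts <- config_perturbations(config)
  hemo <- make_hemo_series(config$baseline, perts, config$tmeas, config$fs,
                           seed = config$seed, layers = c("UP", "DW"))
  ops <- purrr::map(config$wavelengths, function(wl)
    config_operator(config, wl, config$sdd))
  names(ops) <- format(config$wavelengths)
  settings <- acquisition_settings(config$n_tot, config$tmeas, config$fs,
                                   config$sdd, config$wavelengths,
                                   seed = config$seed)
  dtofs <- synthesize_dtof_series(hemo, ops, settings, config$table)
  grid <- time_grid(0, 5, config$dt)

  per_wl <- purrr::imap(dtofs, function(dtof, wl_name) {
    wl <- as.numeric(wl_name)
    mean_dtof <- colMeans(dtof$counts)
    bfit <- fit_homogeneous_baseline(
      mean_dtof, grid, config$sdd, config$slab, config$n_index,
      init = list(mua = 0.1, musp = 10))
    props <- if (fit_baseline) {
      optical_properties(bfit$mua, bfit$musp, config$n_index)
    } else {
      config_baseline_props(config, wl)
    }
    plop <- tmpp_pathlengths(props, props, config$bilayer, config$sdd, grid,
                             gates = gates)
    dmua <- tmpp_invert(gate_counts(dtof, gates), plop, min_gate_counts)
    list(fit = bfit, dmua = dmua)
  })

  n_frames <- nrow(per_wl[[1]]$dmua)
  hb <- purrr::map(c(up = "up", dw = "dw"), function(ly) {
    dmua_mat <- vapply(per_wl, function(x) x$dmua[[paste0("dmua_", ly)]],
                       numeric(n_frames))
    unmix_chromophores(dmua_mat, config$wavelengths, config$table)
  })
  hemoglobin <- purrr::imap(hb, function(h, ly) {
    tibble::tibble(frame = per_wl[[1]]$dmua$frame,
                   time = per_wl[[1]]$dmua$time,
                   layer = toupper(ly), do2hb = h$do2hb, dhhb = h$dhhb)
  }) |> purrr::list_rbind()

  freqs <- unique(stats::na.omit(c(
    if (isTRUE(config$amp_up > 0)) config$freq_up,
    if (isTRUE(config$amp_dw > 0)) config$freq_dw)))
  if (length(freqs) == 0) freqs <- 1
  species_cols <- c(O2Hb = "do2hb", HHb = "dhhb")
  spec_rows <- list()
  peak_rows <- list()
  for (ly in c("UP", "DW")) {
    sub <- hemoglobin[hemoglobin$layer == ly, ]
    for (sp in names(species_cols)) {
      spec <- periodogram_psd(detrend_poly(sub[[species_cols[[sp]]]],
                                           detrend_order), config$fs)
      eps <- noise_floor(spec)
      spec_rows[[paste(ly, sp)]] <-
        dplyr::mutate(spec, layer = ly, species = sp)
      peak_rows[[paste(ly, sp)]] <- purrr::map(freqs, function(f0) {
        pk <- peak_report(spec, f0, config$threshold, eps)
        tibble::tibble(layer = ly, species = sp, target_frequency = f0,
                       peak_psd = pk$psd, epsilon = as.numeric(eps),
                       contrast_db = pk$contrast_db,
                       significant = pk$significant)
      }) |> purrr::list_rbind()
    }
  }
  list(hemoglobin = hemoglobin,
       spectra = purrr::list_rbind(spec_rows),
       peaks = purrr::list_rbind(peak_rows),
       baseline_fits = purrr::map(per_wl, "fit"))
}

#' CW hemoglobin retrieval of a bilayer case (modified Beer-Lambert)
#'
#' Integrates the synthetic DTOFs to CW intensities, inverts absorption
#' changes with the modified Beer-Lambert law (photon-mean pathlength from the
#' baseline model curve), unmixes the two wavelengths into hemoglobin changes
#' and reports spectral peaks. The CW retrieval has no depth resolution: it
#' returns a single effective (whole-medium) hemoglobin series.
#'
#' @inheritParams run_tmpp_case
#' @return A list `hemoglobin` (tibble `frame, time, do2hb, dhhb`), `peaks`
#'   (per species and imposed frequency).
#' @examples
#' cfg <- scenario_config("B_DW", n_tot = 1e6, sdd = 1, tmeas = 120)
#' # run_cw_retrieval(cfg)
#' @export
run_cw_retrieval <- function(config, detrend_order = 3) {
  stopifnot(inherits(config, "scenario_config"),
            config$geometry == "bilayer",
            length(config$n_tot) == 1, length(config$sdd) == 1,
            length(config$wavelengths) == 2)
  perts <- config_perturbations(config)
  hemo <- make_hemo_series(config$baseline, perts, config$tmeas, config$fs,
                           seed = config$seed, layers = c("UP", "DW"))
  ops <- purrr::map(config$wavelengths, function(wl)
    config_operator(config, wl, config$sdd))
  names(ops) <- format(config$wavelengths)
  settings <- acquisition_settings(config$n_tot, config$tmeas, config$fs,
                                   config$sdd, config$wavelengths,
                                   seed = config$seed)
  dtofs <- synthesize_dtof_series(hemo, ops, settings, config$table)
  dmua_mat <- vapply(names(ops), function(wl_name) {
    dtof <- dtofs[[wl_name]]
    cw <- integrate_to_cw(dtof)
    L <- mean_photon_pathlength(ops[[wl_name]]$baseline, config$n_index)
    cw_mbll(cw, L)$dmua
  }, numeric(settings$n_frames))
  hb <- unmix_chromophores(dmua_mat, config$wavelengths, config$table)
  hemoglobin <- tibble::tibble(frame = seq.int(0, settings$n_frames - 1),
                               time = seq.int(0, settings$n_frames - 1) /
                                 config$fs,
                               do2hb = hb$do2hb, dhhb = hb$dhhb)
  freqs <- unique(stats::na.omit(c(
    if (isTRUE(config$amp_up > 0)) config$freq_up,
    if (isTRUE(config$amp_dw > 0)) config$freq_dw)))
  if (length(freqs) == 0) freqs <- 1
  peaks <- purrr::map(c(O2Hb = "do2hb", HHb = "dhhb"), function(col) {
    spec <- periodogram_psd(detrend_poly(hemoglobin[[col]], detrend_order),
                            config$fs)
    eps <- noise_floor(spec)
    purrr::map(freqs, function(f0) {
      pk <- peak_report(spec, f0, config$threshold, eps)
      tibble::tibble(target_frequency = f0, peak_psd = pk$psd,
                     epsilon = as.numeric(eps), contrast_db = pk$contrast_db,
                     significant = pk$significant)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind(names_to = "species")
  list(hemoglobin = hemoglobin, peaks = peaks)
}

#' Plot a per-gate contrast profile
#'
#' @param profile Output of [gate_contrast_profile()] (profiles from several
#'   cases/SDDs may be row-bound).
#' @param threshold Significance threshold line (dB).
#' @return A ggplot object.
#' @export
plot_gate_profile <- function(profile, threshold = 15) {
  profile$gate <- factor(profile$gate,
                         levels = c(sort(unique(suppressWarnings(
                           as.numeric(profile$gate)))), "CW"))
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$gate, y = .data$contrast_db,
                               colour = .data$case, group = .data$case)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "gate", y = "1-Hz peak contrast (dB)")
}
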