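#' Baseline hemoglobin concentrations
#'
#' @param o2hb Oxygenated hemoglobin concentration (uM), `> 0`. Default 30 uM.
#' @param hhb Deoxygenated hemoglobin concentration (uM), `> 0`. Default 20 uM.
#' @return An object of class `hemo_baseline`.
#' @examples
#' hemo_baseline()
#' @export
hemo_baseline <- function(o2hb = 30, hhb = 20) {
  stopifnot(o2hb > 0, hhb > 0)
  structure(list(o2hb = o2hb, hhb = hhb), class = "hemo_baseline")
}

#' Mie-approximation scattering power law
#'
#' Reduced scattering follows `musp(lambda) = a * (lambda0 / lambda)^b`, so
#' `musp(lambda0) = a` and `musp` decreases with wavelength for `b > 0`.
#'
#' @param a Scattering amplitude at the reference wavelength (1/cm), `> 0`.
#' @param b Scattering power (dimensionless).
#' @param lambda0 Reference wavelength (nm).
#' @return An object of class `scattering_law`.
#' @examples
#' scattering_at(scattering_law(), 830)
#' @export
scattering_law <- function(a = 10, b = 1, lambda0 = 690) {
  stopifnot(a > 0, lambda0 > 0)
  structure(list(a = a, b = b, lambda0 = lambda0), class = "scattering_law")
}

#' @rdname scattering_law
#' @param law A `scattering_law`.
#' @param wavelength Wavelength (nm), `> 0`; vectorized.
#' @export
scattering_at <- function(law, wavelength) {
  stopifnot(inherits(law, "scattering_law"), all(wavelength > 0))
  law$a * (law$lambda0 / wavelength)^law$b
}

#' Specific absorption factors of oxy- and deoxy-hemoglobin
#'
#' Loads the bundled compilation of hemoglobin molar extinction coefficients
#' (base-10, per cm per M) and returns them pre-multiplied by `ln(10) * 1e-6`,
#' so that `mua = factor * concentration_uM` directly in 1/cm with no
#' logarithm-base ambiguity at run time.
#'
#' @param path Optional path to a CSV with columns `wavelength_nm`, `species`
#'   (`O2Hb` / `HHb`) and `factor_cm1_uM1`; defaults to the table shipped with
#'   the package.
#' @return A tibble with columns `wavelength`, `o2hb` and `hhb` (factors in
#'   1/cm per uM).
#' @examples
#' extinction_table()
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction.csv",
                        package = "fnirsim", mustWork = TRUE)
  }
  raw <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "species", "factor_cm1_uM1") %in% names(raw)))
  out <- raw |>
    dplyr::select(wavelength = "wavelength_nm", species = "species",
                  factor = "factor_cm1_uM1") |>
    tidyr::pivot_wider(names_from = "species", values_from = "factor") |>
    dplyr::rename(o2hb = "O2Hb", hhb = "HHb") |>
    tibble::as_tibble()
  if (any(out$o2hb <= 0) || any(out$hhb <= 0))
    stop("extinction factors must be positive")
  out
}

#' Absorption coefficient from hemoglobin concentrations (Beer's law)
#'
#' @param o2hb,hhb Concentrations (uM), `>= 0`; vectorized.
#' @param wavelength A single wavelength (nm) present in `table`.
#' @param table Extinction factors from [extinction_table()].
#' @return Absorption coefficient(s) in 1/cm.
#' @examples
#' hemoglobin_to_mua(30, 20, 690)
#' @export
hemoglobin_to_mua <- function(o2hb, hhb, wavelength, table = extinction_table()) {
  stopifnot(all(o2hb >= 0), all(hhb >= 0), length(wavelength) == 1)
  row <- table[table$wavelength == wavelength, ]
  if (nrow(row) != 1)
    stop("wavelength ", wavelength, " nm not present in the extinction table")
  row$o2hb * o2hb + row$hhb * hhb
}

#' Sinusoidal hemodynamic perturbation specification
#'
#' @param amplitude_frac Amplitude as a fraction of the baseline concentration
#'   (e.g. 0.01 for a 1% oscillation), `>= 0`.
#' @param frequency Oscillation frequency (Hz), `> 0`.
#' @param phase Phase (radians in `[0, 2*pi)`), or `"random"` to draw one
#'   reproducibly per (layer, species) from the series seed.
#' @param layer Target layer: `"UP"`, `"DW"` or `"WHOLE"`.
#' @param species Target species: `"O2Hb"`, `"HHb"` or `"both"`. `"both"`
#'   expands to two independent perturbations (one per species), each with its
#'   own random phase.
#' @return An object of class `perturbation_spec`.
#' @examples
#' perturbation_spec(0.01, 1, layer = "WHOLE")
#' @export
perturbation_spec <- function(amplitude_frac, frequency, phase = "random",
                              layer = c("WHOLE", "UP", "DW"),
                              species = c("both", "O2Hb", "HHb")) {
  layer <- match.arg(layer)
  species <- match.arg(species)
  stopifnot(amplitude_frac >= 0, frequency > 0)
  if (!identical(phase, "random")) {
    stopifnot(is.numeric(phase), length(phase) == 1,
              phase >= 0, phase < 2 * pi)
  }
  structure(list(amplitude_frac = amplitude_frac, frequency = frequency,
                 phase = phase, layer = layer, species = species),
            class = "perturbation_spec")
}

# deterministic 31-bit sub-stream seed from a master seed and a string key
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Generate per-layer hemoglobin concentration trajectories
#'
#' Builds frame-by-frame O2Hb and HHb concentration time series for each layer,
#' as the baseline value modulated by the summed sinusoidal perturbations
#' targeting that (layer, species):
#' `c(t) = baseline * (1 + sum_k amplitude_k * sin(2 pi f_k t + phi_k))`.
#' Random phases are drawn independently per (layer, species) from sub-streams
#' of `seed`, so the same (layer, species) oscillation is reproduced exactly
#' across scenarios sharing a seed.
#'
#' @param baseline [hemo_baseline()] concentrations, shared by all layers.
#' @param perturbations A list of [perturbation_spec()] objects.
#' @param tmeas Measurement length (s); `tmeas * fs` must be an integer `>= 2`.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for random phases.
#' @param layers Character vector of layers to generate (default from the
#'   perturbation targets; `"WHOLE"` for homogeneous media, `c("UP", "DW")`
#'   for bilayer media). Layers without a perturbation stay at baseline.
#' @return A tibble with columns `frame` (0-based), `time` (s), `layer`,
#'   `o2hb`, `hhb` (uM), of class `hemo_series`, with attributes `fs`,
#'   `baseline` and `phases` (the phase actually used per perturbation).
#' @examples
#' hemo <- make_hemo_series(hemo_baseline(),
#'                          list(perturbation_spec(0.01, 1, layer = "WHOLE")),
#'                          tmeas = 10, fs = 20, seed = 1)
#' @export
make_hemo_series <- function(baseline, perturbations, tmeas, fs, seed = 1,
                             layers = NULL) {
  stopifnot(inherits(baseline, "hemo_baseline"), fs > 0, tmeas > 0)
  n_frames <- round(tmeas * fs)
  if (abs(n_frames - tmeas * fs) > 1e-9 || n_frames < 2)
    stop("`tmeas * fs` must be an integer >= 2")
  stopifnot(is.list(perturbations),
            all(vapply(perturbations, inherits, TRUE, "perturbation_spec")))

  # expand species = "both" into one spec per species
  expanded <- purrr::list_flatten(purrr::map(perturbations, function(p) {
    if (p$species != "both") return(list(p))
    purrr::map(c("O2Hb", "HHb"), function(sp) {
      q <- p
      q$species <- sp
      q
    })
  }))
  keys <- vapply(expanded, function(p)
    paste(p$layer, p$species, format(p$frequency), sep = "/"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate perturbation for the same (layer, species, frequency): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))

  if (is.null(layers)) {
    targets <- unique(vapply(expanded, `[[`, character(1), "layer"))
    layers <- if ("WHOLE" %in% targets || length(targets) == 0) "WHOLE"
              else c("UP", "DW")
  }

  time <- seq.int(0, n_frames - 1) / fs
  phases <- purrr::map_dbl(expanded, function(p) {
    if (identical(p$phase, "random")) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(derive_seed(seed, paste("phase", p$layer, p$species, p$frequency)))
      stats::runif(1, 0, 2 * pi)
    } else p$phase
  })

  out <- purrr::map(layers, function(ly) {
    conc <- list(O2Hb = rep(baseline$o2hb, n_frames),
                 HHb = rep(baseline$hhb, n_frames))
    for (i in seq_along(expanded)) {
      p <- expanded[[i]]
      if (p$layer != ly) next
      base <- if (p$species == "O2Hb") baseline$o2hb else baseline$hhb
      conc[[p$species]] <- conc[[p$species]] +
        base * p$amplitude_frac * sin(2 * pi * p$frequency * time + phases[i])
    }
    tibble::tibble(frame = seq.int(0, n_frames - 1), time = time, layer = ly,
                   o2hb = conc$O2Hb, hhb = conc$HHb)
  }) |> purrr::list_rbind()

  structure(out, fs = fs, tmeas = tmeas,
            baseline = baseline,
            phases = tibble::tibble(key = keys, phase = phases),
            class = c("hemo_series", class(out)))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Map a hemoglobin series to absorption coefficients
#'
#' Applies Beer's law per frame and layer at each requested wavelength.
#'
#' @param hemo A `hemo_series` from [make_hemo_series()].
#' @param wavelengths Wavelengths (nm) present in `table`.
#' @param table Extinction factors from [extinction_table()].
#' @return A tibble `frame, time, layer, wavelength, mua` (1/cm).
#' @examples
#' hemo <- make_hemo_series(hemo_baseline(),
#'                          list(perturbation_spec(0.01, 1, layer = "WHOLE")),
#'                          tmeas = 10, fs = 20, seed = 1)
#' mua <- hemo_to_mua_series(hemo, c(690, 830))
#' @export
hemo_to_mua_series <- function(hemo, wavelengths = c(690, 830),
                               table = extinction_table()) {
  stopifnot(inherits(hemo, "hemo_series"))
  purrr::map(wavelengths, function(wl) {
    tibble::tibble(frame = hemo$frame, time = hemo$time, layer = hemo$layer,
                   wavelength = wl,
                   mua = hemoglobin_to_mua(hemo$o2hb, hemo$hhb, wl, table))
  }) |> purrr::list_rbind()
}
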