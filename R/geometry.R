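#' Laterally infinite slab geometry
#'
#' @param thickness Slab thickness (cm), `> 0`. Default 5 cm.
#' @return An object of class `slab_geometry`.
#' @examples
#' slab_geometry(5)
#' @export
slab_geometry <- function(thickness = 5) {
  stopifnot(is.numeric(thickness), length(thickness) == 1, thickness > 0)
  structure(list(thickness = thickness, lateral_extent = "infinite"),
            class = "slab_geometry")
}

#' Two-layer finite-cylinder geometry
#'
#' Two stacked homogeneous cylinders sharing a radius: a superficial layer
#' ("UP") on top of a deeper layer ("DW"). The default dimensions are a 10 cm
#' radius, a 1 cm superficial layer and a 4 cm deep layer (5 cm total).
#'
#' @param radius Cylinder radius (cm), `> 0`.
#' @param thickness_up Superficial-layer thickness (cm), `> 0`.
#' @param thickness_dw Deep-layer thickness (cm), `> 0`.
#' @return An object of class `bilayer_geometry`.
#' @examples
#' bilayer_geometry()
#' @export
bilayer_geometry <- function(radius = 10, thickness_up = 1, thickness_dw = 4) {
  stopifnot(radius > 0, thickness_up > 0, thickness_dw > 0)
  structure(list(radius = radius, thickness_up = thickness_up,
                 thickness_dw = thickness_dw),
            class = "bilayer_geometry")
}

#' Uniform time grid for time-resolved curves
#'
#' Defines contiguous time bins of width `dt` covering `[t_start, t_end]`.
#' Curves are evaluated at bin centers and stored per bin.
#'
#' @param t_start Start of the window (ns), `>= 0`.
#' @param t_end End of the window (ns), `> t_start`.
#' @param dt Bin width (ns), `> 0`.
#' @return An object of class `time_grid` with elements `t_start`, `t_end`,
#'   `dt`, `n_bins`, `centers` and `edges`.
#' @examples
#' time_grid(0, 5, 0.008)
#' @export
time_grid <- function(t_start = 0, t_end = 5, dt = 0.008) {
  stopifnot(t_start >= 0, dt > 0, t_end > t_start)
  n_bins <- as.integer(round((t_end - t_start) / dt))
  if (abs(n_bins * dt - (t_end - t_start)) > 1e-9 * dt) {
    stop("time grid must cover [t_start, t_end] with an integer number of bins")
  }
  edges <- t_start + dt * seq.int(0, n_bins)
  structure(list(t_start = t_start, t_end = t_end, dt = dt, n_bins = n_bins,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 edges = edges),
            class = "time_grid")
}

# Construct a reflectance_curve tibble: per-bin values (flux density already
# multiplied by dt) on a time grid, tagged with wavelength / SDD metadata.
new_reflectance_curve <- function(grid, values, wavelength = NA_real_,
                                  sdd = NA_real_) {
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n_bins)
  out <- tibble::tibble(time = grid$centers, value = as.numeric(values))
  structure(out, dt = grid$dt, wavelength = wavelength, sdd = sdd,
            class = c("reflectance_curve", class(out)))
}

#' @export
print.reflectance_curve <- function(x, ...) {
  cat(sprintf(
    "<reflectance_curve> %d bins, dt = %g ns, sdd = %s cm, wavelength = %s nm\n",
    nrow(x), attr(x, "dt"), format(attr(x, "sdd")), format(attr(x, "wavelength"))))
  NextMethod()
}

curve_grid <- function(curve) {
  dt <- attr(curve, "dt")
  time_grid(curve$time[1] - dt / 2, curve$time[nrow(curve)] + dt / 2, dt)
}
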