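#' Time-resolved diffuse reflectance of a homogeneous slab
#'
#' Evaluates the diffusion-equation Green's function for a laterally infinite
#' homogeneous slab with extrapolated boundary conditions, using the classic
#' image-source expansion, and returns the time-resolved reflectance at a
#' source-detector distance `sdd` on the entry surface. Detection follows
#' Fick's law at the physical boundary. Absorption enters exactly through the
#' factor `exp(-mua v t)`, which downstream code exploits as a fast path for
#' per-frame synthesis.
#'
#' @param props [optical_properties()] of the medium.
#' @param geom [slab_geometry()].
#' @param sdd Source-detector distance (cm), `> 0`.
#' @param grid [time_grid()] on which to evaluate the curve (ns).
#' @param wavelength Optional wavelength tag (nm) stored on the result.
#' @param rel_tol Relative truncation tolerance for the image series; source
#'   pairs are added until the next pair contributes less than this fraction.
#'
#' @return A `reflectance_curve` tibble with columns `time` (bin centers, ns)
#'   and `value` (per-bin reflectance, i.e. flux density times `dt`).
#' @examples
#' curve <- slab_td_reflectance(optical_properties(0.1, 10, 1.4),
#'                              slab_geometry(5), sdd = 3,
#'                              grid = time_grid(0, 5, 0.008))
#' head(curve)
#' @export
slab_td_reflectance <- function(props, geom = slab_geometry(), sdd, grid,
                                wavelength = NA_real_, rel_tol = 1e-12) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "slab_geometry"), inherits(grid, "time_grid"))
  if (sdd <= 0) stop("`sdd` must be > 0")
  flux <- slab_flux_density(grid$centers, props$mua, props$musp, props$n,
                            geom$thickness, sdd, rel_tol)
  new_reflectance_curve(grid, flux * grid$dt, wavelength = wavelength, sdd = sdd)
}

# Reflectance flux density R(t) (photons / ns / cm^2 per injected photon) for
# the EBC slab via image sources; vectorized over t (ns).
slab_flux_density <- function(t, mua, musp, n, thickness, rho, rel_tol = 1e-12,
                              m_max = 50) {
  v <- light_speed(n)
  D <- diffusion_coefficient(musp)
  z0 <- 1 / musp
  zb <- 2 * boundary_coefficient_A(n) * D
  period <- thickness + 2 * zb
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  k <- 4 * D * v * tt
  pref <- exp(-mua * v * tt - rho^2 / k) / (2 * (pi * k)^1.5 * tt)
  acc <- numeric(length(tt))
  # m = 0, then +/- pairs until the added pair is negligible everywhere
  for (m in 0:m_max) {
    ms <- if (m == 0) 0 else c(-m, m)
    term <- numeric(length(tt))
    for (mm in ms) {
      zp <- 2 * mm * period + z0
      zm <- 2 * mm * period - 2 * zb - z0
      term <- term + zp * exp(-zp^2 / k) - zm * exp(-zm^2 / k)
    }
    acc <- acc + term
    if (m > 0 && all(abs(term) <= rel_tol * pmax(abs(acc), .Machine$double.xmin)))
      break
    if (m == m_max)
      stop("slab image series not converged to rel_tol = ", rel_tol,
           " within ", m_max, " source pairs")
  }
  out[pos] <- pmax(pref * acc, 0)
  out
}

#' Integrate a time-resolved curve to a CW intensity
#'
#' Sums the per-bin values of a reflectance curve over the full time window,
#' giving the continuous-wave (total) intensity. Linear in the curve values.
#'
#' @param curve A `reflectance_curve`.
#' @return A single non-negative number.
#' @examples
#' curve <- slab_td_reflectance(optical_properties(0.1, 10, 1.4),
#'                              slab_geometry(5), sdd = 3,
#'                              grid = time_grid(0, 5, 0.02))
#' cw_intensity(curve)
#' @export
cw_intensity <- function(curve) {
  stopifnot(inherits(curve, "reflectance_curve"))
  if (any(!is.finite(curve$value))) stop("curve contains non-finite values")
  sum(curve$value)
}
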