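#' Speed of light in vacuum (cm/ns)
#' @keywords internal
#' @noRd
C_VACUUM_CM_NS <- 29.9792458

#' Optical properties of a diffusive medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and
#' refractive index of one homogeneous tissue domain.
#'
#' @param mua Absorption coefficient (1/cm), `>= 0`.
#' @param musp Reduced scattering coefficient (1/cm), `> 0`.
#' @param n Refractive index (dimensionless), `>= 1`.
#'
#' @return An object of class `optical_properties` (a named list with elements
#'   `mua`, `musp`, `n`).
#' @examples
#' optical_properties(mua = 0.1, musp = 10, n = 1.4)
#' @export
optical_properties <- function(mua, musp, n = 1.4) {
  stopifnot(is.numeric(mua), length(mua) == 1, is.finite(mua),
            is.numeric(musp), length(musp) == 1, is.finite(musp),
            is.numeric(n), length(n) == 1, is.finite(n))
  if (mua < 0) stop("`mua` must be >= 0 (got ", mua, ")")
  if (musp <= 0) stop("`musp` must be > 0 (got ", musp, ")")
  if (n < 1) stop("`n` must be >= 1 (got ", n, ")")
  structure(list(mua = mua, musp = musp, n = n), class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mua = %g 1/cm, musp = %g 1/cm, n = %g\n",
              x$mua, x$musp, x$n))
  invisible(x)
}

# Speed of light in the medium, cm/ns.
light_speed <- function(n) C_VACUUM_CM_NS / n

# Diffusion coefficient D = 1/(3 musp), cm. The mua-free convention is used
# throughout; absorption enters only via the exp(-mua v t) factor or the
# mua term of the frequency-domain wavenumber.
diffusion_coefficient <- function(musp) 1 / (3 * musp)

#' Internal-reflection coefficient A for the extrapolated boundary
#'
#' Computes the boundary coefficient `A = (1 + R_eff) / (1 - R_eff)` from the
#' Fresnel reflection moments of the refractive-index mismatch between the
#' medium (index `n`) and the outside (index `n_out`), following the standard
#' partial-current treatment. The extrapolated-boundary distance is
#' `zb = 2 A D`.
#'
#' @param n Refractive index of the medium.
#' @param n_out Refractive index of the outer medium (default 1, air).
#' @return The dimensionless coefficient A (about 2.95 for n = 1.4 into air).
#' @examples
#' boundary_coefficient_A(1.4)
#' @export
boundary_coefficient_A <- function(n, n_out = 1) {
  stopifnot(n >= n_out)
  if (n == n_out) return(1)
  n_rel <- n / n_out
  # unpolarized Fresnel reflectance for internal incidence angle theta
  fresnel_r <- function(theta) {
    theta_c <- asin(1 / n_rel)
    r <- numeric(length(theta))
    tot <- theta >= theta_c
    r[tot] <- 1
    th <- theta[!tot]
    tht <- asin(n_rel * sin(th)) # transmission angle (Snell, into rarer medium)
    rs <- (sin(th - tht) / sin(th + tht))^2
    rp <- (tan(th - tht) / tan(th + tht))^2
    r[!tot] <- (rs + rp) / 2
    r
  }
  r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * fresnel_r(th),
                            0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * fresnel_r(th),
                          0, pi / 2, rel.tol = 1e-10)$value
  r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
  (1 + r_eff) / (1 - r_eff)
}
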