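#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial of the given order from a uniformly
#' sampled signal; the residual is orthogonal to the polynomial basis. The
#' default order 3 removes slow drifts before spectral estimation.
#'
#' @param x Numeric signal, length `> order + 1`.
#' @param order Polynomial order, `>= 0`.
#' @return The detrended signal (numeric vector, same length).
#' @examples
#' detrend_poly(sin(1:100 / 5) + (1:100)^2 / 1e3)
#' @export
detrend_poly <- function(x, order = 3) {
  stopifnot(is.numeric(x), order >= 0, length(x) > order + 1)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  idx <- seq_along(x)
  basis <- stats::poly(idx, degree = max(order, 1), simple = TRUE)
  if (order == 0) basis <- basis[, 0, drop = FALSE]
  stats::lm.fit(cbind(1, basis), x)$residuals
}

#' One-sided periodogram power spectral density
#'
#' Un-windowed, non-averaged periodogram via the FFT: maximum frequency
#' resolution, no variance reduction. The normalization is the one-sided power
#' density convention, `PSD(f_k) = 2 |X_k|^2 / (fs N)` (half that at the
#' Nyquist bin), so that `sum(PSD) * fs / N` equals the mean square of the
#' (zero-mean) signal and a full-length sinusoid of amplitude `A` on an exact
#' grid frequency peaks at `A^2 N / (2 fs)`. The zero-frequency bin is
#' excluded.
#'
#' @param x Numeric signal, uniformly sampled; typically already detrended via
#'   [detrend_poly()].
#' @param fs Sampling rate (Hz).
#' @return A tibble `frequency, psd` of class `fnirs_spectrum`, with attributes
#'   `fs` and `n`.
#' @examples
#' sp <- periodogram_psd(sin(2 * pi * 1 * (0:199) / 20), fs = 20)
#' @export
periodogram_psd <- function(x, fs) {
  stopifnot(length(x) >= 2, fs > 0)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  X <- stats::fft(x)
  k <- seq_len(floor(n / 2))
  psd <- 2 * Mod(X[k + 1])^2 / (fs * n)
  if (n %% 2 == 0) psd[length(k)] <- psd[length(k)] / 2
  out <- tibble::tibble(frequency = k * fs / n, psd = psd)
  structure(out, fs = fs, n = n,
            class = c("fnirs_spectrum", class(out)))
}

#' Average PSD in the noise-only band
#'
#' The noise floor is the mean PSD over frequencies above 5 Hz when the
#' Nyquist frequency allows it (band `(5, fs/2]`); otherwise the band
#' `(2, 2.5]` Hz is used, which excludes a possible second harmonic of a 1-Hz
#' oscillation sitting exactly at 2 Hz.
#'
#' @param spec An `fnirs_spectrum` from [periodogram_psd()].
#' @return The noise floor (positive scalar) with attribute `band` (the
#'   half-open frequency interval actually averaged).
#' @examples
#' sp <- periodogram_psd(rnorm(4000), fs = 20)
#' noise_floor(sp)
#' @export
noise_floor <- function(spec) {
  stopifnot(inherits(spec, "fnirs_spectrum"))
  fs <- attr(spec, "fs")
  band <- if (fs / 2 > 5) c(5, fs / 2) else c(2, 2.5)
  sel <- spec$frequency > band[1] & spec$frequency <= band[2]
  if (!any(sel)) stop("empty noise band (", band[1], ", ", band[2], "] Hz")
  structure(mean(spec$psd[sel]), band = band)
}

#' Spectral contrast against the noise floor
#'
#' Elementwise contrast `C(f) = PSD(f) / epsilon` and its decibel form
#' `C_dB(f) = 10 log10(PSD(f) / epsilon)` against the noise floor `epsilon`.
#'
#' @param spec An `fnirs_spectrum`.
#' @param epsilon Noise floor; defaults to [noise_floor()] of `spec`.
#' @return The spectrum tibble with added columns `contrast` and `contrast_db`
#'   and attribute `epsilon`.
#' @examples
#' sp <- periodogram_psd(rnorm(4000), fs = 20)
#' head(add_contrast(sp))
#' @export
add_contrast <- function(spec, epsilon = noise_floor(spec)) {
  stopifnot(inherits(spec, "fnirs_spectrum"))
  if (epsilon <= 0) stop("noise floor must be positive")
  spec$contrast <- spec$psd / as.numeric(epsilon)
  spec$contrast_db <- 10 * log10(spec$contrast)
  attr(spec, "epsilon") <- epsilon
  spec
}

#' Peak report at a target frequency
#'
#' Reads the PSD at the grid frequency nearest the target (ties break toward
#' the lower frequency; no local-maximum search) and reports its contrast and
#' significance against a decibel threshold.
#'
#' @param spec An `fnirs_spectrum`.
#' @param f0 Target frequency (Hz), below Nyquist.
#' @param threshold Significance threshold in dB (default 15).
#' @param epsilon Noise floor; defaults to [noise_floor()] of `spec`.
#' @return A one-row tibble `target_frequency, frequency, psd, contrast,
#'   contrast_db, significant`.
#' @examples
#' x <- sin(2 * pi * (0:1999) / 20) + rnorm(2000)
#' peak_report(periodogram_psd(x, fs = 20), f0 = 1)
#' @export
peak_report <- function(spec, f0, threshold = 15, epsilon = noise_floor(spec)) {
  stopifnot(inherits(spec, "fnirs_spectrum"), f0 > 0)
  fs <- attr(spec, "fs")
  if (f0 > fs / 2 + 1e-12)
    stop("target frequency ", f0, " Hz beyond Nyquist (", fs / 2, " Hz)")
  d <- abs(spec$frequency - f0)
  i <- which(d == min(d))[1]
  cdb <- 10 * log10(spec$psd[i] / as.numeric(epsilon))
  tibble::tibble(target_frequency = f0, frequency = spec$frequency[i],
                 psd = spec$psd[i], epsilon = as.numeric(epsilon),
                 contrast = spec$psd[i] / as.numeric(epsilon),
                 contrast_db = cdb, significant = cdb >= threshold)
}

#' @rdname peak_report
#' @details `second_harmonic_check()` is the same report evaluated at `2 * f0`,
#'   used to detect the second harmonic that intensity signals develop because
#'   counts respond exponentially to an oscillating absorption.
#' @export
second_harmonic_check <- function(spec, f0, threshold = 15,
                                  epsilon = noise_floor(spec)) {
  peak_report(spec, 2 * f0, threshold = threshold, epsilon = epsilon)
}

#' Power-law fit in log-log space
#'
#' Ordinary least squares of `log(y)` on `log(x)`: `y = prefactor * x^exponent`.
#' The coefficient of determination is reported in log-log space, the space of
#' the fit.
#'
#' @param x,y Strictly positive numeric vectors of equal length `>= 3`.
#' @return An object of class `power_law_fit` with elements `exponent`,
#'   `prefactor`, `r_squared` and `n`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' fit_power_law(c(1, 2, 4), 3 * c(1, 2, 4)^2)
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive values")
  lx <- log(x)
  ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = length(x), fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g  (r^2 = %.6f, n = %d)\n",
              x$prefactor, x$exponent, x$r_squared, x$n))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("log(prefactor)", "exponent"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, prefactor = x$prefactor,
                 r.squared = x$r_squared, nobs = x$n)
}

#' @method autoplot fnirs_spectrum
#' @export
autoplot.fnirs_spectrum <- function(object, f0 = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$psd)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD")
  if (!is.null(f0))
    p <- p + ggplot2::geom_vline(xintercept = f0, linetype = 2, colour = "red")
  p
}
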