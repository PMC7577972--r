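# Empirical Nasmyth shear spectrum (Wolk-style rational fit) and helpers.
# Nondimensional form: G2(x) = 8.05 x^(1/3) / (1 + (20.6 x)^3.715),
# x = k / k_s, k_s = (epsilon / nu^3)^(1/4) in cyclic units (cpm).
# The fit integrates so that 7.5 * nu * integral(Phi dk) = epsilon, which is
# the defining normalization since epsilon = 7.5 nu <shear^2>.

.turbflux_env <- new.env(parent = emptyenv())

.nasmyth_g2 <- function(x) {
  8.05 * x^(1 / 3) / (1 + (20.6 * x)^3.715)
}

# Total nondimensional shear variance of the fit (~ 1/7.5).
.nasmyth_total <- function() {
  if (is.null(.turbflux_env$nasmyth_total)) {
    .turbflux_env$nasmyth_total <-
      stats::integrate(.nasmyth_g2, 0, Inf, rel.tol = 1e-10)$value
  }
  .turbflux_env$nasmyth_total
}

# Cumulative variance fraction F(x) = int_0^x G2 / int_0^inf G2, as a
# monotone spline lookup built once per session (quadrature per call would
# dominate the iterative integration loop).
.nasmyth_cdf <- function(x) {
  if (is.null(.turbflux_env$nasmyth_cdf_fun)) {
    xg <- c(0, 10^seq(-5, 1.5, length.out = 400))
    g <- .nasmyth_g2(xg[-1])
    cum <- c(0, pracma::cumtrapz(xg[-1], g))
    # open-ended tail beyond the grid
    frac <- cum / .nasmyth_total()
    frac <- pmin(frac, 1)
    fun <- stats::approxfun(xg, frac, yleft = 0, yright = 1, rule = 2)
    .turbflux_env$nasmyth_cdf_fun <- fun
  }
  .turbflux_env$nasmyth_cdf_fun(pmax(x, 0))
}

# Nondimensional wavenumber below which `fraction` of the shear variance
# is resolved.
.nasmyth_quantile <- function(fraction) {
  stopifnot(fraction > 0, fraction < 1)
  key <- sprintf("q%.6f", fraction)
  if (is.null(.turbflux_env[[key]])) {
    .turbflux_env[[key]] <- stats::uniroot(
      function(x) .nasmyth_cdf(x) - fraction,
      interval = c(1e-5, 30), tol = 1e-8
    )$root
  }
  .turbflux_env[[key]]
}

#' Kolmogorov wavenumber
#'
#' Viscous roll-off wavenumber `k_s = (epsilon / nu^3)^(1/4)` in cycles per
#' metre, the scaling wavenumber of the universal shear spectrum.
#'
#' @param epsilon TKE dissipation rate, W kg^-1 (> 0).
#' @param nu kinematic viscosity of seawater, m^2 s^-1 (> 0).
#' @return Wavenumber in cpm.
#' @export
kolmogorov_wavenumber <- function(epsilon, nu) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop("`epsilon` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(nu)) || any(nu <= 0)) {
    stop("`nu` must be finite and > 0", call. = FALSE)
  }
  (epsilon / nu^3)^(1 / 4)
}

#' Empirical Nasmyth shear spectrum
#'
#' One-sided wavenumber spectrum of vertical microstructure shear for a given
#' dissipation rate and viscosity, using the standard closed-form rational fit
#' in `k / k_s`. The fit satisfies the defining normalization
#' `7.5 nu * integral(Phi dk) = epsilon` (the dissipation estimate is
#' `epsilon = 7.5 nu <(du'/dz)^2>`).
#'
#' @param k wavenumber, cycles per metre (> 0); vectorized.
#' @param epsilon TKE dissipation rate, W kg^-1 (> 0, scalar).
#' @param nu kinematic viscosity, m^2 s^-1 (> 0, scalar).
#' @return Spectral density `Phi(k)` in s^-2 cpm^-1, same length as `k`.
#' @examples
#' k <- 10^seq(0, 2.5, length.out = 100)
#' phi <- nasmyth_spectrum(k, epsilon = 1e-8, nu = 1.2e-6)
#' @export
nasmyth_spectrum <- function(k, epsilon, nu) {
  if (length(epsilon) != 1L || length(nu) != 1L) {
    stop("`epsilon` and `nu` must be scalars", call. = FALSE)
  }
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(nu) || nu <= 0) stop("`nu` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be finite and > 0", call. = FALSE)
  }
  ks <- kolmogorov_wavenumber(epsilon, nu)
  (epsilon^3 / nu)^(1 / 4) * .nasmyth_g2(k / ks)
}

#' Fraction of Nasmyth shear variance resolved in a wavenumber band
#'
#' @param k_lo,k_hi band limits, cpm (`k_lo >= 0`, `k_hi > k_lo`).
#' @param epsilon,nu dissipation rate and viscosity defining `k_s`.
#' @return Fraction in (0, 1] of the total model shear variance lying in
#'   `[k_lo, k_hi]`.
#' @export
nasmyth_variance_fraction <- function(k_lo, k_hi, epsilon, nu) {
  ks <- kolmogorov_wavenumber(epsilon, nu)
  .nasmyth_cdf(k_hi / ks) - .nasmyth_cdf(k_lo / ks)
}

#' Kinematic viscosity of seawater from temperature
#'
#' Standard temperature fit
#' `nu(T) = 1.792e-6 / (1 + 0.0337 T + 0.000221 T^2)` m^2 s^-1, adequate for
#' dissipation estimation (salinity dependence is a ~2% effect). A constant
#' can be supplied instead wherever a `nu` argument is taken.
#'
#' @param temperature in-situ temperature, degrees C; vectorized.
#' @return Kinematic viscosity, m^2 s^-1.
#' @export
seawater_viscosity <- function(temperature) {
  if (any(!is.finite(temperature))) {
    stop("`temperature` must be finite", call. = FALSE)
  }
  1.792e-6 / (1 + 0.0337 * temperature + 0.000221 * temperature^2)
}
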