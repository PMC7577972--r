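# Vertical turbulent nutrient fluxes F = -K dC/dz (z up; implemented on a
# depth-down grid so the upward flux is +K dC/d(depth)), and the downstream
# budgets: Redfield new production, steady-state chlorophyll depletion rate,
# and the tidal-excursion diagnostic.

#' Budget constants
#'
#' Constants of the production / depletion / excursion budgets with the
#' standard values: carbon atomic weight, Redfield carbon:nitrogen and
#' carbon:phosphorus ratios, the carbon:chlorophyll range for
#' pico-phytoplankton-dominated water, euphotic-zone thickness and mean
#' chlorophyll, the f-ratio, and the diurnal (K1) tidal amplitude and
#' frequency with the topographic half-width range.
#'
#' @param M_c atomic weight of carbon, g mol^-1.
#' @param r_CN Redfield C:N mole ratio.
#' @param r_CP Redfield C:P mole ratio.
#' @param r_CChl carbon-to-chlorophyll mass ratio range, g C (g Chl)^-1.
#' @param h_e euphotic-zone thickness, m.
#' @param C_bar euphotic-zone mean chlorophyll a, mg m^-3.
#' @param f_ratio new-to-total production ratio.
#' @param U_K1 diurnal tidal current amplitude, m s^-1.
#' @param omega_K1 diurnal tidal frequency, rad s^-1.
#' @param W_range topographic half-width range, km.
#' @return A validated `budget_constants` list.
#' @export
budget_constants <- function(M_c = 12, r_CN = 106 / 16, r_CP = 106,
                             r_CChl = c(25, 52), h_e = 100, C_bar = 0.4,
                             f_ratio = 0.5, U_K1 = 0.5, omega_K1 = 7.3e-5,
                             W_range = c(10, 20)) {
  vals <- c(M_c, r_CN, r_CP, r_CChl, h_e, C_bar, f_ratio, U_K1, omega_K1, W_range)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all budget constants must be finite and > 0", call. = FALSE)
  }
  if (diff(r_CChl) < 0) stop("`r_CChl` interval must be ordered", call. = FALSE)
  if (diff(W_range) < 0) stop("`W_range` interval must be ordered", call. = FALSE)
  structure(
    list(
      M_c = M_c, r_CN = r_CN, r_CP = r_CP, r_CChl = r_CChl, h_e = h_e,
      C_bar = C_bar, f_ratio = f_ratio, U_K1 = U_K1, omega_K1 = omega_K1,
      W_range = W_range
    ),
    class = "budget_constants"
  )
}

#' Vertical gradient of a profile quantity
#'
#' Centred differences on the interior, one-sided at the edges, after an
#' optional boxcar smoothing of the profile. Depth-down convention: a
#' quantity increasing downward has a positive gradient.
#'
#' @param x profile values.
#' @param depth depths, m, increasing.
#' @param smooth_scale boxcar window length, m (0 disables smoothing).
#' @return Gradient `dx/d(depth)`, per metre; NA where `x` is NA or a
#'   difference would cross a gap.
#' @export
vertical_gradient <- function(x, depth, smooth_scale = 10) {
  n <- length(x)
  stopifnot(length(depth) == n)
  if (sum(is.finite(x)) < 3) stop("need at least 3 valid points", call. = FALSE)
  if (smooth_scale > 0) {
    half <- smooth_scale / 2
    xs <- vapply(seq_len(n), function(i) {
      w <- which(depth >= depth[i] - half & depth <= depth[i] + half)
      v <- x[w]
      if (all(!is.finite(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  } else {
    xs <- x
  }
  g <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- if (i > 1) i - 1L else i
    hi <- if (i < n) i + 1L else i
    if (is.finite(xs[lo]) && is.finite(xs[hi]) && hi > lo) {
      g[i] <- (xs[hi] - xs[lo]) / (depth[hi] - depth[lo])
    }
  }
  g
}

#' Vertical turbulent flux from diffusivity and gradient
#'
#' Upward flux `F = K * dC/d(depth)` (the depth-down form of
#' `F = -K dC/dz`), converted from per-second to per-day. Masked wherever K
#' or the gradient is masked.
#'
#' @param k_rho eddy diffusivity profile, m^2 s^-1 (NA where masked), or a
#'   `diffusivity_profile` data.frame.
#' @param gradient nutrient gradient `dC/d(depth)`, mmol m^-4.
#' @param depth depths, m (taken from `k_rho` if it is a profile).
#' @return A `flux_profile` data.frame: `depth`, `flux`
#'   (mmol m^-2 d^-1, positive upward), `k_rho`, `gradient`.
#' @export
turbulent_flux <- function(k_rho, gradient, depth = NULL) {
  if (is.data.frame(k_rho)) {
    depth <- k_rho$depth
    k <- k_rho$k_rho
  } else {
    k <- k_rho
  }
  if (length(k) != length(gradient)) {
    stop("diffusivity and gradient grids differ in length", call. = FALSE)
  }
  flux <- ifelse(is.finite(k) & is.finite(gradient),
    k * gradient * 86400, NA_real_
  )
  out <- data.frame(depth = depth, flux = flux, k_rho = k, gradient = gradient)
  class(out) <- c("flux_profile", "data.frame")
  out
}

#' Flux at the euphotic-zone base
#'
#' The headline flux is the value at the `h_e` horizon (default 100 m). With
#' `window > 0` the maximum over `h_e +/- window` is taken instead.
#'
#' @param flux a `flux_profile`.
#' @param horizon depth of record, m.
#' @param window half-window for a local maximum search, m (0 = value at
#'   the nearest bin).
#' @return Flux value, mmol m^-2 d^-1.
#' @export
flux_at_horizon <- function(flux, horizon = 100, window = 0) {
  if (window > 0) {
    sel <- which(flux$depth >= horizon - window & flux$depth <= horizon + window)
    v <- flux$flux[sel]
    if (!any(is.finite(v))) return(NA_real_)
    return(max(v, na.rm = TRUE))
  }
  ok <- which(is.finite(flux$flux))
  if (!length(ok)) return(NA_real_)
  i <- ok[which.min(abs(flux$depth[ok] - horizon))]
  flux$flux[i]
}

#' New production from a nutrient flux
#'
#' Converts an upward nutrient flux at the euphotic-zone base to
#' carbon-based new production, `M_c * r * F / 1000` g C m^-2 d^-1, with
#' `r = r_CN` for nitrate and `r = r_CP` for phosphate. An uncertainty on
#' the flux propagates linearly.
#'
#' @param flux nutrient flux, mmol m^-2 d^-1.
#' @param species `"nitrate"` or `"phosphate"`.
#' @param constants a [budget_constants()].
#' @param flux_hw optional half-width on the flux (same units).
#' @return List `value` (g C m^-2 d^-1) and `hw`.
#' @export
new_production <- function(flux, species = c("nitrate", "phosphate"),
                           constants = budget_constants(), flux_hw = NULL) {
  species <- match.arg(species)
  r <- switch(species, nitrate = constants$r_CN, phosphate = constants$r_CP)
  value <- constants$M_c * r * flux / 1000
  hw <- if (is.null(flux_hw)) NA_real_ else constants$M_c * r * flux_hw / 1000
  list(value = value, hw = hw, species = species)
}

#' Steady-state chlorophyll depletion rate
#'
#' Equates carbon-based production from the upward nitrate flux to
#' chlorophyll loss: `M_c r_CN r_CChl^-1 F = gamma h_e C_bar`, so
#' `gamma = M_c r_CN F / (r_CChl h_e C_bar)` (d^-1), evaluated at both ends
#' of the carbon:chlorophyll range. Dividing by the f-ratio removes the
#' new-production-only restriction (regenerated production scales the
#' growth the same flux can sustain).
#'
#' @param flux nitrate flux, mmol N m^-2 d^-1.
#' @param constants a [budget_constants()].
#' @param flux_hw optional half-width on the flux.
#' @return List with `gamma` (named `lower`/`upper`, d^-1; lower at the
#'   large C:Chl end), `gamma_hw`, `gamma_modified`, `gamma_modified_hw`.
#' @export
depletion_rate <- function(flux, constants = budget_constants(),
                           flux_hw = NULL) {
  if (constants$C_bar <= 0 || constants$h_e <= 0) {
    stop("`C_bar` and `h_e` must be > 0", call. = FALSE)
  }
  g <- constants$M_c * constants$r_CN * flux /
    (constants$r_CChl * constants$h_e * constants$C_bar)
  gamma <- c(lower = min(g), upper = max(g))
  rel <- if (is.null(flux_hw)) NA_real_ else flux_hw / flux
  list(
    gamma = gamma,
    gamma_hw = gamma * rel,
    gamma_modified = gamma / constants$f_ratio,
    gamma_modified_hw = gamma * rel / constants$f_ratio,
    r_CChl = c(lower = max(constants$r_CChl), upper = min(constants$r_CChl))
  )
}

#' Tidal excursion length and topographic ratio
#'
#' `L_e = U_K1 / omega_K1`, the horizontal distance a parcel travels in a
#' tidal oscillation, compared to the topographic half-width `W`: ratios
#' well above one mean advection controls the tracer field over the ridge.
#'
#' @param constants a [budget_constants()].
#' @return List `L_e_km` and `ratio_range` (`L_e/W` at `W_range` ends,
#'   small ratio first).
#' @export
tidal_excursion <- function(constants = budget_constants()) {
  le_km <- constants$U_K1 / constants$omega_K1 / 1000
  ratio <- sort(le_km / constants$W_range)
  list(L_e_km = le_km, ratio_range = ratio)
}

#' Propagate regression uncertainty to a flux
#'
#' The reconstructed nutrient gradient is linear in the regression slope, so
#' the relative flux half-width equals the relative slope half-width; other
#' error sources (sampling variability of epsilon, N^2) are deliberately not
#' folded in.
#'
#' @param flux flux value, mmol m^-2 d^-1.
#' @param model the `regression_model` used for nutrient reconstruction.
#' @return List `flux`, `hw`, `relative`.
#' @export
propagate_uncertainty <- function(flux, model) {
  if (is.null(model$slope_hw) || !is.finite(model$slope_hw)) {
    stop("regression model carries no confidence half-width", call. = FALSE)
  }
  rel <- model$slope_hw / abs(model$slope)
  list(flux = flux, hw = abs(flux) * rel, relative = rel)
}

#' Full budget from a headline nitrate/phosphate flux
#'
#' Convenience wrapper producing the headline numbers: N- and P-based new
#' production, the depletion-rate range with its f-ratio-modified version,
#' and the tidal excursion diagnostic.
#'
#' @param flux_no3 nitrate flux, mmol N m^-2 d^-1.
#' @param flux_po4 phosphate flux, mmol P m^-2 d^-1 (optional).
#' @param constants a [budget_constants()].
#' @param flux_no3_hw,flux_po4_hw optional half-widths.
#' @return A `budget_result` list.
#' @export
budget_report <- function(flux_no3, flux_po4 = NA_real_,
                          constants = budget_constants(),
                          flux_no3_hw = NULL, flux_po4_hw = NULL) {
  np_n <- new_production(flux_no3, "nitrate", constants, flux_no3_hw)
  np_p <- if (is.finite(flux_po4)) {
    new_production(flux_po4, "phosphate", constants, flux_po4_hw)
  } else {
    list(value = NA_real_, hw = NA_real_)
  }
  dep <- depletion_rate(flux_no3, constants, flux_no3_hw)
  structure(
    list(
      flux_no3 = flux_no3, flux_no3_hw = if (is.null(flux_no3_hw)) NA_real_ else flux_no3_hw,
      flux_po4 = flux_po4,
      new_production_n = np_n, new_production_p = np_p,
      depletion = dep, excursion = tidal_excursion(constants),
      constants = constants
    ),
    class = "budget_result"
  )
}

#' @export
print.budget_result <- function(x, ...) {
  cat("<budget_result>\n")
  cat(sprintf(
    "  nitrate flux at h_e: %.3g +/- %.3g mmol N m-2 d-1\n",
    x$flux_no3, x$flux_no3_hw
  ))
  cat(sprintf(
    "  new production (N): %.3g +/- %.3g g C m-2 d-1\n",
    x$new_production_n$value, x$new_production_n$hw
  ))
  if (is.finite(x$new_production_p$value)) {
    cat(sprintf(
      "  new production (P): %.3g +/- %.3g g C m-2 d-1\n",
      x$new_production_p$value, x$new_production_p$hw
    ))
  }
  cat(sprintf(
    "  depletion rate gamma: %.3g-%.3g d-1 (modified: %.3g-%.3g d-1)\n",
    x$depletion$gamma["lower"], x$depletion$gamma["upper"],
    x$depletion$gamma_modified["lower"], x$depletion$gamma_modified["upper"]
  ))
  cat(sprintf(
    "  tidal excursion L_e = %.2f km, L_e/W = %.2f-%.2f\n",
    x$excursion$L_e_km, x$excursion$ratio_range[1], x$excursion$ratio_range[2]
  ))
  invisible(x)
}
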