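# Linear theta-nutrient regressions (pooled and station-specific) and the
# two-step fluorescence -> chlorophyll calibration chain. Confidence limits
# are 95% Student-t intervals on ordinary least squares.

#' Fit a simple linear regression with Student-t confidence limits
#'
#' Ordinary least squares of `y` on `x`; the confidence half-widths are
#' `t_{n-2, 1-alpha/2}` times the coefficient standard errors.
#'
#' @param x predictor values.
#' @param y response values.
#' @param confidence confidence level (default 0.95).
#' @param label optional label (species / station scope).
#' @param valid_range predictor interval inside which predictions are
#'   considered valid; defaults to `range(x)`.
#' @return A `regression_model`: list with `slope`, `slope_hw`, `intercept`,
#'   `intercept_hw`, `n`, `sigma`, `valid_range`, `label`.
#' @export
fit_linear <- function(x, y, confidence = 0.95, label = "",
                       valid_range = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite (x, y) pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero predictor variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 2)
  regression_model(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_hw = unname(tq * se[2]),
    intercept_hw = unname(tq * se[1]),
    n = n,
    sigma = summary(fit)$sigma,
    valid_range = if (is.null(valid_range)) range(x) else valid_range,
    label = label
  )
}

#' Construct a regression model from known coefficients
#'
#' @param slope,intercept coefficients.
#' @param slope_hw,intercept_hw 95% confidence half-widths (>= 0).
#' @param n number of observations behind the fit (NA if external).
#' @param sigma residual standard deviation (optional).
#' @param valid_range predictor interval of validity.
#' @param label scope label.
#' @return A `regression_model`.
#' @export
regression_model <- function(slope, intercept, slope_hw = 0, intercept_hw = 0,
                             n = NA_integer_, sigma = NA_real_,
                             valid_range = c(-Inf, Inf), label = "") {
  if (slope_hw < 0 || intercept_hw < 0) {
    stop("confidence half-widths must be >= 0", call. = FALSE)
  }
  structure(
    list(
      slope = slope, intercept = intercept, slope_hw = slope_hw,
      intercept_hw = intercept_hw, n = n, sigma = sigma,
      valid_range = valid_range, label = label
    ),
    class = "regression_model"
  )
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf(
    "<regression_model%s> y = (%.4g +/- %.3g) x + (%.4g +/- %.3g), n = %s, valid x in [%.3g, %.3g]\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$slope, x$slope_hw, x$intercept, x$intercept_hw,
    ifelse(is.na(x$n), "?", x$n), x$valid_range[1], x$valid_range[2]
  ))
  invisible(x)
}

#' Predict from a regression model
#'
#' @param object a `regression_model`.
#' @param newdata predictor values.
#' @param extrapolate allow prediction outside `valid_range`
#'   (default FALSE: masked as NA).
#' @param ... unused.
#' @return Predicted responses, NA outside the valid range.
#' @export
predict.regression_model <- function(object, newdata, extrapolate = FALSE,
                                     ...) {
  y <- object$slope * newdata + object$intercept
  if (!extrapolate) {
    y[newdata < object$valid_range[1] | newdata > object$valid_range[2]] <- NA_real_
  }
  y
}

#' Cruise nutrient regression registry
#'
#' The temperature-nutrient regressions used to reconstruct nutrient
#' profiles from potential temperature: a pooled model per species fitted
#' over the theta > 15 degC range, and a separate model for station L4,
#' where turbulence and the temperature structure differ from the rest of
#' the section. Coefficients are 95% Student-t limits.
#'
#' @return Nested list: `registry[[species]]$pooled` and optional
#'   station-named overrides (`$L4`), each a [regression_model()].
#' @export
nutrient_models <- function() {
  vr <- c(15, 27)
  list(
    nitrate = list(
      pooled = regression_model(-0.540, 14.077, 0.085, 1.881,
        valid_range = vr, label = "nitrate pooled"
      ),
      L4 = regression_model(-0.939, 24.666, 0.380, 8.776,
        valid_range = vr, label = "nitrate L4"
      )
    ),
    phosphate = list(
      pooled = regression_model(-0.032, 0.819, 0.006, 0.138,
        valid_range = vr, label = "phosphate pooled"
      ),
      L4 = regression_model(-0.065, 1.720, 0.031, 0.719,
        valid_range = vr, label = "phosphate L4"
      )
    )
  )
}

#' Select the nutrient regression for a station
#'
#' Station-specific model when one is registered (e.g. L4), the pooled model
#' otherwise.
#'
#' @param station station label.
#' @param species `"nitrate"` or `"phosphate"`.
#' @param registry registry as returned by [nutrient_models()].
#' @return A `regression_model`.
#' @export
select_nutrient_model <- function(station, species = "nitrate",
                                  registry = nutrient_models()) {
  if (!length(registry)) stop("empty model registry", call. = FALSE)
  models <- registry[[species]]
  if (is.null(models)) stop(sprintf("unknown species '%s'", species), call. = FALSE)
  if (!is.null(models[[station]])) models[[station]] else models$pooled
}

#' Reconstruct a nutrient profile from potential temperature
#'
#' Applies the linear theta-nutrient relation where theta exceeds
#' `theta_min` (15 degC by default: the relation is fitted in, and the flux
#' of interest crosses, the warm upper layer); masked elsewhere. Negative
#' predictions are clipped to zero and flagged.
#'
#' @param theta potential temperature profile, deg C.
#' @param model a `regression_model`.
#' @param theta_min validity threshold, deg C.
#' @return data.frame `theta`, `concentration` (mmol m^-3, NA where masked),
#'   `flag` (`"ok"`, `"theta-out-of-range"`, `"clipped"`).
#' @export
nutrient_from_theta <- function(theta, model, theta_min = 15) {
  conc <- model$slope * theta + model$intercept
  flag <- rep("ok", length(theta))
  mask <- !is.finite(theta) | theta <= theta_min
  conc[mask] <- NA_real_
  flag[mask] <- "theta-out-of-range"
  neg <- !mask & conc < 0
  conc[neg] <- 0
  flag[neg] <- "clipped"
  data.frame(theta = theta, concentration = conc, flag = flag)
}

#' Two-step fluorescence calibration chain
#'
#' Stage 1 maps profiler fluorescence to the reference (CTD rosette)
#' fluorometer; stage 2 maps reference fluorescence to bottle chlorophyll a.
#' Both stages are affine, so the chain composes to a single affine map.
#'
#' @param stage1,stage2 [regression_model()] objects.
#' @param min_depth minimum depth (m) of the pairs used to fit the chain;
#'   shallow daytime fluorescence is depressed by non-photochemical
#'   quenching, so calibration pairs are taken at ~100 m and deeper.
#' @return A `calibration_chain`.
#' @export
calibration_chain <- function(stage1, stage2, min_depth = 100) {
  stopifnot(inherits(stage1, "regression_model"), inherits(stage2, "regression_model"))
  structure(
    list(stage1 = stage1, stage2 = stage2, min_depth = min_depth),
    class = "calibration_chain"
  )
}

#' Default calibration chain (cruise coefficients)
#'
#' `Flu_ref = 1.42 Flu_tm + 0.10` then `Chl = 1.11 Flu_ref - 0.08`, with the
#' 95% half-widths of the cruise fits.
#'
#' @return A [calibration_chain()].
#' @export
default_calibration_chain <- function() {
  calibration_chain(
    regression_model(1.42, 0.10, 0.09, 0.01, label = "Flu_tm -> Flu_ref"),
    regression_model(1.11, -0.08, 0.25, 0.05, label = "Flu_ref -> Chl")
  )
}

#' Stage coefficients of a calibration chain
#'
#' @param chain a `calibration_chain`.
#' @return Named numeric `c(slope, intercept)`.
#' @export
stage1_coef <- function(chain) {
  c(slope = chain$stage1$slope, intercept = chain$stage1$intercept)
}

#' @rdname stage1_coef
#' @export
stage2_coef <- function(chain) {
  c(slope = chain$stage2$slope, intercept = chain$stage2$intercept)
}

#' Composed affine map of a calibration chain
#'
#' @param chain a `calibration_chain`.
#' @return Named numeric `c(slope, intercept)` of the single affine map
#'   `Chl = slope * Flu_tm + intercept`.
#' @export
compose_calibration <- function(chain) {
  a1 <- stage1_coef(chain)
  a2 <- stage2_coef(chain)
  c(
    slope = unname(a2["slope"] * a1["slope"]),
    intercept = unname(a2["slope"] * a1["intercept"] + a2["intercept"])
  )
}

#' Convert profiler fluorescence to chlorophyll a
#'
#' Applies both calibration stages; negative chlorophyll is clipped at zero
#' and flagged.
#'
#' @param flu profiler fluorescence values.
#' @param chain a [calibration_chain()].
#' @return data.frame `fluorescence`, `chl` (mg m^-3), `flag`.
#' @export
apply_calibration_chain <- function(flu, chain = default_calibration_chain()) {
  if (is.null(chain$stage1) || is.null(chain$stage2)) {
    stop("calibration chain is missing a stage", call. = FALSE)
  }
  s1 <- stage1_coef(chain)
  s2 <- stage2_coef(chain)
  chl <- s2["slope"] * (s1["slope"] * flu + s1["intercept"]) + s2["intercept"]
  chl <- unname(chl)
  flag <- rep("ok", length(flu))
  neg <- is.finite(chl) & chl < 0
  chl[neg] <- 0
  flag[neg] <- "clipped"
  data.frame(fluorescence = flu, chl = chl, flag = flag)
}

#' Fit the two-stage fluorescence calibration chain
#'
#' Stage 1 regresses reference fluorescence on profiler fluorescence using
#' co-located pairs at `min_depth` or deeper; stage 2 regresses bottle
#' chlorophyll on reference fluorescence, again at depth, to avoid
#' near-surface non-photochemical quenching.
#'
#' @param tm data.frame `depth`, `fluorescence` (profiler).
#' @param ctd data.frame `depth`, `fluorescence` (reference fluorometer).
#' @param bottles data.frame `depth`, `chl`.
#' @param min_depth minimum depth of calibration pairs, m.
#' @param match_tol maximum depth mismatch when pairing records, m.
#' @return A [calibration_chain()].
#' @export
fit_calibration_chain <- function(tm, ctd, bottles, min_depth = 100,
                                  match_tol = 2) {
  pair <- function(da, va, db, vb) {
    keep <- which(da >= min_depth)
    j <- vapply(da[keep], function(z) {
      i <- which.min(abs(db - z))
      if (abs(db[i] - z) <= match_tol) i else NA_integer_
    }, integer(1))
    ok <- !is.na(j)
    cbind(va[keep][ok], vb[j[ok]])
  }
  p1 <- pair(tm$depth, tm$fluorescence, ctd$depth, ctd$fluorescence)
  if (nrow(p1) < 3) {
    stop("fewer than 3 qualifying fluorescence pairs at depth", call. = FALSE)
  }
  stage1 <- fit_linear(p1[, 1], p1[, 2], label = "Flu_tm -> Flu_ref")
  p2 <- pair(bottles$depth, bottles$chl, ctd$depth, ctd$fluorescence)
  if (nrow(p2) < 3) {
    stop("fewer than 3 qualifying chlorophyll pairs at depth", call. = FALSE)
  }
  stage2 <- fit_linear(p2[, 2], p2[, 1], label = "Flu_ref -> Chl")
  calibration_chain(stage1, stage2, min_depth = min_depth)
}
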