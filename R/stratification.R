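# Stratification from potential density: Thorpe resorting, buoyancy
# frequency from the resorted profile, mixed-layer depth by density
# threshold, and the Osborn eddy diffusivity K_rho = Gamma * epsilon / N^2.

# Gravitational acceleration and reference density used throughout.
.g <- 9.81 # m s^-2
.rho0 <- 1027.0 # kg m^-3

#' Thorpe resorting of a potential density profile
#'
#' Rearranges observed potential density into its stable (non-decreasing with
#' depth) order. The Thorpe displacement of each sample is its observed depth
#' minus the depth it is moved to; non-zero displacements mark overturns.
#' Missing values are excluded with a warning and reinserted as gaps.
#'
#' @param depth depth, m positive down, increasing.
#' @param sigma observed potential density anomaly (or density), kg m^-3.
#' @return A `stratification_profile` data.frame with columns `depth`,
#'   `sigma_obs`, `sigma_sorted`, `displacement` (m).
#' @export
thorpe_resort <- function(depth, sigma) {
  stopifnot(length(depth) == length(sigma))
  if (any(diff(depth) <= 0)) stop("`depth` must be strictly increasing", call. = FALSE)
  ok <- is.finite(sigma)
  if (!all(ok)) {
    warning(sprintf("%d missing density values excluded from resorting", sum(!ok)))
  }
  d <- depth[ok]
  s <- sigma[ok]
  ord <- order(s) # stable in R: ties keep observed (depth) order
  out <- data.frame(
    depth = depth,
    sigma_obs = sigma,
    sigma_sorted = NA_real_,
    displacement = NA_real_
  )
  out$sigma_sorted[ok] <- s[ord]
  # sample originally at d[ord[i]] ends up at depth d[i]
  disp <- numeric(length(d))
  disp[ord] <- d[ord] - d
  out$displacement[ok] <- disp
  class(out) <- c("stratification_profile", "data.frame")
  out
}

#' Buoyancy frequency squared from a resorted density profile
#'
#' `N^2 = (g / rho0) * d(rho_s)/d(depth)` with depth positive down (the
#' z-up form carries a minus sign), from centred first differences of the
#' resorted density over a smoothing scale. Values below `n2_floor` are set
#' to the floor and flagged: resorting guarantees `d(rho_s)/d(depth) >= 0`,
#' but homogeneous layers give zeros that would blow up `K_rho`.
#'
#' @param strat a `stratification_profile` from [thorpe_resort()], or a
#'   data.frame with `depth` and `sigma_sorted`.
#' @param smoothing_scale vertical scale of the difference stencil, m.
#' @param n2_floor minimum admissible N^2, s^-2.
#' @return data.frame `depth`, `n2` (s^-2), `n2_flag`
#'   (`"ok"` / `"floored"`).
#' @export
buoyancy_frequency <- function(strat, smoothing_scale = 10, n2_floor = 1e-7) {
  depth <- strat$depth
  rho <- strat$sigma_sorted
  ok <- is.finite(rho)
  if (sum(ok) < 3) stop("need at least 3 valid points", call. = FALSE)
  d <- depth[ok]
  r <- rho[ok]
  half <- smoothing_scale / 2
  n2 <- vapply(seq_along(d), function(i) {
    lo <- max(which(d >= d[i] - half)[1], 1L)
    hi <- max(which(d <= d[i] + half))
    if (hi == lo) {
      lo <- max(1L, i - 1L)
      hi <- min(length(d), i + 1L)
    }
    (.g / .rho0) * (r[hi] - r[lo]) / (d[hi] - d[lo])
  }, numeric(1))
  out <- data.frame(depth = d, n2 = pmax(n2, n2_floor))
  out$n2_flag <- ifelse(n2 < n2_floor, "floored", "ok")
  out
}

#' Mixed-layer depth by density threshold
#'
#' Shallowest depth at which potential density exceeds the uppermost observed
#' density by `threshold` (default 0.03 kg m^-3), linearly interpolated
#' between the bracketing grid points. If the criterion is never met the
#' deepest depth is returned with attribute `criterion_met = FALSE`.
#'
#' @param depth depth, m, increasing.
#' @param sigma potential density, kg m^-3.
#' @param threshold density deviation defining the mixed-layer base, kg m^-3.
#' @return Mixed-layer depth, m, with attribute `criterion_met`.
#' @export
mixed_layer_depth <- function(depth, sigma, threshold = 0.03) {
  ok <- is.finite(sigma)
  depth <- depth[ok]
  sigma <- sigma[ok]
  if (length(depth) < 2) stop("need at least 2 valid points", call. = FALSE)
  dev <- sigma - sigma[1]
  idx <- which(dev >= threshold)
  if (!length(idx)) {
    return(structure(depth[length(depth)], criterion_met = FALSE))
  }
  i <- idx[1]
  if (i == 1) {
    return(structure(depth[1], criterion_met = TRUE))
  }
  # linear interpolation between the bracketing points
  f <- (threshold - dev[i - 1]) / (dev[i] - dev[i - 1])
  structure(depth[i - 1] + f * (depth[i] - depth[i - 1]), criterion_met = TRUE)
}

#' Osborn eddy diffusivity
#'
#' `K_rho = Gamma * epsilon / N^2` with constant mixing efficiency
#' `Gamma = 0.2`, evaluated below the surface mixed layer only (the
#' production-dissipation balance behind the relation fails inside it).
#' Bins with rejected epsilon or floored N^2 are masked with a reason.
#'
#' @param dissipation `dissipation_profile` data.frame (`depth`, `epsilon`).
#' @param n2 data.frame from [buoyancy_frequency()] (`depth`, `n2`,
#'   `n2_flag`) on the same grid, or interpolable to it.
#' @param mld mixed-layer depth, m.
#' @param gamma mixing efficiency (default 0.2).
#' @return A `diffusivity_profile` data.frame: `depth`, `k_rho` (m^2 s^-1,
#'   NA where masked), `epsilon`, `n2`, `mask`
#'   (`"ok"`, `"mixed-layer"`, `"rejected-epsilon"`, `"n2-floor"`).
#' @export
osborn_diffusivity <- function(dissipation, n2, mld, gamma = 0.2) {
  depth <- dissipation$depth
  if (!all(depth %in% n2$depth)) {
    if (max(abs(range(depth) - range(n2$depth))) > max(diff(n2$depth)) * 2 &&
      (min(depth) < min(n2$depth) - 1 || max(depth) > max(n2$depth) + 1)) {
      stop("dissipation and N^2 grids do not overlap", call. = FALSE)
    }
    n2v <- stats::approx(n2$depth, n2$n2, xout = depth, rule = 2)$y
    n2f <- n2$n2_flag[pmax(1, findInterval(depth, n2$depth))]
  } else {
    m <- match(depth, n2$depth)
    n2v <- n2$n2[m]
    n2f <- n2$n2_flag[m]
  }
  mask <- rep("ok", length(depth))
  mask[n2f == "floored"] <- "n2-floor"
  mask[!is.finite(dissipation$epsilon)] <- "rejected-epsilon"
  mask[depth <= mld] <- "mixed-layer"
  k <- ifelse(mask == "ok", gamma * dissipation$epsilon / n2v, NA_real_)
  out <- data.frame(
    depth = depth, k_rho = k, epsilon = dissipation$epsilon,
    n2 = n2v, gamma = gamma, mask = mask
  )
  class(out) <- c("diffusivity_profile", "data.frame")
  out
}
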