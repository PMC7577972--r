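# Seeded synthetic cruise generator. Emits (a) microstructure shear records
# whose wavenumber spectra follow the Nasmyth form at a prescribed
# epsilon(z), (b) density/temperature/fluorescence profiles with a mixed
# layer, prescribed N^2(z) and optionally injected overturns, and (c) bottle
# nutrients obeying linear theta-nutrient relations plus noise. Every
# observable is a deterministic function of the configuration and seed, so
# downstream stages have exact ground truth to recover.

#' Synthetic cruise configuration
#'
#' Ground-truth fields and noise levels for the generator. Defaults emulate a
#' short cross-ridge section: a bottom-intensified band of strong turbulence
#' peaking at the central ("ridge") station over a quiet open-ocean
#' background, a 40 m mixed layer, uniform thermocline stratification, and
#' nutrient/chlorophyll relations with realistic scatter.
#'
#' @param seed integer seed; identical seed + config give bit-identical
#'   output.
#' @param n_stations number of stations (labelled `L1 ... Ln`).
#' @param depth_max maximum profile depth, m.
#' @param epsilon_truth function `(depth, station)` -> dissipation rate,
#'   W kg^-1, strictly positive.
#' @param n2_truth function `(depth)` -> N^2, s^-2, non-negative.
#' @param mld_truth mixed-layer depth, m (< `depth_max`).
#' @param theta_surface mixed-layer potential temperature, deg C.
#' @param dtheta_dz vertical temperature gradient below the mixed layer,
#'   deg C per m (negative: cooling downward).
#' @param nutrient_coef named list per species of `c(slope, intercept)`
#'   (mmol m^-3 per deg C, mmol m^-3) used to generate bottle nutrients.
#' @param chl_truth function `(depth)` -> chlorophyll a, mg m^-3.
#' @param calibration a [calibration_chain()] inverted to turn true
#'   chlorophyll into profiler fluorescence.
#' @param noise_sd named list of additive Gaussian noise standard deviations:
#'   `sigma` (kg m^-3), `theta` (deg C), `nitrate`, `phosphate`
#'   (mmol m^-3), `chl` (mg m^-3), `flu` (fluorescence units).
#' @param fall_speed profiler fall speed, m s^-1.
#' @param sample_rate shear sampling rate, Hz.
#' @param dz hydrographic grid step, m.
#' @param overturn_spec list of `list(station=, center=, extent=)` density
#'   inversions to inject (local permutations of the stable profile).
#' @param bottle_depths bottle sampling depths, m.
#' @param quench if `TRUE`, suppress generated fluorescence above 50 m by
#'   40% (daytime non-photochemical quenching analogue).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_stations = 5,
                             depth_max = 500,
                             epsilon_truth = NULL,
                             n2_truth = function(depth) rep(2e-5, length(depth)),
                             mld_truth = 40,
                             theta_surface = 24,
                             dtheta_dz = -0.025,
                             nutrient_coef = list(
                               nitrate = c(slope = -0.540, intercept = 14.077),
                               phosphate = c(slope = -0.032, intercept = 0.819)
                             ),
                             chl_truth = function(depth) {
                               0.05 + 0.55 * exp(-((depth - 30) / 35)^2)
                             },
                             calibration = default_calibration_chain(),
                             noise_sd = list(
                               sigma = 0.002, theta = 0.01, nitrate = 0.5,
                               phosphate = 0.03, chl = 0.03, flu = 0.02
                             ),
                             fall_speed = 0.6,
                             sample_rate = 512,
                             dz = 1,
                             overturn_spec = list(),
                             bottle_depths = c(0, 50, 100, 200, 300, 400),
                             quench = FALSE) {
  if (is.null(epsilon_truth)) {
    ridge <- ceiling(n_stations / 2)
    epsilon_truth <- function(depth, station) {
      # station-dependent amplitude: 1e-7 at the ridge, ~1e-9 far from it,
      # on a 1e-10 background; vertically a broad mid-depth band
      amp <- 10^(-9 + 2 * exp(-0.5 * ((station - ridge) / 1)^2))
      1e-10 + amp * exp(-((depth - 250) / 150)^2)
    }
  }
  stopifnot(mld_truth < depth_max, fall_speed > 0, sample_rate > 0, dz > 0)
  zchk <- seq(0, depth_max, by = 5)
  for (s in seq_len(n_stations)) {
    if (any(epsilon_truth(zchk, s) <= 0)) {
      stop("`epsilon_truth` must be strictly positive everywhere", call. = FALSE)
    }
  }
  if (any(n2_truth(zchk) < 0)) {
    stop("`n2_truth` must be non-negative", call. = FALSE)
  }
  for (ov in overturn_spec) {
    if (ov$center - ov$extent / 2 < 0 || ov$center + ov$extent / 2 > depth_max) {
      stop("overturn extent exceeds the depth range", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_stations = n_stations, depth_max = depth_max,
      epsilon_truth = epsilon_truth, n2_truth = n2_truth,
      mld_truth = mld_truth, theta_surface = theta_surface,
      dtheta_dz = dtheta_dz, nutrient_coef = nutrient_coef,
      chl_truth = chl_truth, calibration = calibration, noise_sd = noise_sd,
      fall_speed = fall_speed, sample_rate = sample_rate, dz = dz,
      overturn_spec = overturn_spec, bottle_depths = bottle_depths,
      quench = quench
    ),
    class = "synthetic_config"
  )
}

# Independent substream per (station, kind) so regenerating one product does
# not perturb another. Kept well below 2^31.
.sub_seed <- function(config, station, kind) {
  offs <- c(shear = 11, hydro = 23, bottle = 37, cast = 53)
  as.integer((abs(as.numeric(config$seed)) * 977 + station * 7919 + offs[[kind]]) %% 2147483647)
}

#' True potential temperature profile of the generator
#'
#' Uniform at `theta_surface` within the mixed layer, then linear in depth
#' with slope `dtheta_dz`, floored at 2 deg C.
#'
#' @param config a [synthetic_config()].
#' @param depth depths, m.
#' @return Potential temperature, deg C.
#' @export
theta_truth <- function(config, depth) {
  th <- ifelse(depth <= config$mld_truth,
    config$theta_surface,
    config$theta_surface + config$dtheta_dz * (depth - config$mld_truth)
  )
  pmax(th, 2)
}

# Stable (pre-overturn, noise-free) potential density profile implied by
# n2_truth: uniform above the mixed layer, d(sigma)/dz = N^2 rho0 / g below.
.sigma_stable <- function(config, depth) {
  n2 <- config$n2_truth(depth)
  dsig <- ifelse(depth <= config$mld_truth, 0, n2 * .rho0 / .g)
  sig <- 23.5 + cumsum(c(0, (dsig[-1] + dsig[-length(dsig)]) / 2 * diff(depth)))
  sig
}

#' Ground truth record for a station
#'
#' Everything the generator used: the truth functions evaluated on the hydro
#' grid plus the regression and calibration coefficients, for
#' parameter-recovery assertions in tests.
#'
#' @param config a [synthetic_config()].
#' @param station station index.
#' @return List with `depth`, `epsilon`, `n2`, `theta`, `sigma_stable`,
#'   `chl`, `mld`, `nutrient_coef`, `calibration`.
#' @export
truth_record <- function(config, station) {
  depth <- seq(0, config$depth_max, by = config$dz)
  list(
    station = station,
    depth = depth,
    epsilon = config$epsilon_truth(depth, station),
    n2 = config$n2_truth(depth),
    theta = theta_truth(config, depth),
    sigma_stable = .sigma_stable(config, depth),
    chl = config$chl_truth(depth),
    mld = config$mld_truth,
    nutrient_coef = config$nutrient_coef,
    calibration = config$calibration
  )
}

# Synthesize one stationary block of shear with a one-sided wavenumber
# spectrum equal to the Nasmyth model at (epsilon, nu): independent zero-mean
# Gaussian spectral amplitudes with variance proportional to the model
# spectrum, inverse-transformed to the time domain.
.shear_block <- function(n, epsilon, nu, fall_speed, sample_rate) {
  half <- floor(n / 2)
  f <- (1:half) * sample_rate / n
  k <- f / fall_speed
  s_f <- nasmyth_spectrum(k, epsilon, nu) / fall_speed # Phi(f) = Phi(k) * dk/df
  amp <- sqrt(sample_rate * n * s_f / 2)
  re <- stats::rnorm(half) / sqrt(2)
  im <- stats::rnorm(half) / sqrt(2)
  X <- complex(real = amp * re, imaginary = amp * im)
  # Nyquist bin is real and counted once in the Parseval sum
  if (n %% 2 == 0) X[half] <- complex(real = 2 * amp[half] * re[half], imaginary = 0)
  full <- complex(real = numeric(n), imaginary = numeric(n))
  full[2:(half + 1)] <- X
  if (n %% 2 == 0) {
    full[(half + 2):n] <- Conj(X[(half - 1):1])
  } else {
    full[(half + 2):n] <- Conj(X[half:1])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Generate a synthetic microstructure shear record
#'
#' Builds a free-fall cast whose shear series, block by block, has the
#' one-sided Nasmyth wavenumber spectrum at the locally prescribed
#' `epsilon_truth(depth)` and temperature-derived viscosity.
#'
#' @param config a [synthetic_config()].
#' @param station station index in `1:n_stations`.
#' @param cast cast number (distinct casts get independent noise).
#' @param duration_s record length, s; default covers `depth_max` at the
#'   fall speed.
#' @param n_probes number of shear probes (1 or 2).
#' @param block_s stationarity block length for synthesis, s.
#' @param nu constant viscosity override (default: from the temperature
#'   track).
#' @return A [shear_record()].
#' @export
generate_shear_record <- function(config, station, cast = 1,
                                  duration_s = NULL, n_probes = 2,
                                  block_s = 4, nu = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(duration_s)) duration_s <- config$depth_max / config$fall_speed
  fs <- config$sample_rate
  n <- round(duration_s * fs)
  nb <- round(block_s * fs)
  time <- (seq_len(n) - 1) / fs
  depth <- time * config$fall_speed
  theta <- theta_truth(config, depth)
  set.seed(.sub_seed(config, station, "shear") + 101L * as.integer(cast))
  starts <- seq(1L, n, by = nb)
  shear <- matrix(0, nrow = n, ncol = n_probes)
  for (p in seq_len(n_probes)) {
    for (i0 in starts) {
      i1 <- min(i0 + nb - 1L, n)
      m <- i1 - i0 + 1L
      zmid <- mean(depth[i0:i1])
      eps <- config$epsilon_truth(zmid, station)
      if (!is.finite(eps) || eps <= 0) {
        stop(sprintf("epsilon_truth non-positive at depth %.1f m", zmid),
          call. = FALSE
        )
      }
      nub <- if (is.null(nu)) seawater_viscosity(theta_truth(config, zmid)) else nu
      shear[i0:i1, p] <- .shear_block(m, eps, nub, config$fall_speed, fs)
    }
  }
  shear_record(time, shear, depth, theta,
    fall_speed = config$fall_speed, sample_rate = fs,
    station = paste0("L", station), cast = as.integer(cast)
  )
}

#' Generate a synthetic hydrographic profile
#'
#' Potential density is uniform above the mixed layer and follows the
#' prescribed N^2 below; overturn segments are local permutations of the
#' stable profile (the sorted multiset is preserved exactly, so Thorpe
#' resorting recovers the stable profile). Fluorescence is the true
#' chlorophyll pushed backwards through the calibration chain plus noise.
#'
#' @param config a [synthetic_config()].
#' @param station station index.
#' @param noise_free if `TRUE`, omit all additive noise.
#' @return A `hydro_profile` data.frame: `depth`, `theta`, `sigma_theta`,
#'   `fluorescence`, with the [truth_record()] attached as attribute
#'   `"truth"` and the station label as `"station"`.
#' @export
generate_hydro_profile <- function(config, station, noise_free = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  tr <- truth_record(config, station)
  depth <- tr$depth
  set.seed(.sub_seed(config, station, "hydro"))
  sigma <- tr$sigma_stable
  for (ov in config$overturn_spec) {
    if (!is.null(ov$station) && ov$station != station) next
    idx <- which(depth >= ov$center - ov$extent / 2 &
      depth <= ov$center + ov$extent / 2)
    if (length(idx) > 1) sigma[idx] <- sigma[sample(idx)]
  }
  flu_sbe <- (tr$chl - stage2_coef(config$calibration)["intercept"]) /
    stage2_coef(config$calibration)["slope"]
  flu_tm <- (flu_sbe - stage1_coef(config$calibration)["intercept"]) /
    stage1_coef(config$calibration)["slope"]
  if (config$quench) flu_tm[depth < 50] <- flu_tm[depth < 50] * 0.6
  ns <- config$noise_sd
  if (!noise_free) {
    sigma <- sigma + stats::rnorm(length(depth), 0, ns$sigma)
    theta <- tr$theta + stats::rnorm(length(depth), 0, ns$theta)
    flu_tm <- flu_tm + stats::rnorm(length(depth), 0, ns$flu)
  } else {
    theta <- tr$theta
  }
  out <- data.frame(
    depth = depth, theta = theta, sigma_theta = sigma,
    fluorescence = pmax(flu_tm, 0)
  )
  attr(out, "truth") <- tr
  attr(out, "station") <- paste0("L", station)
  class(out) <- c("hydro_profile", "data.frame")
  out
}

#' Generate synthetic bottle samples
#'
#' Discrete-depth nutrients from the configured linear theta relations plus
#' Gaussian noise (clipped at zero), and chlorophyll from the true profile.
#'
#' @param config a [synthetic_config()].
#' @param station station index.
#' @param hydro optional [generate_hydro_profile()] output; regenerated if
#'   missing (theta is matched at the bottle depths).
#' @param noise_free if `TRUE`, omit noise.
#' @return A `bottle_set` data.frame: `station`, `depth`, `theta`,
#'   `nitrate`, `phosphate`, `chl`.
#' @export
generate_bottles <- function(config, station, hydro = NULL,
                             noise_free = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(hydro)) hydro <- generate_hydro_profile(config, station)
  tr <- attr(hydro, "truth")
  depths <- config$bottle_depths
  depths <- depths[depths <= config$depth_max]
  theta <- theta_truth(config, depths)
  set.seed(.sub_seed(config, station, "bottle"))
  ns <- config$noise_sd
  mk <- function(species) {
    co <- config$nutrient_coef[[species]]
    v <- co[["slope"]] * theta + co[["intercept"]]
    if (!noise_free) v <- v + stats::rnorm(length(v), 0, ns[[species]])
    pmax(v, 0)
  }
  chl <- config$chl_truth(depths)
  if (!noise_free) chl <- pmax(chl + stats::rnorm(length(chl), 0, ns$chl), 0)
  out <- data.frame(
    station = paste0("L", station), depth = depths, theta = theta,
    nitrate = mk("nitrate"), phosphate = mk("phosphate"), chl = chl
  )
  class(out) <- c("bottle_set", "data.frame")
  out
}
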