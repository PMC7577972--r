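# Microstructure shear processing: segmentation, wavenumber spectra via the
# frozen-field hypothesis, and iterative Nasmyth-referenced integration of
# the shear variance to obtain the TKE dissipation rate
# epsilon = 7.5 nu <(du'/dz)^2>.

#' Construct a microstructure shear record
#'
#' Container for a free-fall profiler cast: one or two shear-probe series
#' sampled at a fixed rate, with the depth and temperature tracks needed to
#' attach a viscosity to each depth.
#'
#' @param time sample times, s, strictly increasing.
#' @param shear numeric vector or matrix (one column per probe), s^-1.
#' @param depth depth track, m positive down, monotonically increasing.
#' @param temperature temperature track, degrees C (for viscosity).
#' @param fall_speed nominal fall speed, m s^-1 (> 0).
#' @param sample_rate sampling rate, Hz (> 0).
#' @param station optional station label.
#' @param cast optional cast number.
#' @return An object of class `shear_record`.
#' @export
shear_record <- function(time, shear, depth, temperature,
                         fall_speed = 0.6, sample_rate = 512,
                         station = NA_character_, cast = NA_integer_) {
  shear <- as.matrix(shear)
  n <- length(time)
  stopifnot(nrow(shear) == n, length(depth) == n, length(temperature) == n)
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be > 0", call. = FALSE)
  }
  if (!is.finite(fall_speed) || fall_speed <= 0) {
    stop("`fall_speed` must be > 0", call. = FALSE)
  }
  if (any(diff(depth) < 0)) {
    stop("depth track must be monotonically increasing", call. = FALSE)
  }
  structure(
    list(
      time = as.numeric(time), shear = shear, depth = as.numeric(depth),
      temperature = as.numeric(temperature), fall_speed = fall_speed,
      sample_rate = sample_rate, station = station, cast = cast
    ),
    class = "shear_record"
  )
}

#' @export
print.shear_record <- function(x, ...) {
  cat(sprintf(
    "<shear_record> %s cast %s: %d samples, %d probe(s), %.0f Hz, W = %.2f m/s, %.1f-%.1f m\n",
    x$station, x$cast, length(x$time), ncol(x$shear), x$sample_rate,
    x$fall_speed, min(x$depth), max(x$depth)
  ))
  invisible(x)
}

#' Split a shear record into stationarity segments
#'
#' Half-overlapping (by default) segments, each linearly detrended and tagged
#' with its mean depth and the temperature-derived viscosity at that depth.
#' Tapering is applied later, at spectrum estimation.
#'
#' @param record a [shear_record()].
#' @param segment_seconds segment length, s; must give >= 256 samples.
#' @param overlap_fraction overlap between consecutive segments in \[0, 1).
#' @param nu optional constant kinematic viscosity, m^2 s^-1; by default
#'   computed from the segment-mean temperature with [seawater_viscosity()].
#' @return List of `shear_segment` objects with elements `shear` (detrended
#'   matrix), `depth` (segment mean), `depth_span`, `nu`, `fall_speed`,
#'   `sample_rate`.
#' @export
segment_shear <- function(record, segment_seconds = 4, overlap_fraction = 0.5,
                          nu = NULL) {
  stopifnot(inherits(record, "shear_record"))
  n_seg <- round(segment_seconds * record$sample_rate)
  if (n_seg < 256) {
    stop("segment must contain at least 256 samples", call. = FALSE)
  }
  n <- length(record$time)
  if (n < n_seg) {
    stop(sprintf(
      "record (%d samples) shorter than one segment (%d samples)", n, n_seg
    ), call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  step <- max(1L, round(n_seg * (1 - overlap_fraction)))
  starts <- seq(1L, n - n_seg + 1L, by = step)
  lapply(starts, function(i0) {
    idx <- i0:(i0 + n_seg - 1L)
    sh <- record$shear[idx, , drop = FALSE]
    sh <- apply(sh, 2, .detrend_linear)
    tbar <- mean(record$temperature[idx])
    structure(
      list(
        shear = sh,
        depth = mean(record$depth[idx]),
        depth_span = range(record$depth[idx]),
        nu = if (is.null(nu)) seawater_viscosity(tbar) else nu,
        temperature = tbar,
        fall_speed = record$fall_speed,
        sample_rate = record$sample_rate,
        index = idx
      ),
      class = "shear_segment"
    )
  })
}

.detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

#' One-sided shear wavenumber spectrum of a segment
#'
#' Periodogram of the detrended, tapered segment, converted from frequency to
#' wavenumber through Taylor's frozen-field hypothesis: `k = f / W_fall`,
#' `Phi(k) = Phi(f) * W_fall`. The taper power is corrected so that the
#' integral of the spectrum equals the taper-corrected time-domain shear
#' variance exactly (Parseval).
#'
#' @param segment a `shear_segment` from [segment_shear()], or a raw numeric
#'   vector (then `fall_speed`, `sample_rate`, `nu` must be supplied).
#' @param probe probe column to use (default 1).
#' @param window `"hann"` (default) or `"boxcar"`.
#' @param fall_speed,sample_rate,nu overrides / values for raw-vector input.
#' @return A `shear_spectrum`: list with `k` (cpm), `phi` (s^-2 cpm^-1),
#'   `variance` (taper-corrected time-domain variance, s^-2), `nu`, `depth`,
#'   `depth_span`, `fall_speed`.
#' @export
shear_spectrum <- function(segment, probe = 1, window = c("hann", "boxcar"),
                           fall_speed = NULL, sample_rate = NULL, nu = NULL) {
  window <- match.arg(window)
  if (is.numeric(segment)) {
    if (is.null(fall_speed) || is.null(sample_rate)) {
      stop("raw-vector input needs `fall_speed` and `sample_rate`", call. = FALSE)
    }
    x <- .detrend_linear(as.numeric(segment))
    depth <- NA_real_
    depth_span <- c(NA_real_, NA_real_)
    if (is.null(nu)) nu <- NA_real_
  } else {
    stopifnot(inherits(segment, "shear_segment"))
    x <- segment$shear[, probe]
    fall_speed <- segment$fall_speed
    sample_rate <- segment$sample_rate
    if (is.null(nu)) nu <- segment$nu
    depth <- segment$depth
    depth_span <- segment$depth_span
  }
  if (!is.finite(fall_speed) || fall_speed <= 0) {
    stop("fall speed must be > 0", call. = FALSE)
  }
  n <- length(x)
  w <- if (window == "hann") as.numeric(signal::hanning(n)) else rep(1, n)
  wpow <- mean(w^2)
  xw <- x * w
  xw <- xw - mean(xw) # tapering reintroduces a DC offset; remove it
  X <- stats::fft(xw)
  half <- floor(n / 2)
  # one-sided PSD in frequency, taper-power corrected
  psd_f <- 2 * Mod(X[2:(half + 1)])^2 / (sample_rate * n * wpow)
  if (n %% 2 == 0) psd_f[half] <- psd_f[half] / 2 # Nyquist bin not doubled
  f <- (1:half) * sample_rate / n
  structure(
    list(
      k = f / fall_speed,
      phi = psd_f * fall_speed,
      variance = mean(xw^2) / wpow,
      nu = nu,
      depth = depth,
      depth_span = depth_span,
      fall_speed = fall_speed,
      sample_rate = sample_rate,
      window = window
    ),
    class = "shear_spectrum"
  )
}

#' Dissipation rate from a shear spectrum by iterative Nasmyth integration
#'
#' Integrates the observed spectrum over a band, converts the shear variance
#' to a provisional `epsilon = 7.5 nu * variance`, recomputes the band's
#' upper cutoff from the Kolmogorov wavenumber of the current estimate, adds
#' back the unresolved fraction of model variance, and repeats to
#' convergence. A deterministic spectral-consistency check (mean absolute
#' log10 ratio of observed to model spectrum over the fit band) stands in for
#' manual inspection of each spectrum.
#'
#' @param spectrum a `shear_spectrum` with viscosity attached.
#' @param k_min lower integration limit, cpm.
#' @param resolved_fraction target fraction of model variance to resolve
#'   before correcting for the rest (cutoff wavenumber = this quantile of the
#'   Nasmyth variance distribution).
#' @param k_max_fraction upper usable fraction of the spectral band
#'   (anti-aliasing guard): cutoff never exceeds `k_max_fraction * max(k)`.
#' @param qc_threshold reject the estimate when the mean
#'   `|log10(phi_obs / phi_model)|` over the fit band exceeds this
#'   (default `log10(3)`).
#' @param tol relative convergence tolerance on epsilon.
#' @param max_iter maximum iterations; non-convergence flags rejection.
#' @return List: `epsilon` (W kg^-1), `qc` (`"accepted"` / `"rejected"`),
#'   `qc_reason`, `misfit`, `iterations`, `k_cutoff`, `resolved`.
#' @export
estimate_epsilon <- function(spectrum, k_min = 1, resolved_fraction = 0.9,
                             k_max_fraction = 0.8, qc_threshold = log10(3),
                             tol = 0.01, max_iter = 25) {
  stopifnot(inherits(spectrum, "shear_spectrum"))
  nu <- spectrum$nu
  if (!is.finite(nu) || nu <= 0) {
    stop("spectrum must carry a valid viscosity `nu`", call. = FALSE)
  }
  k <- spectrum$k
  phi <- spectrum$phi
  k_max <- k_max_fraction * max(k)
  band0 <- which(k >= k_min & k <= k_max)
  if (length(band0) < 3) {
    return(list(
      epsilon = NA_real_, qc = "rejected", qc_reason = "band-too-narrow",
      misfit = NA_real_, iterations = 0L, k_cutoff = NA_real_,
      resolved = NA_real_
    ))
  }
  # first guess: everything in the usable band, no resolution correction
  eps <- 7.5 * nu * pracma::trapz(k[band0], phi[band0])
  eps <- max(eps, 1e-13)
  converged <- FALSE
  it <- 0L
  k_cut <- k_max
  frac <- 1
  x_q <- .nasmyth_quantile(resolved_fraction)
  for (it in seq_len(max_iter)) {
    ks <- kolmogorov_wavenumber(eps, nu)
    k_cut <- min(x_q * ks, k_max)
    band <- which(k >= k_min & k <= k_cut)
    if (length(band) < 3) band <- band0[1:3]
    var_obs <- pracma::trapz(k[band], phi[band])
    frac <- nasmyth_variance_fraction(k[band[1]], k[band[length(band)]], eps, nu)
    frac <- max(frac, 0.05)
    eps_new <- max(7.5 * nu * var_obs / frac, 1e-13)
    if (abs(eps_new - eps) / eps < tol) {
      eps <- eps_new
      converged <- TRUE
      break
    }
    eps <- eps_new
  }
  band <- which(k >= k_min & k <= k_cut)
  if (length(band) < 3) band <- band0[1:3]
  phi_model <- nasmyth_spectrum(k[band], eps, nu)
  misfit <- mean(abs(log10(pmax(phi[band], 1e-30) / phi_model)))
  qc <- "accepted"
  reason <- "ok"
  if (!converged) {
    qc <- "rejected"
    reason <- "non-convergence"
  } else if (!is.finite(misfit) || misfit >= qc_threshold) {
    qc <- "rejected"
    reason <- "spectral-misfit"
  }
  list(
    epsilon = eps, qc = qc, qc_reason = reason, misfit = misfit,
    iterations = it, k_cutoff = k_cut, resolved = frac
  )
}

#' Depth-binned dissipation profile from a shear record
#'
#' Runs segmentation, per-segment spectra and [estimate_epsilon()] for each
#' probe, bins accepted per-segment estimates into depth bins, and combines
#' probes: accepted per-probe bin means are averaged unless they disagree by
#' more than `probe_ratio_max`, in which case the smaller is kept (probe
#' contamination guard).
#'
#' @param record a [shear_record()].
#' @param bin_width depth bin width, m.
#' @param segment_seconds,overlap_fraction passed to [segment_shear()].
#' @param nu optional constant viscosity override.
#' @param probe_ratio_max probe-disagreement ratio above which the smaller
#'   per-probe estimate is kept instead of the mean.
#' @param ... further arguments to [estimate_epsilon()].
#' @return A `dissipation_profile` data.frame: `depth` (bin centre, m),
#'   `epsilon` (W kg^-1, NA where every segment was rejected), `nu`,
#'   `n_accepted`, `n_segments`, `flag`, plus per-probe columns.
#' @export
dissipation_profile <- function(record, bin_width = 5, segment_seconds = 4,
                                overlap_fraction = 0.5, nu = NULL,
                                probe_ratio_max = 10, ...) {
  segs <- segment_shear(record, segment_seconds, overlap_fraction, nu = nu)
  n_probe <- ncol(record$shear)
  est <- lapply(segs, function(sg) {
    per <- lapply(seq_len(n_probe), function(p) {
      estimate_epsilon(shear_spectrum(sg, probe = p), ...)
    })
    data.frame(
      depth = sg$depth,
      probe = seq_len(n_probe),
      epsilon = vapply(per, `[[`, numeric(1), "epsilon"),
      accepted = vapply(per, `[[`, character(1), "qc") == "accepted",
      nu = sg$nu
    )
  })
  est <- do.call(rbind, est)
  breaks <- seq(
    floor(min(record$depth) / bin_width) * bin_width,
    ceiling(max(record$depth) / bin_width) * bin_width,
    by = bin_width
  )
  est$bin <- cut(est$depth, breaks, include.lowest = TRUE)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(depth = centres)
  per_probe <- matrix(NA_real_, nrow = length(centres), ncol = n_probe)
  for (p in seq_len(n_probe)) {
    ok <- est[est$probe == p & est$accepted & is.finite(est$epsilon), ]
    if (nrow(ok)) {
      m <- tapply(ok$epsilon, factor(ok$bin, levels = levels(est$bin)), mean)
      per_probe[, p] <- as.numeric(m)
    }
  }
  eps <- apply(per_probe, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    if (length(v) >= 2 && max(v) / min(v) > probe_ratio_max) return(min(v))
    mean(v)
  })
  out$epsilon <- eps
  nsg <- tapply(rep(1, nrow(est)), factor(est$bin, levels = levels(est$bin)), sum)
  nac <- tapply(as.numeric(est$accepted), factor(est$bin, levels = levels(est$bin)), sum)
  out$n_segments <- as.integer(ifelse(is.na(nsg), 0, nsg))
  out$n_accepted <- as.integer(ifelse(is.na(nac), 0, nac))
  munu <- tapply(est$nu, factor(est$bin, levels = levels(est$bin)), mean)
  out$nu <- as.numeric(munu)
  out$flag <- ifelse(is.finite(out$epsilon), "accepted",
    ifelse(out$n_segments > 0, "rejected", "no-data")
  )
  colnames(per_probe) <- paste0("epsilon_probe", seq_len(n_probe))
  out <- cbind(out, per_probe)
  out <- out[out$n_segments > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dissipation_profile", "data.frame")
  out
}

#' Combine dissipation profiles across casts
#'
#' Per-bin arithmetic mean over accepted estimates; bins where every member
#' profile is rejected or missing stay missing (never zero).
#'
#' @param profiles list of `dissipation_profile` data.frames on a common
#'   depth grid.
#' @return A combined `dissipation_profile` data.frame with columns `depth`,
#'   `epsilon`, `nu`, `n_casts`, `flag`.
#' @export
combine_dissipation <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  depths <- sort(unique(unlist(lapply(profiles, `[[`, "depth"))))
  for (p in profiles) {
    if (!all(p$depth %in% depths)) stop("disjoint depth grids", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(profiles, `[[`, "depth"))
  if (!length(common)) stop("profiles share no depth bins", call. = FALSE)
  depths <- sort(common)
  eps_mat <- sapply(profiles, function(p) p$epsilon[match(depths, p$depth)])
  nu_mat <- sapply(profiles, function(p) p$nu[match(depths, p$depth)])
  eps_mat <- matrix(eps_mat, nrow = length(depths))
  nu_mat <- matrix(nu_mat, nrow = length(depths))
  out <- data.frame(
    depth = depths,
    epsilon = apply(eps_mat, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }),
    nu = rowMeans(nu_mat, na.rm = TRUE),
    n_casts = apply(eps_mat, 1, function(v) sum(is.finite(v)))
  )
  out$flag <- ifelse(is.finite(out$epsilon), "accepted", "rejected")
  class(out) <- c("dissipation_profile", "data.frame")
  out
}
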