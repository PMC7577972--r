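# Shared fixtures, built in code.

# Config with spatially constant dissipation (and otherwise small defaults),
# for recovery tests against a known epsilon.
const_eps_config <- function(seed, eps, ...) {
  synthetic_config(seed,
    epsilon_truth = function(depth, station) rep(eps, length(depth)), ...
  )
}

# A white-noise shear record of given duration (no physical spectrum; used
# for segmentation / bookkeeping tests).
noise_record <- function(duration_s = 60, sd = 1e-2, fs = 512, w = 0.6,
                         seed = 42) {
  set.seed(seed)
  n <- duration_s * fs
  t <- (seq_len(n) - 1) / fs
  shear_record(t, stats::rnorm(n, 0, sd), t * w, rep(15, n),
    fall_speed = w, sample_rate = fs
  )
}

# Synthetic shear_spectrum carrying an exact model shape (no time series).
model_spectrum <- function(eps, nu, k = seq(0.5, 300, by = 0.5), phi = NULL) {
  structure(
    list(
      k = k, phi = if (is.null(phi)) nasmyth_spectrum(k, eps, nu) else phi,
      variance = NA_real_, nu = nu, depth = NA_real_,
      depth_span = c(NA_real_, NA_real_), fall_speed = 0.6, sample_rate = 512,
      window = "none"
    ),
    class = "shear_spectrum"
  )
}

# Minimal dissipation_profile data.frame on a given grid.
diss_df <- function(depth, epsilon, nu = 1.2e-6) {
  out <- data.frame(
    depth = depth, epsilon = epsilon, nu = nu,
    n_segments = 1L, n_accepted = as.integer(is.finite(epsilon)),
    flag = ifelse(is.finite(epsilon), "accepted", "rejected")
  )
  class(out) <- c("dissipation_profile", "data.frame")
  out
}
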