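test_that("segmentation count, precondition, and sample coverage", {
  rec <- noise_record(60)
  segs <- segment_shear(rec, segment_seconds = 4, overlap_fraction = 0.5)
  expect_length(segs, 29) # floor((60 - 4) / 2) + 1
  expect_error(segment_shear(noise_record(3), 4), "shorter")
  covered <- sort(unique(unlist(lapply(segs, `[[`, "index"))))
  expect_identical(covered, seq_along(rec$time))
})

test_that("spectrum of a sinusoid: peak wavenumber and Parseval", {
  fs <- 512
  w <- 0.6
  a <- 0.05
  f0 <- 32 # integer number of cycles in a 4-s segment
  t <- (0:(4 * fs - 1)) / fs
  x <- a * sin(2 * pi * f0 * t)
  sp <- shear_spectrum(x,
    window = "boxcar", fall_speed = w, sample_rate = fs,
    nu = 1.2e-6
  )
  expect_equal(sp$k[which.max(sp$phi)], f0 / w, tolerance = 1e-6)
  dk <- diff(sp$k[1:2])
  expect_lt(abs(sum(sp$phi) * dk / (a^2 / 2) - 1), 0.01)
  # doubling the fall speed halves the peak wavenumber
  sp2 <- shear_spectrum(x,
    window = "boxcar", fall_speed = 2 * w, sample_rate = fs, nu = 1.2e-6
  )
  expect_equal(sp2$k[which.max(sp2$phi)], f0 / (2 * w), tolerance = 1e-6)
  expect_error(shear_spectrum(x, window = "boxcar", fall_speed = 0, sample_rate = fs))
})

test_that("white-noise spectrum integrates to the sample variance", {
  set.seed(7)
  x <- stats::rnorm(2048, 0, 3e-3)
  sp <- shear_spectrum(x,
    window = "boxcar", fall_speed = 0.6, sample_rate = 512, nu = 1.2e-6
  )
  dk <- diff(sp$k[1:2])
  v_time <- mean((x - mean(x))^2)
  expect_lt(abs(sum(sp$phi) * dk / v_time - 1), 0.01)
})

test_that("Parseval holds on every segment of a generated record (tapered)", {
  rec <- generate_shear_record(const_eps_config(9, 1e-8), 1,
    duration_s = 30, n_probes = 1, nu = 1.2e-6
  )
  for (sg in segment_shear(rec, 4)) {
    sp <- shear_spectrum(sg)
    dk <- diff(sp$k[1:2])
    expect_lt(abs(sum(sp$phi) * dk / sp$variance - 1), 0.01)
  }
})

test_that("epsilon estimation recovers a noise-free model spectrum", {
  for (eps in c(1e-9, 1e-8, 1e-7)) {
    est <- estimate_epsilon(model_spectrum(eps, 1.2e-6))
    expect_identical(est$qc, "accepted")
    expect_lt(abs(est$epsilon / eps - 1), 0.05)
  }
})

test_that("spectra inconsistent with the model shape are rejected", {
  # a uniform scale factor is absorbed by the refit, so distort the shape:
  # an order-of-magnitude oscillation cannot be matched by any (epsilon, nu)
  k <- seq(0.5, 300, by = 0.5)
  distorted <- model_spectrum(1e-8, 1.2e-6,
    k = k,
    phi = nasmyth_spectrum(k, 1e-8, 1.2e-6) * 10^(1.5 * sin(2 * pi * log10(k)))
  )
  est <- estimate_epsilon(distorted)
  expect_identical(est$qc, "rejected")
  expect_identical(est$qc_reason, "spectral-misfit")
})

test_that("probe and cast combination follows the stated rules", {
  d <- c(2.5, 7.5, 12.5)
  a <- diss_df(d, c(1e-8, 1e-8, NA))
  b <- diss_df(d, c(4e-8, NA, NA))
  comb <- combine_dissipation(list(a, b))
  expect_equal(comb$epsilon, c(2.5e-8, 1e-8, NA_real_))
  expect_identical(comb$flag, c("accepted", "accepted", "rejected"))
  expect_equal(combine_dissipation(list(a, a))$epsilon, a$epsilon)
  expect_error(
    combine_dissipation(list(a, diss_df(c(100, 105, 110), rep(1e-8, 3)))),
    "depth"
  )
})

test_that("Thorpe resorting matches a naive sort oracle with zero-sum displacements", {
  depth <- seq(1, 100)
  # printed 3-point example
  st3 <- thorpe_resort(1:3, c(24.1, 24.0, 24.2))
  expect_equal(st3$sigma_sorted, c(24.0, 24.1, 24.2))
  # stable profile is a fixed point
  stable <- thorpe_resort(depth, 24 + 0.01 * depth)
  expect_true(all(stable$displacement == 0))
  # random permutations vs the independent full-sort oracle
  set.seed(31)
  for (i in 1:50) {
    sig <- 24 + cumsum(stats::rexp(100, 10)) / 10
    sig <- sig[sample(100)]
    st <- thorpe_resort(depth, sig)
    expect_identical(st$sigma_sorted, sort(sig))
    expect_identical(sort(st$sigma_obs), st$sigma_sorted)
    expect_equal(sum(st$displacement), 0)
    expect_true(all(diff(st$sigma_sorted) >= 0))
  }
  # missing values come back as gaps
  expect_warning(stm <- thorpe_resort(1:5, c(24.2, NA, 24.0, 24.1, 24.3)), "missing")
  expect_true(is.na(stm$sigma_sorted[2]))
  expect_equal(stm$sigma_sorted[c(1, 3:5)], c(24.0, 24.1, 24.2, 24.3))
})

test_that("buoyancy frequency from a linear resorted profile is uniform", {
  depth <- seq(0, 200)
  st <- data.frame(depth = depth, sigma_sorted = 24 + 0.01 * depth)
  n2 <- buoyancy_frequency(st, smoothing_scale = 10)
  expect_equal(n2$n2, rep(9.81 / 1027 * 0.01, length(depth)), tolerance = 1e-10)
  expect_true(all(n2$n2_flag == "ok"))
  # homogeneous layer floors and flags
  hom <- data.frame(depth = depth, sigma_sorted = rep(24, length(depth)))
  n2h <- buoyancy_frequency(hom, n2_floor = 1e-7)
  expect_true(all(n2h$n2 == 1e-7))
  expect_true(all(n2h$n2_flag == "floored"))
  expect_error(buoyancy_frequency(hom[1:2, ]), "3")
})

test_that("mixed-layer depth by the 0.03 kg m-3 criterion", {
  # uniform above 37 m, then +0.001 kg m-3 per m: crossing 30 m below
  depth <- seq(0, 100)
  sig <- ifelse(depth <= 37, 24, 24 + 0.001 * (depth - 37))
  expect_equal(as.numeric(mixed_layer_depth(depth, sig)), 67)
  # step profile at 40 m (fine grid: interpolated crossing sits at the step)
  d2 <- seq(0, 60, by = 0.001)
  s2 <- ifelse(d2 < 40, 24, 24.5)
  expect_equal(as.numeric(mixed_layer_depth(d2, s2)), 40, tolerance = 1e-4)
  # criterion never met: deepest depth, flagged
  m <- mixed_layer_depth(depth, rep(24, length(depth)))
  expect_equal(as.numeric(m), 100)
  expect_false(attr(m, "criterion_met"))
})

test_that("Osborn diffusivity arithmetic, masking, and monotonicity", {
  d <- c(10, 30, 50, 70)
  n2 <- data.frame(depth = d, n2 = c(2e-5, 2e-5, 1e-4, 1e-7),
                   n2_flag = c("ok", "ok", "ok", "floored"))
  diss <- diss_df(d, c(1e-7, 1e-7, 1e-8, 1e-8))
  kp <- osborn_diffusivity(diss, n2, mld = 20)
  expect_identical(kp$mask, c("mixed-layer", "ok", "ok", "n2-floor"))
  expect_true(is.na(kp$k_rho[1]))
  expect_equal(kp$k_rho[2], 1e-3) # 0.2 * 1e-7 / 2e-5
  expect_equal(kp$k_rho[3], 2e-5) # 0.2 * 1e-8 / 1e-4
  expect_true(is.na(kp$k_rho[4]))
  # at fixed N^2, K increases strictly with epsilon
  eps_grid <- 10^seq(-10, -6, by = 0.5)
  kk <- osborn_diffusivity(
    diss_df(seq_along(eps_grid) * 10 + 100, eps_grid),
    data.frame(
      depth = seq_along(eps_grid) * 10 + 100,
      n2 = rep(2e-5, length(eps_grid)), n2_flag = "ok"
    ),
    mld = 20
  )$k_rho
  expect_true(all(diff(kk) > 0))
})

test_that("dissipation profile recovers constant truth from a full record", {
  rec <- generate_shear_record(const_eps_config(13, 1e-8), 1,
    duration_s = 60, n_probes = 2, nu = 1.2e-6
  )
  dp <- dissipation_profile(rec, nu = 1.2e-6)
  expect_gt(sum(dp$flag == "accepted"), 0)
  med <- stats::median(dp$epsilon, na.rm = TRUE)
  expect_lt(abs(log10(med / 1e-8)), log10(2))
})
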