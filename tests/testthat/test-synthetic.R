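test_that("generated shear variance matches epsilon / (7.5 nu) over many seeds", {
  eps <- 1e-8
  nu <- 1.2e-6
  target <- eps / (7.5 * nu) # 1.111e-3 s^-2
  v <- vapply(1:50, function(s) {
    rec <- generate_shear_record(const_eps_config(s, eps), 1,
      duration_s = 60, n_probes = 1, nu = nu
    )
    stats::var(rec$shear[, 1])
  }, numeric(1))
  expect_lt(abs(mean(v) / target - 1), 0.10)
})

test_that("generation is deterministic in (seed, config) and rejects bad truth", {
  cfg <- const_eps_config(11, 1e-8, depth_max = 60)
  a <- generate_shear_record(cfg, 1, duration_s = 10, nu = 1.2e-6)
  b <- generate_shear_record(cfg, 1, duration_s = 10, nu = 1.2e-6)
  expect_identical(a, b)
  c2 <- generate_shear_record(cfg, 1, cast = 2, duration_s = 10, nu = 1.2e-6)
  expect_false(identical(a$shear, c2$shear))
  expect_identical(
    generate_bottles(cfg, 1),
    generate_bottles(cfg, 1)
  )
  expect_error(
    synthetic_config(1, epsilon_truth = function(z, s) rep(0, length(z))),
    "positive"
  )
  expect_error(
    synthetic_config(1, overturn_spec = list(list(center = 490, extent = 40))),
    "depth range"
  )
})

test_that("hydro profile realizes the prescribed stratification", {
  cfg <- synthetic_config(3, n2_truth = function(z) rep(1e-5, length(z)))
  hy <- generate_hydro_profile(cfg, 1, noise_free = TRUE)
  # no overturns: resorting is the identity
  st <- thorpe_resort(hy$depth, hy$sigma_theta)
  expect_equal(st$sigma_sorted, st$sigma_obs)
  expect_true(all(st$displacement == 0))
  # recovered N^2 within 15% of truth at mid-depth
  n2 <- buoyancy_frequency(st)
  mid <- n2$depth > 150 & n2$depth < 350
  expect_lt(max(abs(n2$n2[mid] / 1e-5 - 1)), 0.15)
})

test_that("injected overturns are confined, multiset-preserving permutations", {
  cfg <- synthetic_config(4,
    overturn_spec = list(list(station = 1, center = 150, extent = 20))
  )
  hy <- generate_hydro_profile(cfg, 1, noise_free = TRUE)
  st <- thorpe_resort(hy$depth, hy$sigma_theta)
  nz <- which(st$displacement != 0)
  expect_true(all(hy$depth[nz] >= 140 & hy$depth[nz] <= 160))
  expect_gt(length(nz), 0)
  # resorting recovers the stable original exactly
  truth <- attr(hy, "truth")
  expect_equal(st$sigma_sorted, truth$sigma_stable)
})

test_that("mixed-layer detector recovers the configured MLD on a sharp pycnocline", {
  cfg <- synthetic_config(5,
    mld_truth = 40,
    n2_truth = function(z) ifelse(z >= 40 & z <= 50, 1e-3, 2e-5)
  )
  hy <- generate_hydro_profile(cfg, 1, noise_free = TRUE)
  mld <- mixed_layer_depth(hy$depth, hy$sigma_theta)
  expect_lt(abs(mld - 40), 1 + 1e-9) # within one grid step
})

test_that("bottles realize the linear theta-nutrient relation", {
  cfg <- synthetic_config(6, theta_surface = 20, mld_truth = 40)
  b <- generate_bottles(cfg, 1, noise_free = TRUE)
  # theta = 20 C in the mixed layer with the pooled coefficients
  expect_equal(b$nitrate[b$depth == 0], -0.540 * 20 + 14.077) # 3.277
  expect_equal(b$phosphate[b$depth == 0], -0.032 * 20 + 0.819)
  # warm water with a low intercept drives the relation negative -> clipped
  cfg2 <- synthetic_config(6,
    theta_surface = 26,
    nutrient_coef = list(
      nitrate = c(slope = -0.540, intercept = 5),
      phosphate = c(slope = -0.032, intercept = 0.819)
    )
  )
  b2 <- generate_bottles(cfg2, 1, noise_free = TRUE)
  expect_equal(b2$nitrate[b2$depth == 0], 0)
})

test_that("refitting the regression to generated bottles recovers the slope", {
  depths <- seq(0, 400, by = 2)
  hits <- vapply(1:20, function(s) {
    cfg <- synthetic_config(s, bottle_depths = depths)
    b <- generate_bottles(cfg, 1)
    fit <- fit_linear(b$theta, b$nitrate)
    abs(fit$slope - (-0.540)) <= fit$slope_hw
  }, logical(1))
  expect_gte(mean(hits), 0.8) # nominal 95% coverage
})
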