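test_that("signal tensors have the 3 x 5 x 20 structure and are finite", {
  cfg <- generator_config()
  for (dis in c(TRUE, FALSE)) {
    p <- sample_params(3, diseased = dis, rng_seed = 11)
    zs <- generate_signals(p, cfg)
    expect_length(zs, 3L)
    for (z in zs) {
      expect_equal(dim(z), c(3L, 5L, 20L))
      expect_true(all(is.finite(z)))
      expect_equal(attr(z, "noise_std"), 0)
    }
  }
})

test_that("the noise-free generator is a deterministic function of (params, config)", {
  p <- sample_params(4, diseased = TRUE, rng_seed = 3)
  cfg <- generator_config()
  expect_identical(generate_signals(p, cfg), generate_signals(p, cfg))
  # and sensitive to the config constants
  cfg2 <- generator_config(base_amplitude = cfg$base_amplitude * 2)
  expect_false(identical(generate_signals(p, cfg), generate_signals(p, cfg2)))
})

test_that("zero effect scale makes diseased signals identical to matched healthy ones", {
  cfg0 <- generator_config(effect_scale = 0)
  pair <- matched_pair(0.42, 0.77, 0.9, 0.1)
  zh <- generate_signals(pair$healthy, cfg0)
  zd <- generate_signals(pair$diseased, cfg0)
  expect_identical(unclass(zh), unclass(zd))
})

test_that("the disease signature grows strictly with the false-lumen radius", {
  # property over several matched patients and angles, fixed seed
  withr::with_seed(99, {
    for (k in 1:8) {
      u <- runif(3)  # u_rtl, u_theta, u_alpha
      radii <- sort(runif(5))
      norms <- vapply(radii, function(ur) {
        disease_signature_norm(ur, u[1], u[2], u[3])
      }, double(1))
      expect_true(all(diff(norms) > 0))
    }
  })
  # endpoints of the published range
  expect_lt(disease_signature_norm(0), disease_signature_norm(1))
})

test_that("hematocrit increases and lumen radius quadratically scales the healthy pulse", {
  cfg <- generator_config()
  z_mid <- generate_signals(icgdx:::params_from_unit(0.5, 0.5, diseased = FALSE), cfg)
  z_hi_theta <- generate_signals(icgdx:::params_from_unit(0.5, 1, diseased = FALSE), cfg)
  expect_true(all(z_hi_theta >= z_mid))
  z_r0 <- generate_signals(icgdx:::params_from_unit(0, 0.5, diseased = FALSE), cfg)
  z_r1 <- generate_signals(icgdx:::params_from_unit(1, 0.5, diseased = FALSE), cfg)
  expect_equal(as.vector(z_r1) * (1.35 / 1.65)^2,
               as.vector(z_r0) * (1.95 / 1.65)^2, tolerance = 1e-12)
})

test_that("add_noise perturbs every point independently with the requested std", {
  p <- sample_params(1, diseased = FALSE, rng_seed = 2)
  z <- generate_signals(p, generator_config())
  # degenerate std
  expect_identical(unclass(add_noise(z, 0)), unclass(z))
  # determinism
  expect_identical(add_noise(z, 0.5, rng_seed = 9), add_noise(z, 0.5, rng_seed = 9))
  expect_false(identical(add_noise(z, 0.5, rng_seed = 9),
                         add_noise(z, 0.5, rng_seed = 10)))
  expect_equal(attr(add_noise(z, 0.5, rng_seed = 9), "noise_std"), 0.5)
  expect_error(add_noise(z, -0.1), ">= 0")
  # Monte-Carlo: pooled empirical std over 10,000 signal sets within 1% of 0.5
  devs <- unlist(lapply(1:10000, function(k) {
    as.vector(add_noise(z, 0.5, rng_seed = k) - z)
  }))
  expect_lt(abs(sd(devs) - 0.5) / 0.5, 0.01)
  expect_lt(abs(mean(devs)), 0.005)
})
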