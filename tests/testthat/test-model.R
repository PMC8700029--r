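test_that("the default architecture has exactly 5354 trainable parameters", {
  spec <- model_spec()
  expect_identical(count_parameters(spec), 5354L)
  # one branch's conv layer: (kernel * channels + 1) * filters
  expect_identical((3L * 5L + 1L) * 9L, 144L)
  # census of an actually built model agrees with the closed form
  expect_identical(icgdx:::n_trainable(build_model(spec, 1)), 5354)
})

test_that("closed-form parameter count equals the built-model census for random specs", {
  withr::with_seed(7, {
    for (k in 1:50) {
      spec <- model_spec(
        n_injectors = sample(1:4, 1), n_sensors = sample(1:6, 1),
        n_timesteps = sample(8:24, 1), conv_filters = sample(1:12, 1),
        kernel_size = sample(2:4, 1), pool_size = sample(2:3, 1),
        dense_hidden = sample(1:30, 1), n_classes = sample(2:4, 1),
        dropout_rate = runif(1, 0, 0.5))
      expect_equal(icgdx:::n_trainable(build_model(spec, k)),
                   count_parameters(spec))
    }
  })
})

test_that("hidden width 1 gives the closed-form 680 with default layer shapes", {
  expect_identical(count_parameters(model_spec(dense_hidden = 1L)), 680L)
  expect_error(model_spec(dense_hidden = 0L), "integer >= 1")
})

test_that("per-branch flattened length is 81 and the concatenated vector 243", {
  d <- icgdx:::spec_dims(model_spec())
  expect_identical(d$conv_len, 18L)   # 20 - 3 + 1, valid padding
  expect_identical(d$pool_len, 9L)
  expect_identical(d$branch_flat, 81L)
  expect_identical(d$concat, 243L)
})

test_that("invariant-violating specs are rejected before allocation", {
  expect_error(model_spec(n_timesteps = 3L, kernel_size = 3L, pool_size = 2L),
               "pool_size")
  expect_error(model_spec(dropout_rate = 1), "dropout_rate")
  expect_error(model_spec(stride = 2L), "stride")
  expect_error(model_spec(conv_filters = 0L), "integer >= 1")
})

test_that("a built model maps a 3 x 5 x 20 input to a 2-class probability vector", {
  m <- build_model(model_spec(), init_seed = 3)
  p <- sample_params(1, diseased = TRUE, rng_seed = 1)
  z <- generate_signals(p, generator_config())
  pr <- predict(m, z)
  expect_equal(dim(pr), c(1L, 2L))
  expect_true(all(pr > 0))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("initialisation is deterministic in the seed", {
  a <- build_model(model_spec(), init_seed = 11)
  b <- build_model(model_spec(), init_seed = 11)
  expect_identical(a$params, b$params)
  c <- build_model(model_spec(), init_seed = 12)
  expect_false(identical(a$params, c$params))
})

test_that("model checkpoints round-trip through the portable JSON format", {
  m <- build_model(tiny_spec(), init_seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$spec, m$spec)
  expect_equal(back$params, m$params, tolerance = 1e-15)
  # a truncated checkpoint is rejected with a parameter-count diagnostic
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- x$weights[-1]
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_model(path), "inconsistent")
})
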