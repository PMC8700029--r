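test_that("the patience rule stops exactly when the monitored loss stalls", {
  # improvement at epoch 2, then three consecutive non-improvements
  expect_identical(icgdx:::early_stop_epoch(c(1.0, 0.9, 0.91, 0.92, 0.93), 3L),
                   5L)
  expect_identical(icgdx:::early_stop_epoch(c(1.0, 0.9, 0.8, 0.7), 3L),
                   NA_integer_)
  expect_identical(icgdx:::early_stop_epoch(c(1.0, 1.0, 1.0, 1.0), 3L), 4L)
  # never more than best_epoch + patience epochs
  losses <- c(0.5, 0.6, 0.4, 0.41, 0.42, 0.43, 0.3)
  expect_identical(icgdx:::early_stop_epoch(losses, 3L), 6L)
})

test_that("a separable toy cohort is fit to perfect training accuracy", {
  coh <- separable_cohort(20, seed = 1)
  monitor <- separable_cohort(10, seed = 2, split = "validation")
  m <- build_model(model_spec(), init_seed = 1)
  fit <- train(m, coh, monitor,
               train_config(max_epochs = 50, early_stopping_patience = 50,
                            train_seed = 1))
  expect_gte(max(fit$history$train_acc), 1.0)
  expect_s3_class(fit$model, "icg_model")
  expect_true(fit$model$trained)
})

test_that("training is bit-reproducible for identical data, config and seeds", {
  coh <- separable_cohort(10, seed = 3)
  monitor <- separable_cohort(5, seed = 4, split = "validation")
  cfg <- train_config(max_epochs = 5, early_stopping_patience = 0,
                      train_seed = 77)
  f1 <- train(build_model(model_spec(), 9), coh, monitor, cfg)
  f2 <- train(build_model(model_spec(), 9), coh, monitor, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- train(build_model(model_spec(), 9), coh, monitor,
              train_config(max_epochs = 5, early_stopping_patience = 0,
                           train_seed = 78))
  expect_false(identical(f1$model$params, f3$model$params))
})

test_that("history bookkeeping matches the stopping epoch and reason", {
  coh <- separable_cohort(10, seed = 5)
  monitor <- separable_cohort(5, seed = 6, split = "validation")
  fit <- train(build_model(model_spec(), 2), coh, monitor,
               train_config(max_epochs = 4, early_stopping_patience = 0,
                            train_seed = 1))
  expect_identical(fit$stop_reason, "max_epochs")
  expect_identical(nrow(fit$history), fit$stopped_epoch)
  expect_identical(fit$history$epoch, seq_len(fit$stopped_epoch))
  g <- glance(fit)
  expect_identical(g$n_parameters, 5354L)
  expect_identical(tidy(fit), tibble::as_tibble(fit$history))
})

test_that("one epoch of SGD reduces the training loss for most seeds", {
  # small separable cohorts; final loss below initial in >= 95% of 20 runs
  wins <- 0L
  for (s in 1:20) {
    coh <- separable_cohort(10, seed = s)
    monitor <- separable_cohort(4, seed = 1000 + s, split = "validation")
    m <- build_model(model_spec(), init_seed = s)
    X <- icgdx:::cohort_tensor(coh)
    init <- icgdx:::nn_eval(m$params, m$spec, X, coh$label)$loss
    fit <- train(m, coh, monitor,
                 train_config(max_epochs = 3, early_stopping_patience = 0,
                              restore_best_weights = FALSE, train_seed = s))
    final <- fit$history$train_loss[nrow(fit$history)]
    if (final < init) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("shape mismatches are rejected before training starts", {
  coh <- separable_cohort(5, seed = 1)
  monitor <- separable_cohort(3, seed = 2)
  m_small <- build_model(tiny_spec(), 1)
  expect_error(train(m_small, coh, monitor, train_config(max_epochs = 1)),
               "expects 2 x 2 x 6")
  expect_error(train(build_model(model_spec(), 1), coh[0, ], monitor,
                     train_config(max_epochs = 1)), "non-empty")
})

test_that("predictions are normalised, order-preserving and shape-checked", {
  coh <- separable_cohort(6, seed = 8)
  m <- build_model(model_spec(), init_seed = 4)
  pr <- predict(m, coh)
  expect_equal(dim(pr), c(12L, 2L))
  expect_equal(rowSums(pr), rep(1, 12), tolerance = 1e-6)
  # batch predictions equal per-record predictions, in order
  single <- t(vapply(coh$signal, function(z) predict(m, z)[1, ], double(2)))
  expect_equal(unname(pr), unname(single), tolerance = 1e-12)
  cls <- predict(m, coh, type = "class")
  expect_identical(cls, icgdx:::predicted_class(pr))
  expect_error(predict(m, array(0, c(2, 2, 6))), "expects 3 x 5 x 20")
})

test_that("an exact probability tie is classified as healthy", {
  expect_identical(icgdx:::predicted_class(matrix(c(0.5, 0.5), 1)), 0L)
  expect_identical(icgdx:::predicted_class(rbind(c(0.4, 0.6), c(0.7, 0.3))),
                   c(1L, 0L))
})
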