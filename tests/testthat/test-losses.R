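test_that("softmax matches closed-form values", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(7, 7, 7)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
})

test_that("softmax is normalised, positive and shift-invariant on random vectors", {
  withr::with_seed(12, {
    for (k in 1:1000) {
      v <- rnorm(sample(2:6, 1), sd = 10)
      p <- softmax(v)
      expect_true(all(p > 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(softmax(v + rnorm(1, sd = 50)), p, tolerance = 1e-9)
    }
  })
})

test_that("categorical cross-entropy matches its defining sum", {
  # uniform 2-class prediction on one example
  expect_equal(categorical_cross_entropy(0L, c(0.5, 0.5)), log(2))
  # perfect one-hot prediction
  expect_identical(categorical_cross_entropy(1L, c(0, 1)), 0)
  # sum over examples
  pred <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(categorical_cross_entropy(c(0L, 0L), pred),
               log(2) - log(0.9))
  expect_equal(categorical_cross_entropy(c(0L, 0L), pred, reduction = "mean"),
               (log(2) - log(0.9)) / 2)
})

test_that("cross-entropy is non-negative and zero iff one-hot-correct", {
  withr::with_seed(5, {
    for (k in 1:50) {
      m <- sample(1:8, 1); kcl <- sample(2:4, 1)
      pred <- matrix(runif(m * kcl), m, kcl)
      pred <- pred / rowSums(pred)
      y <- sample(0:(kcl - 1), m, replace = TRUE)
      loss <- categorical_cross_entropy(y, pred)
      expect_gte(loss, 0)
      expect_gt(loss, 0)  # random predictions are never exactly one-hot
      onehot <- matrix(0, m, kcl); onehot[cbind(1:m, y + 1)] <- 1
      expect_identical(categorical_cross_entropy(y, onehot), 0)
    }
  })
})

test_that("sparse and one-hot categorical cross-entropy are identical", {
  withr::with_seed(21, {
    for (k in 1:20) {
      m <- sample(2:30, 1); kcl <- sample(2:5, 1)
      pred <- matrix(runif(m * kcl), m, kcl); pred <- pred / rowSums(pred)
      y <- sample(0:(kcl - 1), m, replace = TRUE)
      onehot <- matrix(0, m, kcl); onehot[cbind(1:m, y + 1)] <- 1
      expect_equal(categorical_cross_entropy(y, pred),
                   categorical_cross_entropy(onehot, pred),
                   tolerance = 1e-15)
    }
  })
})

test_that("binary cross-entropy matches closed forms and the 2-class categorical loss", {
  expect_identical(binary_cross_entropy(1, 1), 0)
  expect_equal(binary_cross_entropy(1, 0.5), log(2))
  withr::with_seed(31, {
    m <- 40
    p1 <- runif(m, 0.01, 0.99)
    y <- sample(0:1, m, replace = TRUE)
    expect_equal(binary_cross_entropy(y, p1),
                 categorical_cross_entropy(y, cbind(1 - p1, p1)),
                 tolerance = 1e-12)
  })
})

test_that("a zero predicted probability at the true class is clipped, not fatal", {
  loss <- categorical_cross_entropy(0L, c(0, 1))
  expect_true(is.finite(loss))
  expect_equal(loss, -log(1e-12))
  expect_true(is.finite(binary_cross_entropy(1, 0)))
})
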