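#' Training hyperparameters
#'
#' The published recipe: plain stochastic gradient descent with Nesterov
#' momentum at a constant learning rate of 0.09, mini-batches of 34, sparse
#' categorical cross-entropy loss, and early stopping once the monitored
#' loss has failed to improve for 3 consecutive epochs. The momentum
#' coefficient is not published; 0.9, the framework-conventional value, is
#' the default and is exposed here. `max_epochs` is a safety ceiling — the
#' stopping rule normally fires first.
#'
#' @param learning_rate Constant SGD learning rate (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param early_stopping_patience Consecutive non-improving epochs tolerated
#'   before stopping (>= 0).
#' @param max_epochs Hard epoch ceiling.
#' @param restore_best_weights Return the weights of the best monitored
#'   epoch instead of the last one. On by default: with a constant learning
#'   rate of 0.09 the loss oscillates between epochs, and the patience rule
#'   can otherwise halt on (and return) an oscillation dip. Set to `FALSE`
#'   for the published callback's behaviour of keeping the last weights.
#' @param train_seed Integer seed driving shuffling and dropout.
#' @return A list of class `icg_train_config`.
#' @export
train_config <- function(learning_rate = 0.09, batch_size = 34L,
                         momentum = 0.9, early_stopping_patience = 3L,
                         max_epochs = 200L, restore_best_weights = TRUE,
                         train_seed = 1L) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(momentum, "momentum", lower = 0)
  if (momentum >= 1) abort("`momentum` must be in [0, 1).")
  structure(
    list(learning_rate = as.double(learning_rate),
         batch_size = assert_count(batch_size, "batch_size"),
         momentum = as.double(momentum),
         early_stopping_patience = assert_count(early_stopping_patience,
                                                "early_stopping_patience",
                                                min = 0L),
         max_epochs = assert_count(max_epochs, "max_epochs"),
         restore_best_weights = isTRUE(restore_best_weights),
         train_seed = as.integer(train_seed)),
    class = "icg_train_config"
  )
}

# Early-stopping bookkeeping: given the monitored losses so far, the epoch
# after which training stops (NA if it never fires). Improvement means a
# strictly smaller loss than the best so far; `patience` consecutive
# non-improving epochs trigger the stop.
early_stop_epoch <- function(monitor_losses, patience) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(monitor_losses)) {
    if (monitor_losses[e] < best) {
      best <- monitor_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

#' Train the classifier with SGD + Nesterov momentum and early stopping
#'
#' Minimises the mean sparse categorical cross-entropy over shuffled
#' mini-batches, applying Nesterov-momentum updates at a constant learning
#' rate. After every epoch the loss and accuracy on the training cohort and
#' on a held-out monitor cohort are recorded; training stops when the
#' monitored loss has not improved for `early_stopping_patience` consecutive
#' epochs, or at `max_epochs`. Shuffling and dropout are re-seeded per epoch
#' from `train_seed`, so identical data, config and seeds reproduce the
#' history and final weights bit-for-bit (single-threaded).
#'
#' @param model An untrained (or previously trained) [build_model()] object.
#' @param train_data,monitor_data `icg_cohort`s, shape-compatible with the
#'   model spec; the monitor cohort should be disjoint from training.
#' @param config An [train_config()].
#' @return An object of class `icg_fit`: list with `model` (trained
#'   `icg_model`), `history` (tibble with one row per epoch: `epoch`,
#'   `train_loss`, `train_acc`, `monitor_loss`, `monitor_acc`),
#'   `stopped_epoch` and `stop_reason` (`"early_stop"` or `"max_epochs"`).
#' @export
train <- function(model, train_data, monitor_data, config = train_config()) {
  stopifnot(inherits(model, "icg_model"),
            inherits(config, "icg_train_config"))
  spec <- model$spec
  check_cohort_shape <- function(coh, what) {
    if (!is.data.frame(coh) || nrow(coh) == 0L) {
      abort(sprintf("`%s` must be a non-empty cohort.", what))
    }
    dims <- dim(coh$signal[[1L]])
    want <- c(spec$n_injectors, spec$n_sensors, spec$n_timesteps)
    if (!all(dims == want)) {
      abort(sprintf(
        "`%s` signals are %s but the model expects %s.",
        what, paste(dims, collapse = " x "), paste(want, collapse = " x ")))
    }
  }
  check_cohort_shape(train_data, "train_data")
  check_cohort_shape(monitor_data, "monitor_data")

  X <- cohort_tensor(train_data)
  y <- train_data$label
  Xm <- cohort_tensor(monitor_data)
  ym <- monitor_data$label
  N <- nrow(train_data)

  params <- model$params
  velocity <- zero_like(params)
  history <- vector("list", config$max_epochs)
  best_loss <- Inf
  best_params <- NULL
  wait <- 0L
  stopped <- config$max_epochs
  reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    withr::with_seed(derive_seed(config$train_seed, 404L, epoch), {
      perm <- sample.int(N)
      for (start in seq(1L, N, by = config$batch_size)) {
        ix <- perm[start:min(start + config$batch_size - 1L, N)]
        Xb <- X[ix, , , , drop = FALSE]
        fw <- nn_forward(params, spec, Xb, training = TRUE,
                         keep_cache = TRUE)
        if (any(!is.finite(fw$probs))) {
          abort(sprintf("NaN/Inf in forward pass at epoch %d; training aborted (try a smaller learning rate).",
                        epoch))
        }
        grads <- nn_backward(params, spec, Xb, y[ix], fw)
        upd <- nesterov_update(params, velocity, grads,
                               config$learning_rate, config$momentum)
        params <- upd$params
        velocity <- upd$velocity
      }
    })
    tr <- nn_eval(params, spec, X, y)
    mo <- nn_eval(params, spec, Xm, ym)
    if (!is.finite(tr$loss) || !is.finite(mo$loss)) {
      abort(sprintf("Non-finite loss after epoch %d; training aborted.", epoch))
    }
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = tr$loss, train_acc = tr$accuracy,
                               monitor_loss = mo$loss, monitor_acc = mo$accuracy)
    if (mo$loss < best_loss) {
      best_loss <- mo$loss
      wait <- 0L
      if (config$restore_best_weights) best_params <- params
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stopping_patience &&
          config$early_stopping_patience > 0L) {
        stopped <- epoch
        reason <- "early_stop"
        break
      }
    }
  }
  if (config$restore_best_weights && !is.null(best_params)) {
    params <- best_params
  }
  model$params <- params
  model$trained <- TRUE
  structure(list(model = model,
                 history = dplyr::bind_rows(history[seq_len(stopped)]),
                 stopped_epoch = stopped,
                 stop_reason = reason,
                 config = config),
            class = "icg_fit")
}

zero_like <- function(params) {
  list(conv = lapply(params$conv, function(l) {
    list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  }),
  W1 = array(0, dim(params$W1)), b1 = numeric(length(params$b1)),
  W2 = array(0, dim(params$W2)), b2 = numeric(length(params$b2)))
}

# Keras-style Nesterov SGD: v <- mu*v - lr*g; w <- w + mu*v - lr*g.
nesterov_update <- function(params, velocity, grads, lr, mu) {
  step <- function(w, v, g) {
    v_new <- mu * v - lr * g
    list(w = w + mu * v_new - lr * g, v = v_new)
  }
  for (b in seq_along(params$conv)) {
    s <- step(params$conv[[b]]$W, velocity$conv[[b]]$W, grads$conv[[b]]$W)
    params$conv[[b]]$W <- s$w; velocity$conv[[b]]$W <- s$v
    s <- step(params$conv[[b]]$b, velocity$conv[[b]]$b, grads$conv[[b]]$b)
    params$conv[[b]]$b <- s$w; velocity$conv[[b]]$b <- s$v
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    s <- step(params[[nm]], velocity[[nm]], grads[[nm]])
    params[[nm]] <- s$w; velocity[[nm]] <- s$v
  }
  list(params = params, velocity = velocity)
}

#' Predict class probabilities for ICG signal tensors
#'
#' Runs the forward pass (dropout disabled) and returns per-patient class
#' probabilities. The predicted class is the argmax; an exact tie is broken
#' toward class 0 (healthy).
#'
#' @param object A trained or untrained `icg_model`.
#' @param newdata An `icg_cohort`, a list of 3 x 5 x 20 arrays, a single
#'   such array, or an N x 3 x 5 x 20 array.
#' @param type `"prob"` for the probability matrix, `"class"` for hard
#'   0/1 labels.
#' @param ... Unused.
#' @return A matrix with `n_classes` columns of probabilities summing to 1
#'   per row (order-preserving), or an integer vector of class labels.
#' @export
predict.icg_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  spec <- object$spec
  X <- as_input_tensor(newdata, spec)
  probs <- matrix(0, dim(X)[1L], spec$n_classes)
  chunk <- 1024L
  for (start in seq(1L, dim(X)[1L], by = chunk)) {
    ix <- start:min(start + chunk - 1L, dim(X)[1L])
    probs[ix, ] <- nn_forward(object$params, spec,
                              X[ix, , , , drop = FALSE])$probs
  }
  if (type == "class") predicted_class(probs) else probs
}

as_input_tensor <- function(newdata, spec) {
  want <- c(spec$n_injectors, spec$n_sensors, spec$n_timesteps)
  if (is.data.frame(newdata) && "signal" %in% names(newdata)) {
    newdata <- newdata$signal
  }
  if (is.list(newdata)) {
    bad <- which(!vapply(newdata, function(z) {
      is.array(z) && length(dim(z)) == 3L && all(dim(z) == want)
    }, logical(1L)))
    if (length(bad)) {
      abort(sprintf("Signal %d is not a %s array.", bad[1L],
                    paste(want, collapse = " x ")))
    }
    X <- array(0, c(length(newdata), want))
    for (k in seq_along(newdata)) X[k, , , ] <- newdata[[k]]
    return(X)
  }
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    if (!all(dim(newdata) == want)) {
      abort(sprintf("Input is %s but the model expects %s.",
                    paste(dim(newdata), collapse = " x "),
                    paste(want, collapse = " x ")))
    }
    X <- array(0, c(1L, want))
    X[1L, , , ] <- newdata
    return(X)
  }
  if (is.array(newdata) && length(dim(newdata)) == 4L &&
      all(dim(newdata)[-1L] == want)) {
    return(newdata)
  }
  abort(sprintf("Cannot interpret `newdata` as %s signal tensors.",
                paste(want, collapse = " x ")))
}

#' Save and load a model as a portable JSON checkpoint
#'
#' The spec is stored as named fields and all trainable scalars as one flat
#' array in a fixed canonical order (per-branch conv weights column-major
#' then conv biases, hidden dense weights/biases, output weights/biases),
#' written at full double precision.
#'
#' @param model An `icg_model`.
#' @param path Output `.json` path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "icg_model"))
  flat <- unlist(lapply(model$params$conv,
                        function(l) c(as.vector(l$W), l$b)),
                 use.names = FALSE)
  flat <- c(flat, as.vector(model$params$W1), model$params$b1,
            as.vector(model$params$W2), model$params$b2)
  x <- list(spec = unclass(model$spec),
            init_seed = model$init_seed,
            trained = model$trained,
            n_parameters = length(flat),
            weights = flat)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(model_spec, as.list(x$spec))
  flat <- as.double(x$weights)
  if (length(flat) != count_parameters(spec)) {
    abort(sprintf(
      "Checkpoint %s is inconsistent with its spec: %d stored scalars, %d expected.",
      path, length(flat), count_parameters(spec)))
  }
  d <- spec_dims(spec)
  kc <- spec$kernel_size * spec$n_sensors
  pos <- 0L
  take <- function(n) {
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  conv <- lapply(seq_len(spec$n_injectors), function(b) {
    list(W = matrix(take(kc * spec$conv_filters), kc, spec$conv_filters),
         b = take(spec$conv_filters))
  })
  params <- list(
    conv = conv,
    W1 = matrix(take(d$concat * spec$dense_hidden), d$concat,
                spec$dense_hidden),
    b1 = take(spec$dense_hidden),
    W2 = matrix(take(spec$dense_hidden * spec$n_classes), spec$dense_hidden,
                spec$n_classes),
    b2 = take(spec$n_classes))
  structure(list(spec = spec, params = params,
                 init_seed = as.integer(x$init_seed),
                 trained = isTRUE(x$trained)),
            class = "icg_model")
}
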