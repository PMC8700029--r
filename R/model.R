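#' Architecture of the branch-fusion 1D convolutional classifier
#'
#' Declares the network that classifies a multi-injector, multi-sensor ICG
#' tensor as healthy or diseased. Each injector's 5 x 20 block is processed
#' by its own branch — a 1D convolution over time with the sensors as input
#' channels (9 filters, kernel 3, stride 1, no padding, ReLU), dropout,
#' max-pooling (pool 2) and flattening — the three branch vectors are
#' concatenated, passed through a ReLU dense layer and a final 2-unit dense
#' layer with softmax. With the defaults the network has exactly 5354
#' trainable parameters. The hidden dense width of 20 is the unique value
#' consistent with that count given the published layer shapes.
#'
#' @param n_injectors,n_sensors,n_timesteps Input tensor dimensions.
#' @param conv_filters,kernel_size,stride Convolution hyperparameters;
#'   `stride` must be 1 (the only supported and published value).
#' @param dropout_rate Dropout probability applied after the convolution
#'   activation, before pooling.
#' @param pool_size Max-pooling window.
#' @param dense_hidden Width of the shared hidden dense layer.
#' @param n_classes Number of output classes (softmax units).
#' @return A list of class `icg_model_spec`.
#' @export
#' @examples
#' count_parameters(model_spec())  # 5354
model_spec <- function(n_injectors = 3L, n_sensors = 5L, n_timesteps = 20L,
                       conv_filters = 9L, kernel_size = 3L, stride = 1L,
                       dropout_rate = 0.2, pool_size = 2L,
                       dense_hidden = 20L, n_classes = 2L) {
  spec <- list(
    n_injectors = assert_count(n_injectors, "n_injectors"),
    n_sensors = assert_count(n_sensors, "n_sensors"),
    n_timesteps = assert_count(n_timesteps, "n_timesteps"),
    conv_filters = assert_count(conv_filters, "conv_filters"),
    kernel_size = assert_count(kernel_size, "kernel_size"),
    stride = assert_count(stride, "stride"),
    dropout_rate = assert_scalar_number(dropout_rate, "dropout_rate",
                                        lower = 0),
    pool_size = assert_count(pool_size, "pool_size"),
    dense_hidden = assert_count(dense_hidden, "dense_hidden"),
    n_classes = assert_count(n_classes, "n_classes", min = 2L)
  )
  if (spec$dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1).")
  if (spec$stride != 1L) abort("Only stride 1 is supported.")
  conv_out <- spec$n_timesteps - spec$kernel_size + 1L
  if (conv_out < spec$pool_size) {
    abort(sprintf(
      "Invalid spec: conv output length %d (= n_timesteps - kernel_size + 1) is smaller than pool_size %d.",
      conv_out, spec$pool_size))
  }
  structure(spec, class = "icg_model_spec")
}

# Derived layer shapes shared by the parameter count and the forward pass.
spec_dims <- function(spec) {
  conv_len <- spec$n_timesteps - spec$kernel_size + 1L
  pool_len <- conv_len %/% spec$pool_size
  branch_flat <- pool_len * spec$conv_filters
  list(conv_len = conv_len, pool_len = pool_len, branch_flat = branch_flat,
       concat = spec$n_injectors * branch_flat)
}

#' Closed-form count of trainable parameters
#'
#' Counts every trainable scalar of the architecture in closed form:
#' `n_injectors * (kernel_size * n_sensors + 1) * conv_filters` for the
#' (unshared) branch convolutions, plus
#' `(concat + 1) * dense_hidden` for the hidden dense layer where
#' `concat = n_injectors * conv_filters * floor((n_timesteps - kernel_size
#' + 1) / pool_size)`, plus `(dense_hidden + 1) * n_classes` for the output
#' layer. Equals the census of an actually built model for any valid spec;
#' the default spec gives 5354.
#'
#' @param spec An [model_spec()].
#' @return Integer number of trainable parameters.
#' @export
count_parameters <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "icg_model_spec"))
  d <- spec_dims(spec)
  conv <- spec$n_injectors * (spec$kernel_size * spec$n_sensors + 1L) *
    spec$conv_filters
  dense1 <- (d$concat + 1L) * spec$dense_hidden
  dense2 <- (spec$dense_hidden + 1L) * spec$n_classes
  as.integer(conv + dense1 + dense2)
}

#' Build a classifier with randomly initialised weights
#'
#' Allocates the weights **w** and biases **b** of the architecture and
#' initialises the weights with Glorot-uniform draws (biases zero),
#' deterministically from `init_seed`.
#'
#' @param spec An [model_spec()].
#' @param init_seed Integer seed for the random initial weights.
#' @return An object of class `icg_model` holding the spec and parameter
#'   arrays.
#' @export
build_model <- function(spec = model_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "icg_model_spec"))
  d <- spec_dims(spec)
  kc <- spec$kernel_size * spec$n_sensors
  glorot <- function(fan_in, fan_out, nrow_, ncol_) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
  }
  params <- withr::with_seed(derive_seed(init_seed, 303L), {
    conv <- lapply(seq_len(spec$n_injectors), function(b) {
      list(W = glorot(kc, spec$kernel_size * spec$conv_filters,
                      kc, spec$conv_filters),
           b = numeric(spec$conv_filters))
    })
    list(conv = conv,
         W1 = glorot(d$concat, spec$dense_hidden, d$concat, spec$dense_hidden),
         b1 = numeric(spec$dense_hidden),
         W2 = glorot(spec$dense_hidden, spec$n_classes,
                     spec$dense_hidden, spec$n_classes),
         b2 = numeric(spec$n_classes))
  })
  structure(list(spec = spec, params = params,
                 init_seed = as.integer(init_seed), trained = FALSE),
            class = "icg_model")
}

# Census of trainable scalars actually allocated in a built model.
n_trainable <- function(model) {
  stopifnot(inherits(model, "icg_model"))
  p <- model$params
  sum(vapply(p$conv, function(l) length(l$W) + length(l$b), double(1L))) +
    length(p$W1) + length(p$b1) + length(p$W2) + length(p$b2)
}

#' @export
print.icg_model <- function(x, ...) {
  s <- x$spec
  d <- spec_dims(s)
  cat(sprintf(
    "<icg_model> %d-branch 1D CNN: conv(%d filters, kernel %d) -> dropout(%.2g) -> maxpool(%d) -> flatten(%d) | concat(%d) -> dense(%d, ReLU) -> dense(%d, softmax)\n",
    s$n_injectors, s$conv_filters, s$kernel_size, s$dropout_rate,
    s$pool_size, d$branch_flat, d$concat, s$dense_hidden, s$n_classes))
  cat(sprintf("  %d trainable parameters; %s\n", n_trainable(x),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Numerically stable softmax
#'
#' Exponentiates and normalises logits so the outputs are positive and sum
#' to one; invariant under adding a constant to all logits.
#'
#' @param logits A numeric vector, or a matrix with one row per example.
#' @return Probabilities of the same shape.
#' @export
#' @examples
#' softmax(c(log(2), 0))  # 2/3, 1/3
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    stopifnot(all(is.finite(logits)))
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

LOG_EPS <- 1e-12  # floor for log arguments in the losses

#' Reference cross-entropy losses
#'
#' `categorical_cross_entropy()` computes `-sum(log(p[true class]))` over
#' examples, accepting either integer class indices (the sparse form) or
#' one-hot rows (the full form); the two are algebraically identical.
#' `binary_cross_entropy()` computes
#' `-sum(t*log(y) + (1-t)*log(1-y))` and equals the categorical form on
#' two-class one-hot problems. Predicted probabilities are floored at 1e-12
#' inside the logarithm so a confident wrong prediction yields a large
#' finite loss rather than an error.
#'
#' @param labels Integer class indices in `0..K-1` (sparse), or a matrix of
#'   one-hot rows.
#' @param predicted A probability matrix with one row per example (rows sum
#'   to 1), or a single probability vector for one example.
#' @param reduction `"sum"` (the defining form) or `"mean"` (per-example
#'   average, as used during training).
#' @return A non-negative scalar; zero exactly when every example puts all
#'   probability on its true class.
#' @export
#' @examples
#' categorical_cross_entropy(0L, c(0.5, 0.5))  # log(2)
categorical_cross_entropy <- function(labels, predicted,
                                      reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!is.matrix(predicted)) predicted <- matrix(predicted, nrow = 1L)
  m <- nrow(predicted)
  if (is.matrix(labels)) {
    stopifnot(all(dim(labels) == dim(predicted)))
    ll <- rowSums(labels * log(pmax(predicted, LOG_EPS)))
  } else {
    labels <- as.integer(labels)
    stopifnot(length(labels) == m, all(labels >= 0L),
              all(labels < ncol(predicted)))
    idx <- cbind(seq_len(m), labels + 1L)
    ll <- log(pmax(predicted[idx], LOG_EPS))
  }
  loss <- -sum(ll)
  if (reduction == "mean") loss / m else loss
}

#' @rdname categorical_cross_entropy
#' @param targets Numeric target values in `[0, 1]` (class-1 membership).
#' @export
binary_cross_entropy <- function(targets, predicted,
                                 reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  stopifnot(length(targets) == length(predicted),
            all(targets >= 0), all(targets <= 1))
  loss <- -sum(targets * log(pmax(predicted, LOG_EPS)) +
                 (1 - targets) * log(pmax(1 - predicted, LOG_EPS)))
  if (reduction == "mean") loss / length(targets) else loss
}
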