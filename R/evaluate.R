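#' Confusion counts and diagnostic metrics
#'
#' Computes the exact confusion table of hard predictions against true
#' labels (1 = diseased positive class, 0 = healthy) and the derived
#' metrics: accuracy `(tp + tn) / total`, sensitivity `tp / (tp + fn)` and
#' specificity `tn / (tn + fp)`. A ratio whose denominator is zero (e.g.
#' specificity of an all-diseased cohort) is reported as `NA`, never as 0.
#'
#' @param labels Integer vector of true labels (0/1).
#' @param predicted Integer vector of predicted labels (0/1).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`, `n`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_metrics <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted), length(labels) >= 1L,
            all(labels %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  tp <- sum(labels == 1L & predicted == 1L)
  tn <- sum(labels == 0L & predicted == 0L)
  fp <- sum(labels == 0L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == 0L)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, n = length(labels),
         accuracy = (tp + tn) / length(labels),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp))
}

#' Evaluate a classifier on a labelled cohort
#'
#' Predicts every record of the cohort and reports exact confusion counts
#' with accuracy, sensitivity and specificity. Deterministic given the model
#' and the data.
#'
#' @param model A (typically trained) `icg_model`.
#' @param data A non-empty `icg_cohort`.
#' @return An `icg_eval` object; see [confusion_metrics()] for the fields.
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(model, "icg_model"))
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a non-empty cohort.")
  }
  pred <- predict(model, data, type = "class")
  rep <- confusion_metrics(data$label, pred)
  structure(list(metrics = rep, n = nrow(data)), class = "icg_eval")
}

#' @export
print.icg_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<icg_eval> n = %d | accuracy %.4f, sensitivity %s, specificity %s\n",
    m$n, m$accuracy,
    ifelse(is.na(m$sensitivity), "NA", sprintf("%.4f", m$sensitivity)),
    ifelse(is.na(m$specificity), "NA", sprintf("%.4f", m$specificity))))
  cat(sprintf("  confusion: tp %d, fn %d, tn %d, fp %d\n",
              m$tp, m$fn, m$tn, m$fp))
  invisible(x)
}

#' Repeat the full study and report mean and spread of the metrics
#'
#' Runs `n_replicates` independent, seeded end-to-end repetitions — fresh
#' training, monitor and test cohorts, fresh weight initialisation, full
#' training, evaluation — and reports the per-metric mean and sample
#' standard deviation across replicates, the reporting style of the original
#' study.
#'
#' @param n_replicates Number of repetitions (>= 2; the standard deviation
#'   is undefined otherwise).
#' @param config Generator config shared by all cohorts.
#' @param n_train,n_monitor,n_test Per-class patient counts
#'   (healthy, diseased) of the three cohorts. Defaults follow the study
#'   design at desk scale: 800 + 800 training, 400 + 400 monitoring.
#' @param noise_std Noise level applied to every cohort.
#' @param spec Model architecture.
#' @param tconf Training configuration.
#' @param seed Master seed; replicate `r` derives its own seeds from it.
#'   Alternatively an integer vector of length `n_replicates` giving each
#'   replicate's seed explicitly.
#' @return An `icg_replication` object: `$replicates` (tibble, one row per
#'   replicate with the metrics and the stopped epoch) and `$summary`
#'   (tibble with mean and sd per metric).
#' @export
replicate_study <- function(n_replicates, config = generator_config(),
                            n_train = c(800L, 800L),
                            n_monitor = c(400L, 400L),
                            n_test = c(1000L, 1000L),
                            noise_std = 0.5,
                            spec = model_spec(),
                            tconf = train_config(),
                            seed = 1L) {
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  seeds <- if (length(seed) == n_replicates) {
    as.integer(seed)
  } else {
    vapply(seq_len(n_replicates), function(r) derive_seed(seed, 70L, r),
           integer(1L))
  }
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    s <- seeds[r]
    res <- run_pipeline_once(config, n_train, n_monitor, n_test, noise_std,
                             spec, tconf, s)
    dplyr::mutate(res$eval$metrics, replicate = r, seed = s,
                  stopped_epoch = res$fit$stopped_epoch,
                  .before = 1L)
  })
  reps <- dplyr::bind_rows(rows)
  summary <- tidyr::pivot_longer(
    reps[c("accuracy", "sensitivity", "specificity")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value),
                              .groups = "drop")
  structure(list(replicates = reps, summary = summary,
                 n_replicates = n_replicates),
            class = "icg_replication")
}

# One end-to-end run: cohorts -> model -> training -> evaluation.
run_pipeline_once <- function(config, n_train, n_monitor, n_test, noise_std,
                              spec, tconf, seed) {
  train_coh <- make_cohort(n_train[1L], n_train[2L], noise_std, config,
                           seed = derive_seed(seed, 11L), split_tag = "train")
  monitor_coh <- make_cohort(n_monitor[1L], n_monitor[2L], noise_std, config,
                             seed = derive_seed(seed, 12L),
                             split_tag = "validation")
  test_coh <- make_cohort(n_test[1L], n_test[2L], noise_std, config,
                          seed = derive_seed(seed, 13L), split_tag = "test")
  model <- build_model(spec, init_seed = derive_seed(seed, 14L))
  tconf$train_seed <- derive_seed(seed, 15L)
  fit <- train(model, train_coh, monitor_coh, tconf)
  list(fit = fit, eval = evaluate(fit$model, test_coh))
}

#' @export
print.icg_replication <- function(x, ...) {
  cat(sprintf("<icg_replication> %d end-to-end replicates\n", x$n_replicates))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s (%.2f +/- %.2f)%%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}
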