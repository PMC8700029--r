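#' Assemble a labelled virtual-patient cohort
#'
#' Samples physiological parameters for the requested numbers of healthy and
#' diseased virtual patients, synthesises their noise-free ICG tensors with
#' the surrogate generator, and superimposes independent Gaussian noise.
#' Every per-patient random stream is derived from the single cohort seed,
#' so the same arguments always reproduce the same cohort record-by-record.
#'
#' @param n_healthy,n_diseased Per-class patient counts (non-negative, not
#'   both zero). The default training design uses 800 of each.
#' @param noise_std Gaussian noise standard deviation added to every data
#'   point (default 0.5, the study's noise level).
#' @param config An [generator_config()].
#' @param seed Integer cohort seed.
#' @param split_tag One of `"train"`, `"test"`, `"validation"`, `"sweep"`;
#'   provenance only.
#' @return An `icg_cohort`: a tibble with one row per patient, the parameter
#'   columns of [sample_params()], a `label` column (0 = healthy,
#'   1 = diseased) and a `signal` list-column of 3 x 5 x 20 arrays.
#'   Provenance (seed, noise std, generator digest and config) is stored in
#'   attributes.
#' @export
#' @examples
#' coh <- make_cohort(4, 4, noise_std = 0.5, seed = 1)
#' dplyr::count(coh, label)
make_cohort <- function(n_healthy, n_diseased, noise_std = 0.5,
                        config = generator_config(), seed = 1L,
                        split_tag = c("train", "test", "validation", "sweep")) {
  n_healthy <- assert_count(n_healthy, "n_healthy", min = 0L)
  n_diseased <- assert_count(n_diseased, "n_diseased", min = 0L)
  if (n_healthy + n_diseased < 1L) {
    abort("A cohort needs at least one patient: n_healthy + n_diseased >= 1.")
  }
  assert_scalar_number(noise_std, "noise_std", lower = 0)
  stopifnot(inherits(config, "icg_generator_config"))
  split_tag <- match.arg(split_tag)

  parts <- list()
  if (n_healthy > 0L) {
    parts$healthy <- sample_params(n_healthy, diseased = FALSE,
                                   rng_seed = derive_seed(seed, 1L))
  }
  if (n_diseased > 0L) {
    parts$diseased <- sample_params(n_diseased, diseased = TRUE,
                                    rng_seed = derive_seed(seed, 2L))
  }
  params <- dplyr::bind_rows(parts)
  clean <- generate_signal_tensor(params, config)
  n <- nrow(params)
  if (noise_std > 0) {
    noise <- withr::with_seed(derive_seed(seed, 3L),
                              rnorm(length(clean), sd = noise_std))
    clean <- clean + noise
  }
  signals <- lapply(seq_len(n), function(k) {
    z <- clean[k, , , , drop = TRUE]
    dim(z) <- c(N_INJECTORS, N_SENSORS, N_TIMESTEPS)
    signal_set(z, noise_std = noise_std)
  })

  cohort <- params
  cohort$patient_id <- seq_len(n)
  cohort$label <- as.integer(cohort$diseased)
  cohort$signal <- signals
  cohort <- dplyr::relocate(cohort, "patient_id", "label")
  new_icg_cohort(cohort,
                 provenance = list(seed = as.integer(seed),
                                   noise_std = as.double(noise_std),
                                   config_digest = config_digest(config),
                                   config = config),
                 split_tag = split_tag)
}

new_icg_cohort <- function(df, provenance, split_tag) {
  structure(df,
            provenance = provenance,
            split_tag = split_tag,
            class = c("icg_cohort", class(tibble())))
}

#' Cohort provenance and split tag
#'
#' @param cohort An `icg_cohort` from [make_cohort()] or [read_dataset()].
#' @return `cohort_provenance()`: a list with `seed`, `noise_std`,
#'   `config_digest` and (when available) the full generator `config`;
#'   `cohort_split()`: the split tag string.
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")

#' @rdname cohort_provenance
#' @export
cohort_split <- function(cohort) attr(cohort, "split_tag")

# Stack the signal list-column into an N x 3 x 5 x 20 tensor for the network.
cohort_tensor <- function(cohort) {
  stopifnot(is.data.frame(cohort), "signal" %in% names(cohort))
  n <- nrow(cohort)
  x <- array(0, c(n, N_INJECTORS, N_SENSORS, N_TIMESTEPS))
  for (k in seq_len(n)) x[k, , , ] <- cohort$signal[[k]]
  x
}

#' @export
print.icg_cohort <- function(x, ...) {
  prov <- cohort_provenance(x)
  cat(sprintf("<icg_cohort> %d patients (%d healthy, %d diseased), split '%s'\n",
              nrow(x), sum(x$label == 0L), sum(x$label == 1L),
              cohort_split(x) %||% "?"))
  if (!is.null(prov)) {
    cat(sprintf("  seed %d, noise std %.3g, generator %s\n",
                prov$seed, prov$noise_std, prov$config_digest))
  }
  NextMethod()
}
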