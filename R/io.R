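#' Write and read labelled cohorts
#'
#' Two on-disk formats are supported, chosen from the file extension:
#' a human-readable CSV (`.csv`) with one row per (patient, injector,
#' sensor) and 20 time columns `t1..t20` next to the label and parameter
#' columns, and a binary Arrow/Feather container (`.feather` or `.arrow`)
#' for large cohorts, which stores doubles exactly. Both carry the full
#' provenance (cohort seed, noise std, generator config digest and the
#' config itself) — in the CSV as `#`-prefixed JSON header lines, in the
#' Feather file as table metadata — so `read_dataset(write_dataset(d))`
#' reproduces `d` field-for-field.
#'
#' Numbers in the CSV are printed with 17 significant digits, which
#' round-trips IEEE doubles exactly.
#'
#' @param dataset An `icg_cohort` from [make_cohort()].
#' @param path Output path ending in `.csv`, `.feather` or `.arrow`.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the reconstructed `icg_cohort`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "icg_cohort"))
  long <- cohort_to_long(dataset)
  meta <- list(
    provenance = serialize_provenance(cohort_provenance(dataset)),
    split_tag = cohort_split(dataset)
  )
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("The Arrow format needs the 'arrow' package; use a .csv path instead.")
    }
    attr(long, "icg_meta") <- jsonlite::toJSON(meta, digits = NA,
                                               auto_unbox = TRUE)
    arrow::write_feather(long, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# icgdx-dataset %s",
                       jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE)),
               con)
    num <- vapply(long, is.double, logical(1L))
    out <- long
    out[num] <- lapply(long[num], function(x) {
      ifelse(is.na(x), "", sprintf("%.17g", x))
    })
    utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("Dataset file not found: %s", path))
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading the Arrow format needs the 'arrow' package.")
    }
    long <- as.data.frame(arrow::read_feather(path))
    meta_json <- attr(long, "icg_meta")
    if (is.null(meta_json)) abort("Not an icgdx dataset: missing metadata.")
    meta <- jsonlite::fromJSON(meta_json, simplifyVector = TRUE)
  } else {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "# icgdx-dataset ")) {
      abort("Not an icgdx dataset CSV: missing '# icgdx-dataset' header line.")
    }
    meta <- jsonlite::fromJSON(sub("^# icgdx-dataset ", "", first),
                               simplifyVector = TRUE)
    long <- utils::read.csv(path, comment.char = "#",
                            colClasses = c(patient_id = "integer",
                                           label = "integer",
                                           injector = "integer",
                                           sensor = "integer"))
  }
  cohort_from_long(as_tibble(long), meta, path)
}

cohort_to_long <- function(dataset) {
  tcols <- paste0("t", seq_len(N_TIMESTEPS))
  rows <- purrr::map(seq_len(nrow(dataset)), function(k) {
    z <- dataset$signal[[k]]
    flat <- matrix(z, N_INJECTORS * N_SENSORS, N_TIMESTEPS)  # injector fastest
    d <- tibble(
      patient_id = dataset$patient_id[k],
      label = dataset$label[k],
      u_rtl = dataset$u_rtl[k], u_theta = dataset$u_theta[k],
      u_rfl = dataset$u_rfl[k], u_alpha = dataset$u_alpha[k],
      rtl_cm = dataset$rtl_cm[k], theta_pct = dataset$theta_pct[k],
      rfl_mm = dataset$rfl_mm[k], alpha_rad = dataset$alpha_rad[k],
      injector = rep(1:3, N_SENSORS),
      sensor = rep(1:5, each = N_INJECTORS)
    )
    d[tcols] <- as.data.frame(flat)
    d
  })
  dplyr::bind_rows(rows)
}

cohort_from_long <- function(long, meta, path) {
  tcols <- paste0("t", seq_len(N_TIMESTEPS))
  need <- c("patient_id", "label", "u_rtl", "u_theta", "u_rfl", "u_alpha",
            "rtl_cm", "theta_pct", "rfl_mm", "alpha_rad",
            "injector", "sensor", tcols)
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    abort(sprintf("Malformed dataset %s: missing columns %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  prov <- deserialize_provenance(meta$provenance)
  noise_std <- prov$noise_std

  by_patient <- split(long, long$patient_id)
  records <- purrr::map(by_patient, function(d) {
    pid <- d$patient_id[1L]
    if (nrow(d) != N_INJECTORS * N_SENSORS) {
      abort(sprintf(
        "Malformed dataset %s: patient %s has %d (injector, sensor) rows; expected %d (tensor must be 3 x 5 x 20).",
        path, pid, nrow(d), N_INJECTORS * N_SENSORS))
    }
    d <- d[order(d$sensor, d$injector), ]
    vals <- as.matrix(d[tcols])
    if (any(!is.finite(vals))) {
      abort(sprintf("Malformed dataset %s: non-finite signal value for patient %s.",
                    path, pid))
    }
    z <- array(as.double(t(vals)), c(N_TIMESTEPS, N_INJECTORS, N_SENSORS))
    z <- aperm(z, c(2L, 3L, 1L))
    row <- d[1L, c("patient_id", "label", "u_rtl", "u_theta", "u_rfl",
                   "u_alpha", "rtl_cm", "theta_pct", "rfl_mm", "alpha_rad")]
    row$diseased <- row$label == 1L
    row$signal <- list(signal_set(z, noise_std = noise_std))
    row
  })
  cohort <- dplyr::bind_rows(records)
  cohort <- cohort[order(cohort$patient_id), ]
  bad <- which(cohort$diseased != (cohort$label == 1L))
  if (length(bad)) {
    abort(sprintf("Malformed dataset %s: label/diseased mismatch at patient %s.",
                  path, cohort$patient_id[bad[1L]]))
  }
  new_icg_cohort(as_tibble(cohort), provenance = prov,
                 split_tag = meta$split_tag %||% "train")
}

serialize_provenance <- function(prov) {
  out <- prov
  if (!is.null(out$config)) {
    cfg <- unclass(out$config)
    cfg$sensor_geometry <- lapply(cfg$sensor_geometry, function(m) {
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    })
    out$config <- cfg
  }
  out
}

deserialize_provenance <- function(prov) {
  out <- prov
  if (!is.null(out$config)) {
    geom <- lapply(out$config$sensor_geometry, function(rows) {
      if (is.matrix(rows)) matrix(as.double(rows), 3L, 5L)
      else do.call(rbind, lapply(rows, as.double))
    })
    out$config <- generator_config(
      base_amplitude = out$config$base_amplitude,
      effect_scale = out$config$effect_scale,
      sensor_geometry = geom,
      rng_seed = out$config$rng_seed
    )
  }
  out$seed <- as.integer(out$seed)
  out$noise_std <- as.double(out$noise_std)
  out
}
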