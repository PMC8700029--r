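# Physiological parameter bounds: true-lumen radius (cm), hematocrit (%),
# false-lumen radius (mm), false-lumen angle (rad).
RTL_RANGE_CM <- c(1.35, 1.95)
THETA_RANGE_PCT <- c(35, 55)
RFL_RANGE_MM <- c(3, 15)

#' Sample virtual-patient physiological parameters
#'
#' Draws the patient-specific parameters uniformly within their
#' physiological bounds, in both unit-interval and physical representation:
#' maximum true-lumen radius `rtl_cm` in \[1.35, 1.95\] cm, hematocrit
#' `theta_pct` in \[35, 55\] %, and — for diseased patients only —
#' false-lumen radius `rfl_mm` in \[3, 15\] mm and false-lumen angular
#' position `alpha_rad` in \[0, 2*pi). Healthy patients carry only the first
#' two parameters; their false-lumen columns are `NA`.
#'
#' @param n Number of patients to draw (positive integer).
#' @param diseased Logical: draw aortic-dissection patients (`TRUE`) or
#'   healthy ones (`FALSE`).
#' @param rng_seed Integer seed; the same seed reproduces the same draws.
#' @return A tibble with one row per patient and columns `u_rtl`, `u_theta`,
#'   `u_rfl`, `u_alpha` (unit interval), `rtl_cm`, `theta_pct`, `rfl_mm`,
#'   `alpha_rad` (physical units) and `diseased`.
#' @export
#' @examples
#' sample_params(3, diseased = TRUE, rng_seed = 42)
sample_params <- function(n, diseased, rng_seed = 1L) {
  n <- assert_count(n, "n", min = 1L)
  stopifnot(is.logical(diseased), length(diseased) == 1L, !is.na(diseased))
  withr::with_seed(derive_seed(rng_seed, 101L), {
    u_rtl <- runif(n)
    u_theta <- runif(n)
    if (diseased) {
      u_rfl <- runif(n)
      u_alpha <- runif(n)
    } else {
      u_rfl <- rep(NA_real_, n)
      u_alpha <- rep(NA_real_, n)
    }
    params_from_unit(u_rtl, u_theta, u_rfl, u_alpha, diseased = diseased)
  })
}

# Map unit-interval draws to physical units; the [0, 1] interval corresponds
# to the physiological bounds.
params_from_unit <- function(u_rtl, u_theta, u_rfl = NA_real_,
                             u_alpha = NA_real_, diseased) {
  tibble(
    u_rtl = u_rtl,
    u_theta = u_theta,
    u_rfl = u_rfl,
    u_alpha = u_alpha,
    rtl_cm = RTL_RANGE_CM[1] + u_rtl * diff(RTL_RANGE_CM),
    theta_pct = THETA_RANGE_PCT[1] + u_theta * diff(THETA_RANGE_PCT),
    rfl_mm = RFL_RANGE_MM[1] + u_rfl * diff(RFL_RANGE_MM),
    alpha_rad = u_alpha * 2 * pi,
    diseased = diseased
  )
}

validate_params <- function(params) {
  need <- c("u_rtl", "u_theta", "u_rfl", "u_alpha", "rtl_cm", "theta_pct",
            "rfl_mm", "alpha_rad", "diseased")
  if (!is.data.frame(params) || !all(need %in% names(params))) {
    abort(paste0("`params` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(!is.finite(params$rtl_cm)) ||
      any(params$rtl_cm < RTL_RANGE_CM[1] - 1e-12) ||
      any(params$rtl_cm > RTL_RANGE_CM[2] + 1e-12)) {
    abort("rtl_cm out of the calibrated range [1.35, 1.95] cm.")
  }
  dis <- params$diseased
  if (any(dis)) {
    r <- params$rfl_mm[dis]
    if (any(!is.finite(r)) || any(r < RFL_RANGE_MM[1] - 1e-12) ||
        any(r > RFL_RANGE_MM[2] + 1e-12)) {
      abort("rfl_mm of diseased patients out of the calibrated range [3, 15] mm.")
    }
  }
  invisible(params)
}
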