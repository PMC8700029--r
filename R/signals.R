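N_INJECTORS <- 3L
N_SENSORS <- 5L
N_TIMESTEPS <- 20L

#' Generate noise-free ICG signal tensors
#'
#' Evaluates the surrogate waveform model at 20 equidistant time steps over
#' half a cardiac cycle, for each of the 3 injector electrode pairs and 5
#' sensor pairs. The healthy channel `(i, s)` is
#' \deqn{Z_{is}(t_k) = A \, g(\theta) \, (R_{TL}/1.65)^2 \, W(t_k; i, s)}
#' with `A` the base amplitude, `g` linear and increasing in hematocrit
#' (`g = theta / 45`, equal to 1 at the midpoint), a quadratic dependence on
#' the true-lumen radius (impedance change scales with the lumen
#' cross-section), and `W` a smooth unimodal half-cycle pulse (raised sine
#' with channel-specific gain, sharpness and onset). Diseased patients add a
#' delayed false-lumen pulse
#' \deqn{\Delta Z_{is}(t_k) = E \, (R_{FL}/15)^2 \,
#'       (1 + 0.5 \cos(\alpha - \phi_{is})) \, V(t_k)}
#' whose magnitude grows quadratically with the false-lumen radius and is
#' modulated across sensors by the false-lumen angle. The output is a
#' deterministic function of the parameters and the config.
#'
#' @param params A one-row (or multi-row) parameter tibble from
#'   [sample_params()].
#' @param config An [generator_config()].
#' @return For a single patient, a 3 x 5 x 20 numeric array (dimensions
#'   injector, sensor, time) with attribute `noise_std = 0`; for `n` rows, a
#'   list of `n` such arrays.
#' @export
#' @examples
#' p <- sample_params(1, diseased = TRUE, rng_seed = 7)
#' z <- generate_signals(p, generator_config())
#' dim(z)
generate_signals <- function(params, config = generator_config()) {
  validate_params(params)
  stopifnot(inherits(config, "icg_generator_config"))
  big <- generate_signal_tensor(params, config)
  out <- lapply(seq_len(nrow(params)), function(n) {
    z <- big[n, , , , drop = TRUE]
    dim(z) <- c(N_INJECTORS, N_SENSORS, N_TIMESTEPS)
    signal_set(z, noise_std = 0)
  })
  if (length(out) == 1L) out[[1L]] else out
}

signal_set <- function(values, noise_std) {
  stopifnot(all(dim(values) == c(N_INJECTORS, N_SENSORS, N_TIMESTEPS)),
            all(is.finite(values)))
  dimnames(values) <- list(
    injector = paste0("i", 1:3),
    sensor = paste0("s", 1:5),
    time = paste0("t", 1:20)
  )
  attr(values, "noise_std") <- as.double(noise_std)
  values
}

# Vectorised core: N x 3 x 5 x 20 tensor for an N-row parameter table.
generate_signal_tensor <- function(params, config) {
  n <- nrow(params)
  geom <- config$sensor_geometry
  tk <- (0:(N_TIMESTEPS - 1L)) / (N_TIMESTEPS - 1L)

  # channel pulse shapes, 15 x 20, identical for every patient
  w_flat <- as.vector(geom$weight)      # injector fastest
  p_flat <- as.vector(geom$power)
  ts_flat <- as.vector(geom$tshift)
  phi_flat <- as.vector(geom$phi)
  u <- clamp01(outer(-ts_flat, tk, `+`))            # 15 x 20
  W <- w_flat * sin(pi * u)^p_flat                  # recycled by row

  amp <- config$base_amplitude * (params$theta_pct / 45) *
    (params$rtl_cm / 1.65)^2                        # length n
  Z <- outer(amp, W)                                # n x 15 x 20

  dis <- which(params$diseased)
  if (length(dis) && config$effect_scale > 0) {
    v <- sin(pi * clamp01((tk - 0.45) / 0.55))^2    # delayed disease pulse
    r2 <- (params$rfl_mm[dis] / RFL_RANGE_MM[2])^2
    mod <- 1 + 0.5 * cos(outer(params$alpha_rad[dis], phi_flat, `-`))
    dz <- outer(config$effect_scale * r2 * mod, v)  # |dis| x 15 x 20
    Z[dis, , ] <- Z[dis, , , drop = FALSE] + dz
  }
  dim(Z) <- c(n, N_INJECTORS, N_SENSORS, N_TIMESTEPS)
  Z
}

#' Superimpose independent Gaussian measurement noise
#'
#' Adds independent zero-mean Gaussian noise of the given standard deviation
#' to every one of the 300 data points of a signal tensor, emulating the
#' noise level of real ICG recordings. Deterministic in the seed.
#'
#' @param signals A 3 x 5 x 20 signal array from [generate_signals()].
#' @param std Noise standard deviation (>= 0, same arbitrary impedance units
#'   as the signal; 0 returns the input unchanged).
#' @param rng_seed Integer seed.
#' @return A signal array of the same shape with attribute `noise_std = std`.
#' @export
add_noise <- function(signals, std, rng_seed = 1L) {
  assert_scalar_number(std, "std", lower = 0)
  stopifnot(is.array(signals),
            all(dim(signals) == c(N_INJECTORS, N_SENSORS, N_TIMESTEPS)))
  if (std == 0) {
    return(signal_set(unclass(signals), noise_std = 0))
  }
  withr::with_seed(derive_seed(rng_seed, 202L), {
    noisy <- signals + rnorm(length(signals), mean = 0, sd = std)
  })
  signal_set(noisy, noise_std = std)
}
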