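# Shared fixtures, built in code.

# A tiny architecture for fast structural tests.
tiny_spec <- function() {
  model_spec(n_injectors = 2L, n_sensors = 2L, n_timesteps = 6L,
             conv_filters = 2L, kernel_size = 2L, dropout_rate = 0,
             pool_size = 2L, dense_hidden = 3L)
}

# A small, noise-free, strongly separable cohort: large disease effect.
separable_cohort <- function(n_per_class = 20L, seed = 1L,
                             split = "train") {
  make_cohort(n_per_class, n_per_class, noise_std = 0,
              config = generator_config(effect_scale = 10),
              seed = seed, split_tag = split)
}

# Matched healthy/diseased parameter pair: identical (u_rtl, u_theta),
# diseased adds (u_rfl, u_alpha). Used by the disease-signature tests.
matched_pair <- function(u_rtl, u_theta, u_rfl, u_alpha) {
  healthy <- icgdx:::params_from_unit(u_rtl, u_theta, diseased = FALSE)
  diseased <- icgdx:::params_from_unit(u_rtl, u_theta, u_rfl, u_alpha,
                                       diseased = TRUE)
  list(healthy = healthy, diseased = diseased)
}

disease_signature_norm <- function(u_rfl, u_rtl = 0.3, u_theta = 0.6,
                                   u_alpha = 0.25,
                                   config = generator_config()) {
  pair <- matched_pair(u_rtl, u_theta, u_rfl, u_alpha)
  zh <- generate_signals(pair$healthy, config)
  zd <- generate_signals(pair$diseased, config)
  sqrt(sum((zd - zh)^2))
}
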