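# shared helpers: independent analytic oracles and pipeline shorthands

# independent Gaussian band evaluation (the oracle against the generator)
oracle_gauss <- function(x, center, fwhm, amp) {
  amp * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

# evaluate a template's band sum directly from its fields, bypassing
# generate_spectrum()'s internals
oracle_template_sum <- function(template, grid, label_state = "light") {
  y <- numeric(length(grid))
  for (b in template$bands) {
    c0 <- b$center
    if (b$labeled && label_state == "heavy") c0 <- c0 - template$isotope_shift
    a <- b$sign * b$amplitude * (if (b$per_label) template$n_labels else 1)
    y <- y + oracle_gauss(grid, c0, b$fwhm, a)
  }
  y
}

noise_free <- function() noise_model(sigma = 0, jitter_sd = 0, seed = 1)

# the study-condition noise model used in noisy checks (SNR ~ 20 on the
# carbonyl difference band for a doubly labeled duplex)
study_noise <- function(seed) {
  noise_model(sigma = 0.06, drift_coeffs = c(0.05, -0.03),
              jitter_sd = 0.3, seed = seed)
}

preprocessed_difference <- function(template, noise, replicate_index = 1L) {
  l <- preprocess(generate_spectrum(template, "light", noise, replicate_index))
  h <- preprocess(generate_spectrum(template, "heavy", noise, replicate_index))
  spectral_difference(l, h)
}

all_presets <- c("TA_WC", "AT_WC", "TA_ECHINOMYCIN_HG",
                 "AT_ECHINOMYCIN_WC", "A6_WC", "M1A_A6_HG")
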