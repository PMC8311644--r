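#' Specify a single absorption band
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude Peak absorbance (arbitrary units), > 0. The sign of the
#'   band in a spectrum is carried by `sign`, not by `amplitude`.
#' @param sign +1 or -1.
#' @param labeled Does the band carry the 13C2 isotope shift? Labeled bands
#'   move down by the template's `isotope_shift` in the heavy variant.
#' @param per_label Does the band amplitude scale with the number of labeled
#'   bases in the duplex?
#' @return A `band_spec` object (a named list).
#' @export
band_spec <- function(center, fwhm, amplitude, sign = 1,
                      labeled = FALSE, per_label = FALSE) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  if (!is.numeric(amplitude) || amplitude <= 0) stop("`amplitude` must be > 0")
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 sign = sign, labeled = isTRUE(labeled),
                 per_label = isTRUE(per_label)),
            class = "band_spec")
}

#' Build a duplex band-model template
#'
#' A `duplex_template` is a named additive band model for one experimental
#' condition: a list of [band_spec()]s, the number of 13C2-labelled thymine
#' bases, and the isotope shift applied to labeled bands in the heavy
#' variant.
#'
#' @param name Template identifier.
#' @param bands List of [band_spec()] objects.
#' @param n_labels Number of labeled T bases, 1 or 2.
#' @param isotope_shift Downshift (cm^-1, >= 0) applied to labeled band
#'   centers in the heavy spectrum. Default 20, the harmonic expectation for
#'   a 12C -> 13C mass change in a partially localized carbonyl stretch.
#' @return A `duplex_template` object.
#' @export
duplex_template <- function(name, bands, n_labels = 2, isotope_shift = 20) {
  if (!n_labels %in% c(1L, 2L)) stop("`n_labels` must be 1 or 2")
  if (isotope_shift < 0) stop("`isotope_shift` must be >= 0")
  if (!length(bands) || !all(vapply(bands, inherits, logical(1), "band_spec"))) {
    stop("`bands` must be a non-empty list of band_spec objects")
  }
  structure(list(name = name, bands = bands, n_labels = as.integer(n_labels),
                 isotope_shift = isotope_shift),
            class = "duplex_template")
}

#' @export
print.duplex_template <- function(x, ...) {
  cat(sprintf("<duplex_template> %s: %d bands, %d label(s), isotope shift %g cm-1\n",
              x$name, length(x$bands), x$n_labels, x$isotope_shift))
  df <- do.call(rbind, lapply(x$bands, function(b) {
    data.frame(center = b$center, fwhm = b$fwhm, amplitude = b$amplitude,
               sign = b$sign, labeled = b$labeled, per_label = b$per_label)
  }))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Preset duplex templates
#'
#' Band models for the six duplex conditions the analysis distinguishes.
#' Every preset carries the phosphate normalization band at 1080 cm^-1 and a
#' labeled major carbonyl band whose amplitude scales with the number of
#' labeled bases (1.0 absorbance unit per label before normalization). The
#' minor carbonyl region carries one quarter of the major amplitude, split
#' into one or two components depending on the condition:
#'
#' * `TA_WC` — free TA duplex, Watson-Crick pairs: major 1720, single broad
#'   minor band at 1670 (fwhm 30), two labels.
#' * `AT_WC` — free AT duplex, Watson-Crick: major 1720, dominant minor
#'   component at 1665 plus a weak shoulder at 1690, two labels.
#' * `TA_ECHINOMYCIN_HG` — echinomycin-bound TA duplex with drug-induced
#'   Hoogsteen A-T pairs: major red-shifted to 1710, minor split into 1690
#'   and 1655, two labels.
#' * `AT_ECHINOMYCIN_WC` — echinomycin-bound AT duplex retaining
#'   Watson-Crick pairs: major 1710, single minor at 1665, two labels.
#' * `A6_WC` — singly labeled A6 duplex, Watson-Crick: same band centers as
#'   `TA_WC` but one label.
#' * `M1A_A6_HG` — singly labeled duplex with N1-methyladenine opposite the
#'   labeled T, chemically enforced Hoogsteen: minor split into 1680 and
#'   1655.
#'
#' Drug-bound presets additionally carry weak unlabeled features at 1740 and
#' 1605 cm^-1 (drug-binding markers); their amplitudes are free parameters
#' of the model, not measured quantities.
#'
#' @param name One of the preset names above.
#' @return A [duplex_template()].
#' @examples
#' make_template("TA_WC")
#' @export
make_template <- function(name) {
  presets <- c("TA_WC", "AT_WC", "TA_ECHINOMYCIN_HG",
               "AT_ECHINOMYCIN_WC", "A6_WC", "M1A_A6_HG")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "))
  }
  phosphate <- band_spec(1080, 35, 2.0)
  major <- function(center) band_spec(center, 25, 1.0, labeled = TRUE, per_label = TRUE)
  minor <- function(center, fwhm, amp) {
    band_spec(center, fwhm, amp, labeled = TRUE, per_label = TRUE)
  }
  aux_drug <- list(band_spec(1740, 20, 0.08), band_spec(1605, 30, 0.10))
  # minor-region total amplitude is 1/4 of the major band (0.25 per label)
  bands <- switch(
    name,
    TA_WC = list(phosphate, major(1720), minor(1670, 30, 0.25)),
    AT_WC = list(phosphate, major(1720),
                 minor(1665, 20, 0.1875), minor(1690, 20, 0.0625)),
    TA_ECHINOMYCIN_HG = c(list(phosphate, major(1710),
                               minor(1690, 20, 0.125), minor(1655, 20, 0.125)),
                          aux_drug),
    AT_ECHINOMYCIN_WC = c(list(phosphate, major(1710), minor(1665, 25, 0.25)),
                          aux_drug),
    A6_WC = list(phosphate, major(1720), minor(1670, 30, 0.25)),
    M1A_A6_HG = list(phosphate, major(1720),
                     minor(1680, 20, 0.125), minor(1655, 20, 0.125))
  )
  n_labels <- if (name %in% c("A6_WC", "M1A_A6_HG")) 1L else 2L
  duplex_template(name, bands, n_labels = n_labels, isotope_shift = 20)
}

#' Replicate noise model
#'
#' Describes the stochastic components added to generated spectra: additive
#' Gaussian noise, a smooth polynomial baseline drift, and
#' replicate-to-replicate jitter of band centers. The same
#' `(seed, replicate_index, label_state)` triple always reproduces the same
#' spectrum; there is no hidden global RNG state.
#'
#' @param sigma Additive noise SD (absorbance units), >= 0.
#' @param drift_coeffs Polynomial coefficients of the baseline drift,
#'   evaluated in the scaled coordinate `t = (nu - min) / (max - min)` over
#'   the grid: `drift = c[1] + c[2] t + c[3] t^2 + ...`. Default no drift.
#' @param jitter_sd SD (cm^-1) of a per-band, per-spectrum center jitter.
#' @param seed Integer base seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma = 0.005, drift_coeffs = numeric(0),
                        jitter_sd = 0, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  structure(list(sigma = sigma, drift_coeffs = as.numeric(drift_coeffs),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# evaluate with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# one deterministic sub-seed per (seed, replicate, label state), < 2^31
stream_seed <- function(seed, replicate_index, label_state) {
  base <- (abs(as.numeric(seed)) %% 1e6) * 2011 +
    as.numeric(replicate_index) * 7919 +
    if (identical(label_state, "heavy")) 104729 else 0
  as.integer(base %% 2147483647)
}

# unit-amplitude line profiles; fwhm > 0
profile_gaussian <- function(x, center, fwhm) {
  exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

profile_lorentzian <- function(x, center, fwhm) {
  1 / (1 + 4 * ((x - center) / fwhm)^2)
}

# pseudo-Voigt: eta Lorentzian + (1 - eta) Gaussian with a shared fwhm
profile_pseudo_voigt <- function(x, center, fwhm, eta) {
  eta * profile_lorentzian(x, center, fwhm) +
    (1 - eta) * profile_gaussian(x, center, fwhm)
}

band_profile <- function(x, center, fwhm, profile = "gaussian", eta = 0.5) {
  switch(profile,
         gaussian = profile_gaussian(x, center, fwhm),
         pseudo_voigt = profile_pseudo_voigt(x, center, fwhm, eta),
         stop("unknown profile '", profile, "'"))
}

#' Default wavenumber grid
#'
#' 1000-1800 cm^-1 at 1 cm^-1 spacing. The fine grid keeps interpolation and
#' fitting discretization errors well below the 4 cm^-1 instrument
#' resolution the band positions are reported at; [resample()] can coarsen
#' to 4 cm^-1 when emulating raw instrument output.
#'
#' @param from,to,by Grid limits and step (cm^-1).
#' @return Numeric wavenumber vector.
#' @export
default_grid <- function(from = 1000, to = 1800, by = 1) seq(from, to, by = by)

# effective signed amplitude of a band within a template
effective_amplitude <- function(band, template) {
  band$sign * band$amplitude * (if (band$per_label) template$n_labels else 1)
}

# band centers actually used for a given label state
effective_center <- function(band, template, label_state) {
  band$center - (if (band$labeled && label_state == "heavy") template$isotope_shift else 0)
}

#' Generate one synthetic spectrum
#'
#' Evaluates the template's additive band model on a wavenumber grid and
#' adds baseline drift and Gaussian noise. In the heavy variant every
#' labeled band is moved down by the template's isotope shift; bands flagged
#' `per_label` have their amplitude multiplied by the number of labeled
#' bases. Output is deterministic given `(noise$seed, replicate_index,
#' label_state)`.
#'
#' @param template A [duplex_template()].
#' @param label_state `"light"` (12C) or `"heavy"` (13C2).
#' @param noise A [noise_model()].
#' @param replicate_index Integer replicate number (>= 1).
#' @param grid Wavenumber grid; default [default_grid()].
#' @param profile Band line shape, `"gaussian"` (default) or
#'   `"pseudo_voigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt profile.
#' @return An [ir_spectrum()] with provenance metadata.
#' @examples
#' s <- generate_spectrum(make_template("TA_WC"), "light",
#'                        noise_model(sigma = 0), 1)
#' s$grid[which.max(s$values[s$grid > 1600])]
#' @export
generate_spectrum <- function(template, label_state = c("light", "heavy"),
                              noise = noise_model(), replicate_index = 1L,
                              grid = default_grid(),
                              profile = c("gaussian", "pseudo_voigt"),
                              eta = 0.5) {
  label_state <- match.arg(label_state)
  profile <- match.arg(profile)
  stopifnot(inherits(template, "duplex_template"), inherits(noise, "noise_model"))
  centers <- vapply(template$bands, effective_center, numeric(1),
                    template = template, label_state = label_state)
  if (any(centers < min(grid) | centers > max(grid))) {
    stop("grid span [", min(grid), ", ", max(grid),
         "] does not cover all band centers (", paste(round(centers), collapse = ", "), ")")
  }
  n <- length(grid)
  seed_k <- stream_seed(noise$seed, replicate_index, label_state)
  draws <- with_seed(seed_k, {
    list(jitter = stats::rnorm(length(template$bands), 0, max(noise$jitter_sd, 0)),
         eps = stats::rnorm(n, 0, max(noise$sigma, 0)))
  })
  if (noise$jitter_sd == 0) draws$jitter[] <- 0
  if (noise$sigma == 0) draws$eps[] <- 0
  values <- numeric(n)
  for (i in seq_along(template$bands)) {
    b <- template$bands[[i]]
    a <- effective_amplitude(b, template)
    values <- values + a * band_profile(grid, centers[i] + draws$jitter[i],
                                        b$fwhm, profile, eta)
  }
  if (length(noise$drift_coeffs)) {
    t <- (grid - min(grid)) / diff(range(grid))
    drift <- rowSums(outer(t, seq_along(noise$drift_coeffs) - 1, `^`) *
                       rep(noise$drift_coeffs, each = n))
    values <- values + drift
  }
  values <- values + draws$eps
  ir_spectrum(grid, values,
              meta = list(template = template$name, label_state = label_state,
                          replicate = as.integer(replicate_index),
                          history = list("generated")))
}

#' Generate paired light/heavy replicate sets
#'
#' @param template A [duplex_template()].
#' @param noise A [noise_model()].
#' @param n Number of replicates (>= 2; noise lines need pairs).
#' @param ... Passed to [generate_spectrum()] (`grid`, `profile`, `eta`).
#' @return A list with elements `light` and `heavy`, each a list of `n`
#'   [ir_spectrum()]s with independent noise draws.
#' @export
generate_replicates <- function(template, noise = noise_model(), n = 3L, ...) {
  if (n < 2) stop("`n` must be >= 2 (replicate-minus-replicate noise lines need pairs)")
  list(
    light = lapply(seq_len(n), function(k) {
      generate_spectrum(template, "light", noise, k, ...)
    }),
    heavy = lapply(seq_len(n), function(k) {
      generate_spectrum(template, "heavy", noise, k, ...)
    })
  )
}

#' Expected components of a light-minus-heavy difference spectrum
#'
#' Derives, from a template, the signed band components expected in its
#' isotope-edited difference spectrum: each labeled band contributes a
#' positive component at its light position and a negative component at its
#' heavy (downshifted) position; unlabeled bands cancel. Amplitudes are
#' expressed on the phosphate-normalized scale. Useful for initializing
#' [fit_bands()] when band assignments are known a priori, as is standard in
#' band deconvolution.
#'
#' @param template A [duplex_template()].
#' @return A data frame with columns `center`, `fwhm`, `amplitude` (signed).
#' @export
difference_components <- function(template) {
  stopifnot(inherits(template, "duplex_template"))
  phos <- vapply(template$bands, function(b) {
    if (!b$labeled && b$center >= 1050 && b$center <= 1110) b$amplitude else NA_real_
  }, numeric(1))
  norm <- if (all(is.na(phos))) 1 else max(phos, na.rm = TRUE)
  out <- do.call(rbind, lapply(template$bands, function(b) {
    if (!b$labeled) return(NULL)
    a <- effective_amplitude(b, template) / norm
    data.frame(center = c(b$center, b$center - template$isotope_shift),
               fwhm = b$fwhm, amplitude = c(a, -a))
  }))
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  out
}
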