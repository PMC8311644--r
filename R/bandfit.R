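#' Find signed peaks in a window
#'
#' Local maxima of the absolute absorbance inside the window, each tagged
#' with the sign of the underlying value. Intended to initialize
#' [fit_bands()]. A peak must exceed `min_prominence * noise_rms`; with the
#' default `noise_rms = 0` every strict local extremum is returned.
#'
#' @param x An [ir_spectrum()].
#' @param window Search window `c(lo, hi)` (cm^-1).
#' @param noise_rms Noise RMS estimate (e.g. from a noise line), used to
#'   threshold peaks.
#' @param min_prominence Threshold in units of `noise_rms`.
#' @return A data frame with columns `center`, `value`, `sign`, sorted by
#'   decreasing `abs(value)`. Zero rows if nothing qualifies.
#' @export
find_peaks <- function(x, window = c(1600, 1780), noise_rms = 0,
                       min_prominence = 3) {
  stopifnot(is_ir_spectrum(x))
  idx <- window_idx(x, window)
  g <- x$grid[idx]
  v <- x$values[idx]
  s <- abs(v)
  n <- length(s)
  if (n < 3L) return(data.frame(center = numeric(0), value = numeric(0),
                                sign = numeric(0)))
  thr <- min_prominence * noise_rms
  is_pk <- logical(n)
  for (i in 2:(n - 1L)) {
    is_pk[i] <- s[i] > s[i - 1L] && s[i] >= s[i + 1L] && s[i] > thr && s[i] > 0
  }
  out <- data.frame(center = g[is_pk], value = v[is_pk],
                    sign = sign(v[is_pk]))
  out[order(-abs(out$value)), , drop = FALSE]
}

band_model <- function(par, grid, k, profile, eta) {
  # par = (amp_1, center_1, fwhm_1, ..., amp_k, center_k, fwhm_k)
  y <- numeric(length(grid))
  for (j in seq_len(k)) {
    a <- par[3L * j - 2L]
    c0 <- par[3L * j - 1L]
    w <- par[3L * j]
    y <- y + a * band_profile(grid, c0, w, profile, eta)
  }
  y
}

fit_k_bands <- function(g, v, init, profile, eta, min_fwhm, max_fwhm,
                        center_slack = Inf, fix_sign = FALSE) {
  k <- nrow(init)
  par0 <- as.numeric(t(as.matrix(init[, c("amplitude", "center", "fwhm")])))
  amp_abs <- max(abs(v))
  lower <- upper <- numeric(3L * k)
  for (j in seq_len(k)) {
    a0 <- init$amplitude[j]
    if (fix_sign) {
      # assignment-driven deconvolution: each component keeps its assigned
      # sign and stays within a factor of 3 of its assigned amplitude and a
      # factor of 2 of its assigned width, which keeps overlapping
      # opposite-sign components from inflating while cancelling
      a_lo <- abs(a0) / 3
      a_hi <- abs(a0) * 3
      lower[3L * j - 2L] <- if (a0 >= 0) a_lo else -a_hi
      upper[3L * j - 2L] <- if (a0 >= 0) a_hi else -a_lo
      lower[3L * j] <- max(min_fwhm, init$fwhm[j] / 2)
      upper[3L * j] <- min(max_fwhm, init$fwhm[j] * 2)
    } else {
      lower[3L * j - 2L] <- -5 * amp_abs
      upper[3L * j - 2L] <- 5 * amp_abs
      lower[3L * j] <- min_fwhm
      upper[3L * j] <- max_fwhm
    }
    lower[3L * j - 1L] <- max(min(g), init$center[j] - center_slack)
    upper[3L * j - 1L] <- min(max(g), init$center[j] + center_slack)
  }
  par0 <- pmin(pmax(par0, lower), upper)
  res_fn <- function(p) band_model(p, g, k, profile, eta) - v
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                 maxfev = 20000))
  rss <- sum(fit$fvec^2)
  se <- rep(NA_real_, 3L * k)
  cov <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) NULL)
  if (!is.null(cov)) se <- as.numeric(cov)
  comp <- data.frame(
    id = seq_len(k),
    amplitude = fit$par[seq(1L, 3L * k, by = 3L)],
    center = fit$par[seq(2L, 3L * k, by = 3L)],
    fwhm = fit$par[seq(3L, 3L * k, by = 3L)],
    se_amplitude = se[seq(1L, 3L * k, by = 3L)],
    se_center = se[seq(2L, 3L * k, by = 3L)],
    se_fwhm = se[seq(3L, 3L * k, by = 3L)]
  )
  list(components = comp, rss = rss, info = fit$info,
       message = fit$message, par = fit$par)
}

aicc <- function(rss, n, p) {
  rss <- max(rss, n * .Machine$double.eps^2)
  penalty <- if (n - p - 1L > 0L) 2 * p * (p + 1) / (n - p - 1L) else Inf
  n * log(rss / n) + 2 * p + penalty
}

#' Fit multi-component band models
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt with box bounds) of a
#' sum of k signed Gaussian or pseudo-Voigt components inside a window.
#' When `init` is `NULL`, candidate components are seeded from
#' [find_peaks()] and k is selected among 1..`k_max` by a corrected-AIC
#' criterion on the residuals, with ties broken toward smaller k so noise
#' is not over-fitted into spurious splits. When `init` is supplied (a data
#' frame of `center`, `fwhm`, `amplitude` — e.g. from
#' [difference_components()] when band assignments are known a priori), all
#' of its components are fitted with each center bounded within
#' `center_slack` of its initial value and each amplitude confined to its
#' initial sign, the usual constraints of assignment-driven band
#' deconvolution.
#'
#' Widths are bounded below by twice the grid step so components cannot
#' collapse onto single grid points.
#'
#' @param x An [ir_spectrum()].
#' @param window Fit window `c(lo, hi)` (cm^-1).
#' @param k_max Maximum number of components for automatic selection.
#' @param profile `"gaussian"` (default) or `"pseudo_voigt"`.
#' @param eta Fixed Lorentzian fraction for pseudo-Voigt components.
#' @param init Optional initial component table (see above).
#' @param center_slack Center bound half-width (cm^-1) when `init` is
#'   given.
#' @param max_fwhm Upper width bound (cm^-1).
#' @return An object of class `band_fit`: `window`, `components` (sorted by
#'   center, with standard errors; the `id` column is the index of the
#'   initializing component, so assigned identities survive the sort),
#'   `residual_rms`, `model_selection` (k candidates and AICc), `profile`.
#' @examples
#' reps <- generate_replicates(make_template("TA_WC"), noise_model(sigma = 0), 2)
#' d <- spectral_difference(preprocess(reps$light[[1]]), preprocess(reps$heavy[[1]]))
#' fit_bands(d, c(1600, 1780), k_max = 4)
#' @export
fit_bands <- function(x, window = c(1600, 1780), k_max = 4L,
                      profile = c("gaussian", "pseudo_voigt"), eta = 0.5,
                      init = NULL, center_slack = 4, max_fwhm = 80) {
  stopifnot(is_ir_spectrum(x))
  profile <- match.arg(profile)
  if (k_max < 1L) stop("`k_max` must be >= 1")
  idx <- window_idx(x, window)
  g <- x$grid[idx]
  v <- x$values[idx]
  step <- stats::median(diff(g))
  min_fwhm <- 2 * step

  if (!is.null(init)) {
    stopifnot(all(c("center", "fwhm", "amplitude") %in% names(init)))
    ft <- fit_k_bands(g, v, init, profile, eta, min_fwhm, max_fwhm,
                      center_slack = center_slack, fix_sign = TRUE)
    if (!ft$info %in% 1:4) {
      stop("band fit did not converge (", ft$message, "); last residual RMS ",
           signif(sqrt(ft$rss / length(g)), 4))
    }
    sel <- data.frame(k = nrow(init), aicc = aicc(ft$rss, length(g), 3L * nrow(init)),
                      chosen = TRUE)
    best <- ft
  } else {
    peaks <- find_peaks(x, window)
    if (nrow(peaks) == 0L) stop("no peaks found in window to initialize the fit")
    k_hi <- min(k_max, nrow(peaks))
    fits <- vector("list", k_hi)
    sel <- data.frame(k = seq_len(k_hi), aicc = NA_real_, chosen = FALSE)
    for (k in seq_len(k_hi)) {
      init_k <- data.frame(center = peaks$center[seq_len(k)],
                           fwhm = rep(15, k),
                           amplitude = peaks$value[seq_len(k)])
      ft <- try(fit_k_bands(g, v, init_k, profile, eta, min_fwhm, max_fwhm),
                silent = TRUE)
      if (!inherits(ft, "try-error") && ft$info %in% 1:4) {
        fits[[k]] <- ft
        sel$aicc[k] <- aicc(ft$rss, length(g), 3L * k)
      }
    }
    if (all(is.na(sel$aicc))) {
      stop("band fit did not converge for any k in 1..", k_hi)
    }
    k_best <- which(sel$aicc <= min(sel$aicc, na.rm = TRUE) + 1e-9)[1L]
    sel$chosen[k_best] <- TRUE
    best <- fits[[k_best]]
  }

  comp <- best$components
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(window = window,
                 components = comp,
                 residual_rms = sqrt(best$rss / length(g)),
                 model_selection = sel,
                 profile = profile),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %d %s component(s) in %g-%g cm-1, residual RMS %.3g\n",
              nrow(x$components), x$profile, x$window[1], x$window[2],
              x$residual_rms))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit an isotope-pair difference model
#'
#' Fits a light-minus-heavy difference spectrum with the model an
#' isotope-edited experiment actually implies: each labeled band
#' contributes a positive component at its light position and a negative
#' partner of *equal amplitude and width* at the position downshifted by
#' one shared isotope shift. Isotope substitution leaves the oscillator
#' strength and bandwidth essentially unchanged and shifts every mode
#' carrying the labeled atom by the same reduced-mass factor, so the tied
#' parameterization is physical — and it removes the shift-versus-
#' amplitude trade-off that makes free signed fits of strongly overlapped
#' band pairs weakly identified.
#'
#' Parameters are one global shift plus (amplitude, center, fwhm) per
#' labeled band; the same assignment-window constraints as init-seeded
#' [fit_bands()] apply (center within `center_slack`, amplitude within a
#' factor of 3, width within a factor of 2 of the assigned values).
#'
#' @param x An [ir_spectrum()] difference spectrum.
#' @param pairs Data frame of assigned light-side bands: columns `center`,
#'   `fwhm`, `amplitude` (positive). From a template, the positive rows of
#'   [difference_components()].
#' @param window Fit window (cm^-1).
#' @param shift_init,shift_range Initial value and bounds (cm^-1) for the
#'   shared isotope shift.
#' @param profile,eta,center_slack,max_fwhm As in [fit_bands()].
#' @return A `band_fit` whose `components` hold the 2k tied components
#'   (light positive and heavy negative, `id` pairing them), plus a
#'   `shift` element with the fitted isotope shift and `se_shift` its
#'   standard error.
#' @export
fit_isotope_pairs <- function(x, pairs, window = c(1600, 1780),
                              shift_init = 20, shift_range = c(0, 40),
                              profile = c("gaussian", "pseudo_voigt"),
                              eta = 0.5, center_slack = 4, max_fwhm = 80) {
  stopifnot(is_ir_spectrum(x))
  profile <- match.arg(profile)
  stopifnot(all(c("center", "fwhm", "amplitude") %in% names(pairs)))
  if (any(pairs$amplitude <= 0)) stop("`pairs` amplitudes must be positive (light side)")
  idx <- window_idx(x, window)
  g <- x$grid[idx]
  v <- x$values[idx]
  step <- stats::median(diff(g))
  k <- nrow(pairs)
  # par = (shift, A_1, c_1, w_1, ..., A_k, c_k, w_k)
  par0 <- c(shift_init, as.numeric(t(as.matrix(pairs[, c("amplitude", "center", "fwhm")]))))
  lower <- c(shift_range[1L],
             as.numeric(t(cbind(pairs$amplitude / 3,
                                pairs$center - center_slack,
                                pmax(2 * step, pairs$fwhm / 2)))))
  upper <- c(shift_range[2L],
             as.numeric(t(cbind(pairs$amplitude * 3,
                                pairs$center + center_slack,
                                pmin(max_fwhm, pairs$fwhm * 2)))))
  par0 <- pmin(pmax(par0, lower), upper)
  model <- function(p) {
    y <- numeric(length(g))
    for (j in seq_len(k)) {
      a <- p[3L * j - 1L]
      c0 <- p[3L * j]
      w <- p[3L * j + 1L]
      y <- y + a * (band_profile(g, c0, w, profile, eta) -
                      band_profile(g, c0 - p[1L], w, profile, eta))
    }
    y
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(p) model(p) - v,
                            control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                 maxfev = 20000))
  if (!fit$info %in% 1:4) {
    stop("isotope-pair fit did not converge (", fit$message, ")")
  }
  se <- rep(NA_real_, length(par0))
  se_try <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  if (!is.null(se_try)) se <- as.numeric(se_try)
  amp <- fit$par[seq(2L, by = 3L, length.out = k)]
  cen <- fit$par[seq(3L, by = 3L, length.out = k)]
  wid <- fit$par[seq(4L, by = 3L, length.out = k)]
  comp <- data.frame(
    id = rep(seq_len(k), 2L),
    amplitude = c(amp, -amp),
    center = c(cen, cen - fit$par[1L]),
    fwhm = c(wid, wid),
    se_amplitude = rep(se[seq(2L, by = 3L, length.out = k)], 2L),
    se_center = rep(se[seq(3L, by = 3L, length.out = k)], 2L),
    se_fwhm = rep(se[seq(4L, by = 3L, length.out = k)], 2L)
  )
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(window = window, components = comp,
                 residual_rms = sqrt(sum(fit$fvec^2) / length(g)),
                 model_selection = data.frame(k = k, aicc = aicc(sum(fit$fvec^2),
                                                                 length(g), 3L * k + 1L),
                                              chosen = TRUE),
                 profile = profile,
                 shift = fit$par[1L], se_shift = se[1L]),
            class = "band_fit")
}

#' Estimate the isotope shift from a difference spectrum
#'
#' Fits the difference spectrum in the carbonyl window and returns the
#' center of the strongest positive component minus the center of the
#' strongest negative component — the light-minus-heavy frequency downshift
#' of the labeled carbonyl (about 20 cm^-1 for a 12C -> 13C substitution in
#' a partially localized C=O stretch).
#'
#' @param diff An [ir_spectrum()] difference spectrum.
#' @param window Fit window; default 1600-1780 cm^-1.
#' @param k_max,init,... Passed to [fit_bands()].
#' @return The shift in cm^-1 (positive when heavy is downshifted).
#' @export
isotope_shift_estimate <- function(diff, window = c(1600, 1780), k_max = 6L,
                                   init = NULL, ...) {
  stopifnot(is_ir_spectrum(diff))
  if (is.null(init)) {
    peaks <- find_peaks(diff, window)
    if (!any(peaks$sign > 0) || !any(peaks$sign < 0)) {
      stop("difference spectrum lacks a ",
           if (!any(peaks$sign > 0)) "positive" else "negative",
           " peak in the window: no isotope-edited band pair to measure")
    }
  }
  fit <- fit_bands(diff, window, k_max = k_max, init = init, ...)
  major_pair_shift(fit, init)
}

# shift from the fitted major band pair; with an init table the pair is the
# assigned strongest positive/negative initial components (robust to noise
# inflating weak overlapping components), otherwise the strongest fitted ones
major_pair_shift <- function(fit, init = NULL) {
  comp <- fit$components
  if (!any(comp$amplitude > 0) || !any(comp$amplitude < 0)) {
    stop("fitted model lacks components of both signs: cannot form a shift")
  }
  if (!is.null(init)) {
    pos <- comp$center[comp$id == which.max(init$amplitude)]
    neg <- comp$center[comp$id == which.min(init$amplitude)]
  } else {
    pos <- comp$center[which.max(comp$amplitude)]
    neg <- comp$center[which.min(comp$amplitude)]
  }
  pos - neg
}

#' Classify minor-band splitting and the Hoogsteen marker
#'
#' Examines the positive components of a band fit that fall inside the
#' minor carbonyl window. The region is called split when at least two
#' positive components are separated by `min_separation` or more and the
#' weaker is at least `min_amp_fraction` of the stronger. The Hoogsteen
#' marker fires when the region is split and the lowest split component
#' lies at or below `marker_cutoff`: both Hoogsteen-forming conditions show
#' a ~1655 cm^-1 component and no Watson-Crick condition does, so a low
#' split component distinguishes the pairing geometries.
#'
#' Negative (heavy-side) components are ignored, which automatically
#' excludes the downshifted heavy major band that overlaps the minor window
#' in drug-bound conditions.
#'
#' @param fit A `band_fit` from [fit_bands()] whose window covers
#'   `minor_window`.
#' @param min_separation Minimum center separation (cm^-1) for a split.
#' @param min_amp_fraction Minimum weaker/stronger amplitude ratio; the
#'   default 0.2 keeps a weak shoulder countable.
#' @param minor_window The minor carbonyl region, default 1630-1700 cm^-1.
#' @param marker_cutoff Hoogsteen cutoff (cm^-1) for the lower split
#'   component, default 1660.
#' @return An object of class `split_call`: list with `is_split`,
#'   `hoogsteen_marker`, and `components` (the positive minor-region
#'   components considered).
#' @export
detect_splitting <- function(fit, min_separation = 10, min_amp_fraction = 0.2,
                             minor_window = c(1630, 1700),
                             marker_cutoff = 1660) {
  stopifnot(inherits(fit, "band_fit"))
  if (fit$window[1L] > minor_window[1L] || fit$window[2L] < minor_window[2L]) {
    stop("fit window [", fit$window[1L], ", ", fit$window[2L],
         "] does not cover the minor region [", minor_window[1L], ", ",
         minor_window[2L], "]")
  }
  comp <- fit$components
  comp <- comp[comp$amplitude > 0 &
                 comp$center >= minor_window[1L] &
                 comp$center <= minor_window[2L], , drop = FALSE]
  is_split <- FALSE
  marker <- FALSE
  members <- comp
  if (nrow(comp) >= 2L) {
    comp <- comp[order(-comp$amplitude), , drop = FALSE]
    strongest <- comp[1L, ]
    qualifies <- abs(comp$center - strongest$center) >= min_separation &
      comp$amplitude >= min_amp_fraction * strongest$amplitude
    qualifies[1L] <- TRUE
    members <- comp[qualifies, , drop = FALSE]
    is_split <- nrow(members) >= 2L
    if (is_split) marker <- min(members$center) <= marker_cutoff
  }
  structure(list(is_split = is_split, hoogsteen_marker = marker,
                 components = members[order(members$center), , drop = FALSE]),
            class = "split_call")
}

#' @export
print.split_call <- function(x, ...) {
  cat(sprintf("<split_call> split: %s, Hoogsteen marker: %s\n",
              x$is_split, x$hoogsteen_marker))
  if (nrow(x$components)) print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Full analysis of an isotope-edited difference spectrum
#'
#' Convenience wrapper. With a template (a priori band assignments), the
#' difference is fitted with the tied isotope-pair model
#' ([fit_isotope_pairs()]) whose shared shift is the isotope-shift
#' estimate; without one, a free signed fit ([fit_bands()]) seeded from
#' detected peaks is used and the shift is taken between the strongest
#' positive and negative components. Minor-band splitting is classified on
#' the fitted positive components either way.
#'
#' @param diff An [ir_spectrum()] difference spectrum.
#' @param template Optional [duplex_template()] supplying a priori band
#'   assignments via [difference_components()].
#' @param window Carbonyl fit window.
#' @param ... Passed to [fit_isotope_pairs()] or [fit_bands()].
#' @return A list with `fit` (band_fit), `isotope_shift` (cm^-1), and
#'   `split` (split_call).
#' @export
analyze_difference <- function(diff, template = NULL, window = c(1600, 1780),
                               ...) {
  if (!is.null(template)) {
    comps <- difference_components(template)
    pairs <- comps[comps$amplitude > 0 &
                     comps$center >= window[1L] & comps$center <= window[2L], ,
                   drop = FALSE]
    fit <- fit_isotope_pairs(diff, pairs, window,
                             shift_init = template$isotope_shift, ...)
    shift <- fit$shift
  } else {
    fit <- fit_bands(diff, window, ...)
    shift <- tryCatch(major_pair_shift(fit), error = function(e) NA_real_)
  }
  list(fit = fit, isotope_shift = shift, split = detect_splitting(fit))
}
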