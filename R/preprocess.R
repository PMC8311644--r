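#' Multipoint baseline correction
#'
#' Subtracts from the spectrum the interpolant through its own values at the
#' anchor wavenumbers, so the corrected spectrum is exactly zero at every
#' anchor. This mirrors vendor-style multipoint baselining; both
#' piecewise-linear and natural-spline interpolants are provided since
#' vendor implementations differ. The operation is linear in the spectrum
#' and idempotent.
#'
#' Default anchors flank the two analysis windows where duplex spectra are
#' locally flat: 1000 and 1350 cm^-1 around the phosphate band and 1550 and
#' 1790 cm^-1 around the carbonyl region.
#'
#' @param x An [ir_spectrum()].
#' @param anchors Strictly increasing anchor wavenumbers (>= 2), all inside
#'   the grid span.
#' @param mode `"linear"` (piecewise-linear, default) or `"spline"`
#'   (natural cubic).
#' @return The baseline-corrected [ir_spectrum()].
#' @examples
#' s <- generate_spectrum(make_template("TA_WC"), "light", noise_model(sigma = 0), 1)
#' b <- baseline_correct(s)
#' @export
baseline_correct <- function(x, anchors = c(1000, 1350, 1550, 1790),
                             mode = c("linear", "spline")) {
  stopifnot(is_ir_spectrum(x))
  mode <- match.arg(mode)
  anchors <- as.numeric(anchors)
  if (length(anchors) < 2L) stop("need at least 2 baseline anchors")
  if (any(diff(anchors) <= 0)) stop("`anchors` must be strictly increasing")
  if (min(anchors) < min(x$grid) || max(anchors) > max(x$grid)) {
    stop("anchor outside the grid span [", min(x$grid), ", ", max(x$grid), "]")
  }
  anchor_vals <- stats::approx(x$grid, x$values, xout = anchors)$y
  # a cubic spline needs >= 3 knots; through 2 anchors both modes are a line
  base <- if (mode == "linear" || length(anchors) < 3L) {
    grad_lo <- grad_hi <- 0
    if (length(anchors) >= 2L) {
      grad_lo <- grad_hi <- diff(anchor_vals[1:2]) / diff(anchors[1:2])
      nk <- length(anchors)
      grad_hi <- diff(anchor_vals[(nk - 1L):nk]) / diff(anchors[(nk - 1L):nk])
    }
    inner <- stats::approx(anchors, anchor_vals, xout = x$grid, rule = 2)$y
    # extend the end segments linearly beyond the outer anchors
    lo <- x$grid < anchors[1L]
    hi <- x$grid > anchors[length(anchors)]
    inner[lo] <- anchor_vals[1L] + grad_lo * (x$grid[lo] - anchors[1L])
    inner[hi] <- anchor_vals[length(anchors)] +
      grad_hi * (x$grid[hi] - anchors[length(anchors)])
    inner
  } else {
    stats::splinefun(anchors, anchor_vals, method = "natural")(x$grid)
  }
  out <- ir_spectrum(x$grid, x$values - base, meta = x$meta)
  add_history(out, paste0("baseline:", mode))
}

#' Normalize to the phosphate band
#'
#' Divides the whole spectrum by its maximum inside the normalization
#' window, so that window maximum becomes exactly 1. The default window
#' 1050-1110 cm^-1 is centered on the symmetric phosphate stretching band
#' at ~1080 cm^-1, which is present at fixed stoichiometry in every DNA
#' sample and therefore serves as an internal concentration standard. The
#' operation is scale-invariant and idempotent.
#'
#' @param x An [ir_spectrum()].
#' @param window Normalization window `c(lo, hi)` (cm^-1) inside the grid
#'   span.
#' @return The normalized [ir_spectrum()].
#' @export
normalize_phosphate <- function(x, window = c(1050, 1110)) {
  stopifnot(is_ir_spectrum(x))
  idx <- window_idx(x, window)
  m <- max(x$values[idx])
  if (m <= 0) {
    stop("window maximum is ", signif(m, 3),
         " (<= 0): no phosphate band found; baseline-correct first or check the window")
  }
  out <- ir_spectrum(x$grid, x$values / m, meta = x$meta)
  add_history(out, "normalize_phosphate")
}

#' Pointwise mean and SD of replicate spectra
#'
#' @param spectra List of [ir_spectrum()]s on a common grid (use
#'   [resample()] first otherwise).
#' @return A list with elements `mean` and `sd`, both [ir_spectrum()]s; the
#'   SD is the pointwise sample standard deviation and `mean$meta$n` records
#'   the number of replicates.
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop("empty list of spectra")
  stopifnot(all(vapply(spectra, is_ir_spectrum, logical(1))))
  stopifnot_common_grid(spectra, "replicate spectra")
  vals <- do.call(cbind, lapply(spectra, `[[`, "values"))
  n <- ncol(vals)
  mean_v <- rowMeans(vals)
  sd_v <- if (n > 1L) apply(vals, 1L, stats::sd) else rep(0, nrow(vals))
  meta <- spectra[[1L]]$meta
  meta$n <- n
  list(mean = add_history(ir_spectrum(spectra[[1L]]$grid, mean_v, meta), "average"),
       sd = ir_spectrum(spectra[[1L]]$grid, sd_v, meta))
}

#' Standard preprocessing pipeline
#'
#' Baseline-corrects then phosphate-normalizes a spectrum, the preparation
#' every spectrum receives before isotope-edited subtraction.
#'
#' @inheritParams baseline_correct
#' @param norm_window Passed to [normalize_phosphate()].
#' @return The preprocessed [ir_spectrum()].
#' @export
preprocess <- function(x, anchors = c(1000, 1350, 1550, 1790),
                       mode = c("linear", "spline"),
                       norm_window = c(1050, 1110)) {
  normalize_phosphate(baseline_correct(x, anchors, mode), norm_window)
}
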