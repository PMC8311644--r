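#' Construct an IR spectrum
#'
#' An `ir_spectrum` is the basic container of the package: a strictly
#' increasing wavenumber grid (cm^-1), one absorbance value per grid point,
#' and a metadata list carrying provenance (template name, light/heavy label
#' state, replicate index, processing history).
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param values Numeric vector of absorbances, same length as `grid`, all
#'   finite.
#' @param meta Named list of provenance fields. Free-form; the generator and
#'   processing functions use `template`, `label_state`, `replicate`, and
#'   `history`.
#' @return An object of class `ir_spectrum`.
#' @examples
#' s <- ir_spectrum(seq(1000, 1800, 1), rep(0, 801))
#' s
#' @export
ir_spectrum <- function(grid, values, meta = list()) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values)) {
    stop("`grid` and `values` must have the same length (got ",
         length(grid), " and ", length(values), ")")
  }
  if (length(grid) < 2L) stop("a spectrum needs at least 2 grid points")
  if (anyNA(grid) || any(!is.finite(grid))) stop("`grid` contains non-finite wavenumbers")
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values))) stop("`values` contains non-finite absorbances")
  structure(list(grid = grid, values = values, meta = meta),
            class = "ir_spectrum")
}

is_ir_spectrum <- function(x) inherits(x, "ir_spectrum")

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.0f-%.0f cm-1\n",
              length(x$grid), min(x$grid), max(x$grid)))
  if (!is.null(x$meta$template)) cat("  template:   ", x$meta$template, "\n")
  if (!is.null(x$meta$label_state)) cat("  label state:", x$meta$label_state, "\n")
  if (!is.null(x$meta$replicate)) cat("  replicate:  ", x$meta$replicate, "\n")
  if (length(x$meta$history)) {
    cat("  history:    ", paste(unlist(x$meta$history), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$grid, absorbance = x$values)
}

#' @export
plot.ir_spectrum <- function(x, ..., xlab = expression(wavenumber ~ (cm^-1)),
                             ylab = "absorbance", type = "l") {
  graphics::plot(x$grid, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# check that two spectra share a grid (exact up to numerical noise)
same_grid <- function(a, b, tol = 1e-8) {
  length(a$grid) == length(b$grid) && max(abs(a$grid - b$grid)) <= tol
}

stopifnot_common_grid <- function(spectra, what = "spectra") {
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!same_grid(ref, s)) {
      stop(what, " are not on a common grid; resample() them onto one grid first")
    }
  }
  invisible(ref$grid)
}

# append one step to the processing history
add_history <- function(x, step) {
  x$meta$history <- c(x$meta$history, step)
  x
}

# indices of grid points inside a closed window c(lo, hi)
window_idx <- function(x, window) {
  if (length(window) != 2L || !is.numeric(window) || diff(window) <= 0) {
    stop("`window` must be c(lo, hi) with lo < hi")
  }
  idx <- which(x$grid >= window[1L] & x$grid <= window[2L])
  if (!length(idx)) stop("window [", window[1L], ", ", window[2L],
                         "] contains no grid points")
  idx
}
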