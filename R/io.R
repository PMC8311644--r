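#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV dialect: comma separator, dot decimal, one header line, columns
#' `wavenumber_cm-1,absorbance`. JCAMP-DX support covers single-block files
#' with `##XYDATA=(X++(Y..Y))` in AFFN form or with SQZ/DIF/DUP
#' compression; `##XFACTOR`/`##YFACTOR` are honored. Multi-block
#' (`##BLOCKS`) files are rejected.
#'
#' Wavenumbers are returned sorted ascending; descending input is re-ordered
#' (with a message). Duplicate wavenumbers and non-finite absorbances are
#' errors.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.jdx`, `.dx`, `.jcamp` are
#'   JCAMP-DX, everything else CSV), `"csv"`, or `"jcamp"`.
#' @return An [ir_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  xy <- switch(format, csv = read_csv_xy(path), jcamp = read_jcamp_xy(path))
  grid <- xy$x
  values <- xy$y
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop("non-finite absorbance in ", path, " (data row ", bad[1L], ")")
  }
  if (anyNA(grid) || any(!is.finite(grid))) stop("non-numeric wavenumbers in ", path)
  if (is.unsorted(grid)) {
    if (!is.unsorted(rev(grid))) {
      message("wavenumbers in ", path, " are descending; re-ordering ascending")
    }
    o <- order(grid)
    grid <- grid[o]
    values <- values[o]
  }
  if (any(diff(grid) == 0)) stop("duplicate wavenumbers in ", path)
  ir_spectrum(grid, values,
              meta = list(source = path, format = format,
                          history = list(paste0("read:", format))))
}

read_csv_xy <- function(path) {
  df <- tryCatch(utils::read.csv(path, header = TRUE),
                 error = function(e) stop("cannot parse CSV ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed CSV: ", path)
  x <- suppressWarnings(as.numeric(df[[1L]]))
  y <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(x)) stop("non-numeric wavenumber in ", path,
                     " (data row ", which(is.na(x))[1L], ")")
  if (anyNA(y)) stop("non-numeric/NaN absorbance in ", path,
                     " (data row ", which(is.na(y))[1L], ")")
  list(x = x, y = y)
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' CSV is written with the dialect described in [read_spectrum()] at 8
#' significant digits, so write-then-read round trips are exact to well
#' beyond 6 significant digits. JCAMP-DX is written as a single block with
#' AFFN `(X++(Y..Y))` data and unit X/Y factors.
#'
#' @param x An [ir_spectrum()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"`, or `"jcamp"` (as in [read_spectrum()]).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, format = c("auto", "csv", "jcamp")) {
  stopifnot(is_ir_spectrum(x))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  switch(format,
         csv = {
           lines <- c("wavenumber_cm-1,absorbance",
                      sprintf("%.8g,%.8g", x$grid, x$values))
           writeLines(lines, path)
         },
         jcamp = write_jcamp_xy(x, path))
  invisible(path)
}

write_jcamp_xy <- function(x, path) {
  n <- length(x$grid)
  header <- c(
    paste0("##TITLE=", if (is.null(x$meta$template)) "spectrum" else x$meta$template),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    sprintf("##FIRSTX=%.8g", x$grid[1L]),
    sprintf("##LASTX=%.8g", x$grid[n]),
    sprintf("##NPOINTS=%d", n),
    "##XFACTOR=1",
    "##YFACTOR=1",
    "##XYDATA=(X++(Y..Y))"
  )
  per_line <- 6L
  starts <- seq(1L, n, by = per_line)
  body <- vapply(starts, function(i) {
    j <- min(i + per_line - 1L, n)
    paste(c(sprintf("%.8g", x$grid[i]), sprintf("%.8g", x$values[i:j])),
          collapse = " ")
  }, character(1))
  writeLines(c(header, body, "##END="), path)
}

# ---- JCAMP-DX subset reader ------------------------------------------------

jcamp_token_value <- function(tok) {
  # returns list(kind, value) where kind in affn/sqz/dif/dup
  c1 <- substr(tok, 1L, 1L)
  rest <- substr(tok, 2L, nchar(tok))
  sqz <- c("@" = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7, H = 8, I = 9,
           a = -1, b = -2, c = -3, d = -4, e = -5, f = -6, g = -7, h = -8, i = -9)
  dif <- c("%" = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7, Q = 8, R = 9,
           j = -1, k = -2, l = -3, m = -4, n = -5, o = -6, p = -7, q = -8, r = -9)
  dup <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)
  digit_val <- function(map) {
    lead <- map[[c1]]
    mag <- paste0(abs(lead), rest)
    sign(lead + 0.5) * as.numeric(mag)  # sign of lead; lead 0 -> positive
  }
  if (grepl("^[+-]?[0-9.]", tok)) {
    list(kind = "affn", value = as.numeric(tok))
  } else if (c1 %in% names(sqz)) {
    list(kind = "sqz", value = digit_val(sqz))
  } else if (c1 %in% names(dif)) {
    list(kind = "dif", value = digit_val(dif))
  } else if (c1 %in% names(dup)) {
    list(kind = "dup", value = as.numeric(paste0(dup[[c1]], rest)))
  } else {
    stop("unrecognized JCAMP token: ", tok)
  }
}

read_jcamp_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  is_ldr <- grepl("^##", lines)
  ldr_key <- toupper(gsub("[ _-]", "", sub("^##([^=]*)=.*$", "\\1", lines[is_ldr])))
  ldr_val <- sub("^##[^=]*=", "", lines[is_ldr])
  get_ldr <- function(key, default = NA) {
    hit <- which(ldr_key == key)
    if (length(hit)) trimws(ldr_val[hit[1L]]) else default
  }
  if (!is.na(get_ldr("BLOCKS"))) {
    stop("multi-block JCAMP-DX files are not supported: ", path)
  }
  xf <- as.numeric(get_ldr("XFACTOR", "1"))
  yf <- as.numeric(get_ldr("YFACTOR", "1"))
  xy_at <- which(ldr_key == "XYDATA")
  if (!length(xy_at)) stop("no ##XYDATA block in ", path)
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", ldr_val[xy_at[1L]])) {
    stop("only (X++(Y..Y)) XYDATA is supported: ", path)
  }
  start_line <- which(is_ldr)[xy_at[1L]]
  end_line <- which(ldr_key == "END")
  end_line <- if (length(end_line)) which(is_ldr)[end_line[1L]] else length(lines) + 1L
  data_lines <- lines[seq(start_line + 1L, end_line - 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) stop("empty XYDATA block in ", path)

  tok_re <- "([+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?)|([@A-Za-z%][0-9]*(\\.[0-9]+)?)"
  xs <- numeric(0)
  ys <- numeric(0)
  last_dif <- FALSE  # previous line ended with a DIF/DUP-of-DIF token
  for (line in data_lines) {
    m <- gregexpr(tok_re, line)[[1L]]
    toks <- regmatches(line, list(m))[[1L]]
    if (length(toks) < 2L) stop("malformed XYDATA line: ", line)
    x0 <- jcamp_token_value(toks[1L])
    if (x0$kind == "dif") stop("X value in DIF form is not valid: ", line)
    line_y <- numeric(0)
    prev_kind <- NA_character_
    prev_dif <- NA_real_
    for (tok in toks[-1L]) {
      t <- jcamp_token_value(tok)
      if (t$kind == "dup") {
        if (is.na(prev_kind)) stop("DUP token with no preceding Y: ", line)
        reps <- t$value - 1L
        if (reps < 0) stop("invalid DUP count in: ", line)
        for (r in seq_len(reps)) {
          line_y <- c(line_y, if (prev_kind == "dif") {
            line_y[length(line_y)] + prev_dif
          } else {
            line_y[length(line_y)]
          })
        }
      } else if (t$kind == "dif") {
        base <- if (length(line_y)) line_y[length(line_y)] else {
          if (!length(ys)) stop("DIF token with no previous ordinate: ", line)
          ys[length(ys)]
        }
        line_y <- c(line_y, base + t$value)
        prev_kind <- "dif"
        prev_dif <- t$value
      } else {
        line_y <- c(line_y, t$value)
        prev_kind <- t$kind
      }
    }
    if (last_dif && length(ys)) {
      # in DIF mode the first ordinate of a line is a check value duplicating
      # the last ordinate of the previous line
      if (length(line_y)) line_y <- line_y[-1L]
    }
    ys <- c(ys, line_y)
    last_tok <- jcamp_token_value(toks[length(toks)])
    last_dif <- last_tok$kind %in% c("dif") ||
      (last_tok$kind == "dup" && identical(prev_kind, "dif"))
    xs <- c(xs, x0$value)
  }
  npoints <- as.numeric(get_ldr("NPOINTS", NA))
  if (!is.na(npoints) && length(ys) != npoints) {
    stop("JCAMP NPOINTS mismatch in ", path, ": header says ", npoints,
         ", decoded ", length(ys))
  }
  firstx <- as.numeric(get_ldr("FIRSTX", NA))
  lastx <- as.numeric(get_ldr("LASTX", NA))
  if (is.na(firstx) || is.na(lastx) || length(ys) < 2L) {
    stop("JCAMP file lacks FIRSTX/LASTX; cannot reconstruct the grid: ", path)
  }
  x <- seq(firstx, lastx, length.out = length(ys))
  list(x = x, y = ys * yf)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto `grid`, which must lie within the source span
#' (no extrapolation).
#'
#' @param x An [ir_spectrum()].
#' @param grid Target wavenumber grid, strictly increasing.
#' @return An [ir_spectrum()] on `grid`.
#' @examples
#' s <- generate_spectrum(make_template("TA_WC"), "light", noise_model(sigma = 0), 1)
#' s4 <- resample(s, seq(1000, 1800, 4))
#' @export
resample <- function(x, grid) {
  stopifnot(is_ir_spectrum(x))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target `grid` must be strictly increasing")
  if (min(grid) < min(x$grid) || max(grid) > max(x$grid)) {
    stop("target grid [", min(grid), ", ", max(grid),
         "] extends outside the source span [", min(x$grid), ", ", max(x$grid),
         "]; resample() does not extrapolate")
  }
  values <- stats::approx(x$grid, x$values, xout = grid, method = "linear")$y
  out <- ir_spectrum(grid, values, meta = x$meta)
  add_history(out, "resample")
}
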