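test_that("find_peaks returns nothing on flat input and signed peaks on bands", {
  grid <- seq(1600, 1780, 1)
  flat <- ir_spectrum(grid, rep(0.1, length(grid)))
  expect_identical(nrow(find_peaks(flat, c(1600, 1780))), 0L)

  d <- preprocessed_difference(make_template("TA_WC"), noise_free())
  pk <- find_peaks(d, c(1650, 1780))
  expect_gte(nrow(pk), 2)
  top_pos <- pk[pk$sign > 0, ][1, ]
  top_neg <- pk[pk$sign < 0, ][1, ]
  expect_lt(abs(top_pos$center - 1720), 3)
  expect_lt(abs(top_neg$center - 1700), 3)
})

test_that("the drug-bound duplex difference peaks at the red-shifted 1710", {
  d <- preprocessed_difference(make_template("TA_ECHINOMYCIN_HG"), noise_free())
  pk <- find_peaks(d, c(1700, 1780))
  expect_lt(abs(pk[pk$sign > 0, ]$center[1] - 1710), 3)
})

test_that("a single noise-free Gaussian is recovered to 0.1 cm-1 and 1%", {
  grid <- seq(1600, 1780, 1)
  s <- ir_spectrum(grid, oracle_gauss(grid, 1700, 25, 1))
  fit <- fit_bands(s, c(1600, 1780), k_max = 3)
  expect_identical(nrow(fit$components), 1L)
  expect_lt(abs(fit$components$center - 1700), 0.1)
  expect_lt(abs(fit$components$fwhm - 25), 0.25)
  expect_lt(abs(fit$components$amplitude - 1), 0.01)
})

test_that("two overlapping Gaussians select k = 2 with centers within 1 cm-1", {
  grid <- seq(1600, 1780, 1)
  truth <- oracle_gauss(grid, 1690, 20, 1) + oracle_gauss(grid, 1655, 20, 0.6)
  s <- ir_spectrum(grid, truth)
  fit <- fit_bands(s, c(1600, 1780), k_max = 4)
  expect_identical(nrow(fit$components), 2L)
  expect_lt(max(abs(sort(fit$components$center) - c(1655, 1690))), 1)

  # a nested k = 1 fit must leave a larger residual
  fit1 <- fit_bands(s, c(1600, 1780), k_max = 1)
  expect_identical(nrow(fit1$components), 1L)
  expect_gt(fit1$residual_rms, fit$residual_rms)
})

test_that("pseudo-Voigt fitting recovers a pseudo-Voigt band", {
  grid <- seq(1600, 1780, 1)
  pv <- 0.4 / (1 + 4 * ((grid - 1700) / 25)^2) +
    0.6 * exp(-4 * log(2) * ((grid - 1700) / 25)^2)
  s <- ir_spectrum(grid, pv)
  fit <- fit_bands(s, c(1600, 1780), k_max = 2, profile = "pseudo_voigt",
                   eta = 0.4)
  expect_lt(abs(fit$components$center[1] - 1700), 0.1)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("isotope shift is recovered exactly on noise-free differences", {
  d <- preprocessed_difference(make_template("TA_WC"), noise_free())
  expect_equal(isotope_shift_estimate(d), 20, tolerance = 0.1)

  tpl <- make_template("TA_WC")
  pairs <- difference_components(tpl)
  pairs <- pairs[pairs$amplitude > 0 & pairs$center >= 1600, ]
  pf <- fit_isotope_pairs(d, pairs)
  expect_equal(pf$shift, 20, tolerance = 1e-3)
  expect_lt(pf$residual_rms, 1e-6)
})

test_that("a shift-free template yields no negative peak and errors", {
  tpl <- make_template("TA_WC")
  tpl0 <- duplex_template("unshifted", tpl$bands, tpl$n_labels,
                          isotope_shift = 0)
  d <- preprocessed_difference(tpl0, noise_free())
  expect_error(isotope_shift_estimate(d), "no isotope-edited band pair")
})

test_that("noise-free split and Hoogsteen marker calls match every preset", {
  expected_split <- c(TA_WC = FALSE, AT_WC = TRUE, TA_ECHINOMYCIN_HG = TRUE,
                      AT_ECHINOMYCIN_WC = FALSE, A6_WC = FALSE, M1A_A6_HG = TRUE)
  expected_marker <- c(TA_WC = FALSE, AT_WC = FALSE, TA_ECHINOMYCIN_HG = TRUE,
                       AT_ECHINOMYCIN_WC = FALSE, A6_WC = FALSE, M1A_A6_HG = TRUE)
  for (p in all_presets) {
    tpl <- make_template(p)
    d <- preprocessed_difference(tpl, noise_free())
    res <- analyze_difference(d, template = tpl)
    expect_identical(res$split$is_split, unname(expected_split[p]), info = p)
    expect_identical(res$split$hoogsteen_marker, unname(expected_marker[p]),
                     info = p)
    expect_equal(res$isotope_shift, 20, tolerance = 0.1, info = p)
  }
})

test_that("fitted centers match template centers within 1 cm-1, all presets", {
  for (p in all_presets) {
    tpl <- make_template(p)
    d <- preprocessed_difference(tpl, noise_free())
    res <- analyze_difference(d, template = tpl)
    truth <- difference_components(tpl)
    truth <- truth[truth$center >= 1600 & truth$center <= 1780, ]
    got <- sort(res$fit$components$center)
    expect_equal(length(got), nrow(truth), info = p)
    expect_lt(max(abs(got - sort(truth$center))), 1)
  }
})

test_that("a split call requires separation and a countable weak component", {
  # same-sign pair 6 cm-1 apart: below the 10 cm-1 separation floor
  grid <- seq(1600, 1780, 1)
  close_pair <- ir_spectrum(grid, oracle_gauss(grid, 1668, 20, 1) +
                              oracle_gauss(grid, 1674, 20, 0.8))
  fit <- fit_bands(close_pair, c(1600, 1780), k_max = 2)
  expect_false(detect_splitting(fit)$is_split)

  # an 18% shoulder falls under the 20% amplitude floor
  faint <- ir_spectrum(grid, oracle_gauss(grid, 1665, 20, 1) +
                         oracle_gauss(grid, 1690, 20, 0.18))
  ffit <- fit_bands(faint, c(1600, 1780), k_max = 2,
                    init = data.frame(center = c(1665, 1690), fwhm = 20,
                                      amplitude = c(1, 0.18)))
  expect_false(detect_splitting(ffit)$is_split)
  expect_true(detect_splitting(ffit, min_amp_fraction = 0.15)$is_split)
})

test_that("detect_splitting demands a fit covering the minor region", {
  d <- preprocessed_difference(make_template("TA_WC"), noise_free())
  fit <- fit_bands(d, c(1690, 1760), k_max = 2)
  expect_error(detect_splitting(fit), "minor region")
})

test_that("center recovery degrades monotonically with noise", {
  tpl <- make_template("TA_WC")
  err_at <- function(sigma) {
    errs <- vapply(1:5, function(seed) {
      nm <- noise_model(sigma = sigma, jitter_sd = 0, seed = seed)
      d <- preprocessed_difference(tpl, nm)
      res <- analyze_difference(d, template = tpl)
      comp <- res$fit$components
      abs(comp$center[which.max(comp$amplitude)] - 1720)
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lte(err_at(0), err_at(0.03))
  expect_lte(err_at(0.03), err_at(0.12) + 0.05)
})

test_that("fit windows without data and degenerate k are rejected", {
  d <- preprocessed_difference(make_template("TA_WC"), noise_free())
  expect_error(fit_bands(d, c(2000, 2100)), "no grid points")
  expect_error(fit_bands(d, c(1600, 1780), k_max = 0), "k_max")
})
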