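test_that("presets encode the expected band structure", {
  expected <- list(
    TA_WC = list(major = 1720, minor = c(1670), n_labels = 2),
    AT_WC = list(major = 1720, minor = c(1665, 1690), n_labels = 2),
    TA_ECHINOMYCIN_HG = list(major = 1710, minor = c(1655, 1690), n_labels = 2),
    AT_ECHINOMYCIN_WC = list(major = 1710, minor = c(1665), n_labels = 2),
    A6_WC = list(major = 1720, minor = c(1670), n_labels = 1),
    M1A_A6_HG = list(major = 1720, minor = c(1655, 1680), n_labels = 1)
  )
  for (name in names(expected)) {
    tpl <- make_template(name)
    exp <- expected[[name]]
    expect_identical(tpl$n_labels, as.integer(exp$n_labels), info = name)
    expect_equal(tpl$isotope_shift, 20, info = name)
    centers <- vapply(tpl$bands, `[[`, numeric(1), "center")
    labeled <- vapply(tpl$bands, `[[`, logical(1), "labeled")
    amps <- vapply(tpl$bands, `[[`, numeric(1), "amplitude")
    # phosphate band present, unlabeled
    expect_true(any(centers == 1080 & !labeled), info = name)
    # labeled major at the expected position
    major_idx <- which(labeled & amps == max(amps[labeled]))
    expect_equal(centers[major_idx], exp$major, info = name)
    # minor region composition and quarter-amplitude total
    minor_idx <- which(labeled & centers >= 1630 & centers <= 1700)
    expect_equal(sort(centers[minor_idx]), exp$minor, info = name)
    expect_equal(sum(amps[minor_idx]), 0.25 * amps[major_idx], info = name)
    # every labeled band scales with the label count
    expect_true(all(vapply(tpl$bands[labeled], `[[`, logical(1), "per_label")),
                info = name)
  }
})

test_that("the broad TA minor band has the reported 30 cm-1 width", {
  tpl <- make_template("TA_WC")
  minor <- Filter(function(b) b$center == 1670, tpl$bands)[[1]]
  expect_equal(minor$fwhm, 30)
})

test_that("unknown preset names fail with the list of valid names", {
  expect_error(make_template("TA_HOOGSTEEN"), "valid presets.*TA_WC")
})

test_that("noise-free generation equals the analytic band sum everywhere", {
  for (name in c("TA_WC", "TA_ECHINOMYCIN_HG", "M1A_A6_HG")) {
    tpl <- make_template(name)
    for (state in c("light", "heavy")) {
      s <- generate_spectrum(tpl, state, noise_free(), 1)
      expect_equal(s$values, oracle_template_sum(tpl, s$grid, state),
                   tolerance = 1e-12, info = paste(name, state))
    }
  }
})

test_that("baseline drift adds the stated polynomial", {
  tpl <- make_template("TA_WC")
  nm <- noise_model(sigma = 0, drift_coeffs = c(0.1, -0.04, 0.02), jitter_sd = 0)
  s <- generate_spectrum(tpl, "light", nm, 1)
  t <- (s$grid - min(s$grid)) / diff(range(s$grid))
  drift <- 0.1 - 0.04 * t + 0.02 * t^2
  expect_equal(s$values - oracle_template_sum(tpl, s$grid, "light"), drift,
               tolerance = 1e-12)
})

test_that("heavy variant moves exactly the labeled bands", {
  tpl <- make_template("AT_WC")
  light <- generate_spectrum(tpl, "light", noise_free(), 1)
  heavy <- generate_spectrum(tpl, "heavy", noise_free(), 1)
  # heavy equals a hand-shifted light band sum
  shifted <- duplex_template(tpl$name, lapply(tpl$bands, function(b) {
    if (b$labeled) b$center <- b$center - tpl$isotope_shift
    b
  }), n_labels = tpl$n_labels, isotope_shift = 0)
  expect_equal(heavy$values, oracle_template_sum(shifted, heavy$grid, "light"),
               tolerance = 1e-12)
  # shift zero collapses light and heavy
  tpl0 <- duplex_template("no_shift", tpl$bands, tpl$n_labels, isotope_shift = 0)
  l0 <- generate_spectrum(tpl0, "light", noise_free(), 1)
  h0 <- generate_spectrum(tpl0, "heavy", noise_free(), 1)
  expect_identical(l0$values, h0$values)
})

test_that("per-label amplitudes scale with the label count, others do not", {
  bands <- list(band_spec(1080, 35, 2.0),
                band_spec(1720, 25, 1.0, labeled = TRUE, per_label = TRUE))
  one <- duplex_template("one", bands, n_labels = 1)
  two <- duplex_template("two", bands, n_labels = 2)
  s1 <- generate_spectrum(one, "light", noise_free(), 1)
  s2 <- generate_spectrum(two, "light", noise_free(), 1)
  major1 <- oracle_gauss(s1$grid, 1720, 25, 1)
  expect_equal(s2$values - s1$values, major1, tolerance = 1e-12)
})

test_that("generation is deterministic in (seed, replicate, label state)", {
  tpl <- make_template("TA_WC")
  nm <- noise_model(sigma = 0.01, jitter_sd = 0.5, seed = 11)
  a <- generate_spectrum(tpl, "light", nm, 2)
  b <- generate_spectrum(tpl, "light", nm, 2)
  expect_identical(a$values, b$values)
  expect_false(identical(generate_spectrum(tpl, "heavy", nm, 2)$values, a$values))
  expect_false(identical(generate_spectrum(tpl, "light", nm, 3)$values, a$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(42)
  first <- runif(1)
  set.seed(42)
  invisible(generate_spectrum(make_template("TA_WC"), "light",
                              noise_model(sigma = 0.01, seed = 5), 1))
  expect_identical(runif(1), first)
})

test_that("replicate sets are reproducible, distinct, and validated", {
  tpl <- make_template("A6_WC")
  nm <- noise_model(sigma = 0.01, jitter_sd = 0.2, seed = 3)
  r1 <- generate_replicates(tpl, nm, 3)
  r2 <- generate_replicates(tpl, nm, 3)
  expect_identical(r1$light[[2]]$values, r2$light[[2]]$values)
  expect_false(identical(r1$light[[1]]$values, r1$light[[2]]$values))
  # zero-noise replicates are all identical
  r0 <- generate_replicates(tpl, noise_free(), 4)
  for (k in 2:4) expect_identical(r0$light[[k]]$values, r0$light[[1]]$values)
  expect_error(generate_replicates(tpl, nm, 1), ">= 2")
})

test_that("a grid that misses band centers is rejected", {
  expect_error(
    generate_spectrum(make_template("TA_WC"), "light", noise_free(), 1,
                      grid = seq(1500, 1800, 1)),
    "does not cover"
  )
})

test_that("pseudo-Voigt profile matches its closed form", {
  tpl <- duplex_template("pv", list(band_spec(1400, 30, 1.0)), n_labels = 1)
  s <- generate_spectrum(tpl, "light", noise_free(), 1,
                         profile = "pseudo_voigt", eta = 0.3)
  x <- s$grid
  lor <- 1 / (1 + 4 * ((x - 1400) / 30)^2)
  gau <- exp(-4 * log(2) * ((x - 1400) / 30)^2)
  expect_equal(s$values, 0.3 * lor + 0.7 * gau, tolerance = 1e-12)
})

test_that("band and template invariants are enforced", {
  expect_error(band_spec(1700, -5, 1), "fwhm")
  expect_error(band_spec(1700, 25, 0), "amplitude")
  expect_error(duplex_template("x", list(band_spec(1700, 25, 1)), n_labels = 3),
               "n_labels")
  expect_error(noise_model(sigma = -1), "sigma")
})

test_that("difference_components pairs every labeled band with a shifted twin", {
  tpl <- make_template("TA_ECHINOMYCIN_HG")
  dc <- difference_components(tpl)
  pos <- dc[dc$amplitude > 0, ]
  neg <- dc[dc$amplitude < 0, ]
  expect_equal(sort(pos$center - 20), sort(neg$center))
  expect_equal(sum(dc$amplitude), 0)
  # amplitudes on the phosphate-normalized scale: major 2 labels / phosphate 2
  expect_equal(max(pos$amplitude), 1.0)
})
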