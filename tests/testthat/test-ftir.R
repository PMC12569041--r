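test_that("regridding is exact for shared grids and linear signals", {
  s <- gen_spectrum(data.frame(center = 1650, amplitude = 1, fwhm = 20),
                    grid = c(1600, 1700, 2))
  expect_equal(regrid(s, s$wavenumber)$absorbance, s$absorbance)
  ramp <- as_spectrum(seq(1000, 1100, 2), 0.01 * seq(1000, 1100, 2) - 3)
  fine <- seq(1010, 1090, 1)
  expect_equal(regrid(ramp, fine)$absorbance, 0.01 * fine - 3, tolerance = 1e-12)
  expect_error(regrid(ramp, seq(900, 1000, 2)), "extrapolation")
})

test_that("scale correction recovers the closed-form least-squares factor", {
  ref <- gen_spectrum(data.frame(center = 1750, amplitude = 1, fwhm = 30),
                      grid = c(1600, 1900, 2))
  doubled <- as_spectrum(ref$wavenumber, 2 * ref$absorbance)
  out <- correct_spectrum(doubled, scale_to = ref, scale_window = c(1700, 1800))
  expect_equal(attr(out, "corrections")$scale_factor, 0.5, tolerance = 1e-9)
  expect_equal(out$absorbance, ref$absorbance, tolerance = 1e-9)
})

test_that("vapor subtraction recovers the mixing coefficient and removes the lines", {
  grid <- c(1600, 2000, 2)
  vapor <- gen_spectrum(
    data.frame(center = c(1716, 1752, 1790, 1846, 1870),
               amplitude = c(1, 0.8, 1.2, 0.9, 1.1), fwhm = 4),
    grid = grid
  )
  protein <- gen_spectrum(data.frame(center = 1656, amplitude = 1, fwhm = 40),
                          grid = grid)
  contaminated <- as_spectrum(protein$wavenumber,
                              protein$absorbance + 0.3 * vapor$absorbance)
  out <- correct_spectrum(contaminated, subtract_ref = vapor,
                          fit_window = c(1700, 1900))
  expect_equal(attr(out, "corrections")$subtract_alpha, 0.3, tolerance = 0.01)
  residual <- out$absorbance - protein$absorbance
  in_window <- out$wavenumber >= 1700 & out$wavenumber <= 1900
  expect_lt(max(abs(residual[in_window])), 0.01 * 0.3 * 1.2)
})

test_that("correction with no options is the identity map", {
  s <- gen_spectrum(data.frame(center = 1650, amplitude = 1, fwhm = 20),
                    grid = c(1600, 1700, 2))
  out <- correct_spectrum(s)
  expect_equal(out$absorbance, s$absorbance)
  expect_length(attr(out, "corrections"), 0L)
})

test_that("difference spectra are pointwise and antisymmetric", {
  tabs <- ftir_band_tables()
  a <- gen_spectrum(tabs$nalfurafine, label = "nalfurafine-bound")
  i <- gen_spectrum(tabs$naltrexone, label = "naltrexone-bound")
  d_ai <- difference_spectrum(a, i)
  d_ia <- difference_spectrum(i, a)
  expect_equal(d_ai$delta, -d_ia$delta)
  expect_equal(difference_spectrum(a, a)$delta, rep(0, nrow(a)))
  expect_equal(attr(d_ai, "inactive_label"), "naltrexone-bound")
  short <- as_spectrum(seq(1600, 1700, 2), rnorm(51))
  expect_error(difference_spectrum(a, short), "grids")
})

test_that("amide-I exchange from antagonist to agonists shows the expected lobes", {
  tabs <- ftir_band_tables()
  inact <- gen_spectrum(tabs$naltrexone, label = "naltrexone-bound")
  act <- gen_spectrum(tabs$nalfurafine, label = "nalfurafine-bound")
  d <- difference_spectrum(act, inact)
  w <- diagnostic_windows()
  pos <- find_band(d, w$amide_I, "positive")
  neg <- find_band(d, w$amide_I, "negative")
  expect_true(pos$found && neg$found)
  expect_equal(pos$position, 1666, tolerance = 1)
  expect_equal(neg$position, 1651, tolerance = 1)
  expect_equal(band_shift(neg, pos), 15, tolerance = 1)
})

test_that("band location achieves sub-grid accuracy against a dense-grid oracle", {
  # off-grid centers, FWHM >= 8, 2 cm-1 acquisition grid
  for (center in c(2553.7, 2561.1, 2568.4)) {
    coarse <- gen_spectrum(data.frame(center = center, amplitude = 1, fwhm = 9),
                           grid = c(2500, 2600, 2))
    dense <- gen_spectrum(data.frame(center = center, amplitude = 1, fwhm = 9),
                          grid = c(2500, 2600, 0.01))
    oracle <- dense$wavenumber[which.max(dense$absorbance)]
    got <- find_band(coarse, c(2500, 2600), "positive")
    expect_equal(got$position, oracle, tolerance = 0.5)
  }
})

test_that("spikes, flat windows and absent peaks are handled explicitly", {
  wn <- seq(1100, 1200, 2)
  y <- rep(0, length(wn)); y[wn == 1130] <- 1
  spike <- structure(data.frame(wavenumber = wn, delta = y),
                     class = c("difference_spectrum", "data.frame"))
  p <- find_band(spike, c(1100, 1200), "positive")
  expect_equal(p$position, 1130)
  flat <- structure(data.frame(wavenumber = wn, delta = rep(0.1, length(wn))),
                    class = c("difference_spectrum", "data.frame"))
  expect_false(find_band(flat, c(1100, 1200), "positive")$found)
  # all-positive signal has no negative extremum to report
  expect_false(find_band(spike, c(1100, 1200), "negative")$found)
  expect_error(band_shift(find_band(flat, c(1100, 1200), "positive"), p),
               "not found")
})

test_that("generator-to-peak pipeline recovers band centers within 1 cm-1", {
  # separations >= 1.5 x FWHM
  cases <- list(c(1651, 1666), c(2550, 2570), c(1640, 1655))
  for (cs in cases) {
    inact <- gen_spectrum(data.frame(center = cs[1], amplitude = 0.02, fwhm = 10),
                          grid = c(min(cs) - 60, max(cs) + 60, 2))
    act <- gen_spectrum(data.frame(center = cs[2], amplitude = 0.02, fwhm = 10),
                        grid = c(min(cs) - 60, max(cs) + 60, 2))
    d <- difference_spectrum(act, inact)
    win <- c(min(cs) - 30, max(cs) + 30)
    expect_equal(find_band(d, win, "positive")$position, cs[2], tolerance = 1)
    expect_equal(find_band(d, win, "negative")$position, cs[1], tolerance = 1)
  }
})

test_that("spectra survive a write/read round trip", {
  s <- gen_spectrum(data.frame(center = 1651, amplitude = 0.5, fwhm = 12),
                    grid = c(1600, 1700, 2), label = "naltrexone-bound")
  f <- tempfile(fileext = ".csv")
  write_spectrum(s, f)
  back <- read_spectrum(f, label = "naltrexone-bound")
  expect_equal(back$wavenumber, s$wavenumber)
  expect_equal(back$absorbance, s$absorbance, tolerance = 1e-12)
})
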