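#' Spectrum container
#'
#' A `spectrum` is a data frame with `wavenumber` (cm-1, strictly
#' ascending, uniform step) and `absorbance`, plus a `label` attribute
#' naming the state (e.g. `"naltrexone-bound"`).
#'
#' @param wavenumber ascending uniform grid in cm-1.
#' @param absorbance one value per grid point.
#' @param label state tag.
#' @return a `spectrum` object.
#' @export
as_spectrum <- function(wavenumber, absorbance, label = "") {
  assert_that(length(wavenumber) == length(absorbance), "grid/absorbance length mismatch")
  assert_that(length(wavenumber) >= 2L, "a spectrum needs at least two grid points")
  steps <- diff(wavenumber)
  assert_that(all(steps > 0), "wavenumber grid must be strictly ascending")
  assert_that(
    max(steps) - min(steps) < 1e-6 * mean(steps) + 1e-9,
    "wavenumber grid must be uniform"
  )
  structure(
    data.frame(wavenumber = wavenumber, absorbance = absorbance),
    label = label,
    class = c("spectrum", "data.frame")
  )
}

#' Read a two-column wavenumber/absorbance spectrum file
#' @param path CSV with columns `wavenumber_cm-1`, `absorbance` (order on
#'   disk may be descending; it is re-ordered ascending).
#' @param label state tag.
#' @return a `spectrum`.
#' @export
read_spectrum <- function(path, label = "") {
  df <- read_assay_table(path, "spectrum")
  as_spectrum(df$wavenumber, df$absorbance, label = label)
}

#' Write a spectrum as two-column text
#' @param spec a `spectrum`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(`wavenumber_cm-1` = spec$wavenumber,
                   absorbance = spec$absorbance, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target grid by linear interpolation
#'
#' @param spec a `spectrum`.
#' @param target ascending uniform wavenumber grid inside the source
#'   range; extrapolation is an error.
#' @return a `spectrum` on `target`.
#' @export
regrid <- function(spec, target) {
  assert_that(
    min(target) >= min(spec$wavenumber) && max(target) <= max(spec$wavenumber),
    "target grid extends outside the source range (no extrapolation)"
  )
  out <- approx(spec$wavenumber, spec$absorbance, xout = target)$y
  as_spectrum(target, out, label = attr(spec, "label"))
}

#' Apply declared spectral corrections
#'
#' Two correction types, each recorded in the returned provenance, applied
#' in physically sensible order - additive contamination is removed before
#' the multiplicative film normalization:
#' \describe{
#'   \item{subtract}{subtract `alpha * reference` (e.g. a water-vapor
#'     spectrum) with `alpha` minimizing the roughness - the summed
#'     squared first differences - of the corrected spectrum inside
#'     `fit_window` (default 1700-1900 cm-1, a window dominated by sharp
#'     vapor lines and free of protein bands).}
#'   \item{scale}{multiply by the scalar minimizing the squared residual
#'     against `reference` inside `scale_window` (default 1500-1700 cm-1,
#'     the protein-dominated amide region; corrects film
#'     swelling/shrinkage between recordings).}
#' }
#' With no corrections requested the spectrum is returned unchanged.
#'
#' @param spec a `spectrum`.
#' @param scale_to optional reference `spectrum` for scale correction.
#' @param subtract_ref optional reference `spectrum` for subtraction.
#' @param fit_window `c(lo, hi)` cm-1 window the subtraction is fit in.
#' @param scale_window `c(lo, hi)` cm-1 window the scale factor is fit in.
#' @return corrected `spectrum` with attribute `corrections` (named list
#'   of fitted factors).
#' @export
correct_spectrum <- function(spec, scale_to = NULL, subtract_ref = NULL,
                             fit_window = c(1700, 1900),
                             scale_window = c(1500, 1700)) {
  prov <- list()
  window_idx <- function(s, win) {
    idx <- which(s$wavenumber >= win[1] & s$wavenumber <= win[2])
    assert_that(length(idx) >= 3L, "fit window [%g, %g] contains too few grid points",
                win[1], win[2])
    idx
  }
  out <- spec
  if (!is.null(subtract_ref)) {
    assert_that(
      isTRUE(all.equal(out$wavenumber, subtract_ref$wavenumber)),
      "subtraction reference must share the spectrum grid (regrid first)"
    )
    idx <- window_idx(out, fit_window)
    ds <- diff(out$absorbance[idx])
    dv <- diff(subtract_ref$absorbance[idx])
    assert_that(sum(dv^2) > 0, "subtraction reference is flat in the fit window")
    alpha <- sum(ds * dv) / sum(dv^2)
    out <- as_spectrum(out$wavenumber,
                       out$absorbance - alpha * subtract_ref$absorbance,
                       attr(spec, "label"))
    prov$subtract_alpha <- alpha
  }
  if (!is.null(scale_to)) {
    assert_that(
      isTRUE(all.equal(out$wavenumber, scale_to$wavenumber)),
      "scale reference must share the spectrum grid (regrid first)"
    )
    idx <- window_idx(out, scale_window)
    k <- sum(out$absorbance[idx] * scale_to$absorbance[idx]) /
      sum(out$absorbance[idx]^2)
    out <- as_spectrum(out$wavenumber, out$absorbance * k, attr(spec, "label"))
    prov$scale_factor <- k
  }
  attr(out, "corrections") <- prov
  out
}

#' Ligand-exchange difference spectrum
#'
#' Pointwise `active - inactive` on the common grid: bands of the
#' agonist-bound (active) state appear positive, bands of the
#' antagonist-bound (inactive) state negative.
#'
#' @param active,inactive `spectrum` objects on identical grids.
#' @return a `difference_spectrum` (same shape as `spectrum`) carrying the
#'   two input labels as provenance.
#' @export
difference_spectrum <- function(active, inactive) {
  assert_that(
    isTRUE(all.equal(active$wavenumber, inactive$wavenumber)),
    "spectra are on different grids; regrid first"
  )
  structure(
    data.frame(wavenumber = active$wavenumber,
               delta = active$absorbance - inactive$absorbance),
    active_label = attr(active, "label"),
    inactive_label = attr(inactive, "label"),
    class = c("difference_spectrum", "data.frame")
  )
}

#' Locate a band extremum in a diagnostic window
#'
#' Finds the grid extremum of the requested sign inside `window`, then
#' refines the position by parabolic interpolation through the three
#' points around it, giving sub-grid precision (about 0.5 cm-1 on a
#' 2 cm-1 grid for bands of FWHM >= 8 cm-1). If the window contains no
#' extremum of the requested sign (flat or wrong-signed signal), absence
#' is reported rather than a fabricated peak.
#'
#' @param x a `difference_spectrum` (or any data frame with
#'   `wavenumber` and a signal column named `delta` or `absorbance`).
#' @param window `c(lo, hi)` in cm-1.
#' @param sign `"positive"` or `"negative"`.
#' @return list: `found` (logical), `position` (cm-1), `amplitude`,
#'   `sign`, `window`.
#' @export
find_band <- function(x, window, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  y_col <- if ("delta" %in% names(x)) "delta" else "absorbance"
  idx <- which(x$wavenumber >= window[1] & x$wavenumber <= window[2])
  assert_that(length(idx) >= 3L, "window [%g, %g] contains too few grid points",
              window[1], window[2])
  wn <- x$wavenumber[idx]
  y <- x[[y_col]][idx]
  if (sign == "negative") y <- -y
  absent <- list(found = FALSE, position = NA_real_, amplitude = NA_real_,
                 sign = sign, window = window)
  if (max(y) <= 0 || diff(range(y)) < .Machine$double.eps^0.5) return(absent)
  i <- which.max(y)
  pos <- wn[i]
  amp <- y[i]
  if (i > 1L && i < length(y)) {
    a <- y[i - 1L]; b <- y[i]; g <- y[i + 1L]
    denom <- a - 2 * b + g
    if (abs(denom) > .Machine$double.eps) {
      p <- 0.5 * (a - g) / denom
      step <- wn[2] - wn[1]
      pos <- wn[i] + p * step
      amp <- b - 0.25 * (a - g) * p
    }
  }
  list(
    found = TRUE,
    position = pos,
    amplitude = if (sign == "negative") -amp else amp,
    sign = sign,
    window = window
  )
}

#' Band shift between the inactive and active state
#'
#' `positive position - negative position`: an upshift (weakened hydrogen
#' bonding in the active state) is positive.
#'
#' @param negative_peak,positive_peak results of [find_band()] from the
#'   same difference spectrum.
#' @return shift in cm-1.
#' @export
band_shift <- function(negative_peak, positive_peak) {
  assert_that(
    isTRUE(negative_peak$found) && isTRUE(positive_peak$found),
    "band shift needs both peaks; at least one was not found"
  )
  positive_peak$position - negative_peak$position
}

#' Default diagnostic windows
#'
#' S-H stretch of cysteine 2500-2600 cm-1, C-N stretch of the histidine
#' imidazole 1100-1200 cm-1, amide-I 1600-1700 cm-1.
#'
#' @return named list of `c(lo, hi)` windows.
#' @export
diagnostic_windows <- function() {
  list(
    sh_cysteine = c(2500, 2600),
    cn_histidine = c(1100, 1200),
    amide_I = c(1600, 1700)
  )
}
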