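#' Four-parameter logistic model
#'
#' `response = Bottom + (Top - Bottom) / (1 + 10^((log10(EC50) -
#' log10(conc)) * HillSlope))`, the form used throughout for
#' concentration-response data.
#'
#' @param conc concentrations in molar (> 0).
#' @param top,bottom plateaus.
#' @param pec50 -log10(EC50 in molar).
#' @param hill Hill slope.
#' @return predicted responses.
#' @export
fourpl <- function(conc, top, bottom, pec50, hill) {
  assert_that(all(conc > 0), "concentrations must be positive")
  bottom + (top - bottom) / (1 + 10^((-pec50 - log10(conc)) * hill))
}

#' Generate a synthetic dose-response dataset
#'
#' Responses are the 4PL values at the truth parameters plus independent
#' Gaussian noise, per replicate.
#'
#' @param truth data frame with one row per curve: `ligand`, `pathway`,
#'   `construct`, `top`, `bottom`, `pec50`, `hill`.
#' @param concentrations molar concentration grid (should span >= 3 log
#'   units around EC50).
#' @param n_replicates replicates per concentration.
#' @param noise_sd Gaussian response noise s.d.
#' @param seed integer seed.
#' @return data frame in the `dose_response` schema (canonical `conc_M`),
#'   with the truth attached as attribute `truth`.
#' @export
gen_dose_response <- function(truth, concentrations, n_replicates = 3,
                              noise_sd = 0, seed = 1L) {
  assert_that(all(concentrations > 0), "concentrations must be positive")
  assert_that(n_replicates >= 1, "need at least one replicate")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        mu <- fourpl(concentrations, tr$top, tr$bottom, tr$pec50, tr$hill)
        data.frame(
          ligand = tr$ligand, pathway = tr$pathway, construct = tr$construct,
          conc_M = concentrations,
          response = mu + rnorm(length(mu), 0, noise_sd),
          replicate = r
        )
      }))
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate synthetic radioligand binding data
#'
#' Saturation mode: `total = Bmax * L / (Kd + L) + ns * L + noise`,
#' `nonspecific = ns * L + noise`. Competition mode: specific counts
#' follow a descending sigmoid in log10(inhibitor) between `top` and
#' `bottom` plateaus with the true `ic50`; total = specific + ns,
#' nonspecific = ns (constant radioligand concentration). Noise is
#' Gaussian with s.d. `noise_sd`, independent per record.
#'
#' @param mode `"saturation"` or `"competition"`.
#' @param truth saturation: list(`bmax`, `kd`, `ns`); competition:
#'   list(`top`, `bottom`, `ic50`, `hill`, `ns`). Concentrations molar.
#' @param concentrations molar grid: radioligand (saturation) or
#'   inhibitor (competition).
#' @param n_replicates replicates per concentration.
#' @param noise_sd counting noise s.d.
#' @param seed integer seed.
#' @return data frame in the `binding` schema with attribute `truth`.
#' @export
gen_binding <- function(mode = c("saturation", "competition"), truth,
                        concentrations, n_replicates = 3, noise_sd = 0,
                        seed = 1L) {
  mode <- match.arg(mode)
  assert_that(all(concentrations > 0), "concentrations must be positive")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      if (mode == "saturation") {
        assert_that(truth$kd > 0, "Kd must be positive")
        spec <- truth$bmax * concentrations / (truth$kd + concentrations)
        ns <- truth$ns * concentrations
      } else {
        assert_that(truth$ic50 > 0, "IC50 must be positive")
        hill <- truth$hill %||% 1
        spec <- truth$bottom + (truth$top - truth$bottom) /
          (1 + 10^((log10(concentrations) - log10(truth$ic50)) * hill))
        ns <- rep(truth$ns %||% 0, length(concentrations))
      }
      data.frame(
        mode = mode,
        conc_M = concentrations,
        counts_total = spec + ns + rnorm(length(spec), 0, noise_sd),
        counts_nonspecific = ns + rnorm(length(ns), 0, noise_sd),
        replicate = r
      )
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a synthetic absorbance spectrum from additive Gaussian bands
#'
#' `absorbance = baseline + sum of Gaussian bands` on a uniform
#' wavenumber grid (default step 2 cm-1, the instrument resolution the
#' pipeline assumes). Band width is given as FWHM.
#'
#' @param bands data frame with `center` (cm-1), `amplitude`, `fwhm`
#'   (cm-1).
#' @param grid `c(min, max, step)` in cm-1 (default step 2).
#' @param baseline constant baseline, or a function of wavenumber.
#' @param noise_sd Gaussian absorbance noise s.d.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param label state tag carried on the spectrum.
#' @return a `spectrum` object (see [as_spectrum()]).
#' @export
gen_spectrum <- function(bands, grid = c(1000, 3000, 2), baseline = 0,
                         noise_sd = 0, seed = 1L, label = "") {
  assert_that(length(grid) == 3L && grid[3] > 0, "grid must be c(min, max, step) with step > 0")
  wn <- seq(grid[1], grid[2], by = grid[3])
  if (nrow(bands) > 0) {
    assert_that(all(bands$fwhm > 0), "band FWHM must be positive")
    assert_that(
      all(bands$center >= grid[1] & bands$center <= grid[2]),
      "band centers must lie inside the grid"
    )
  }
  base_v <- if (is.function(baseline)) baseline(wn) else rep(baseline, length(wn))
  absorb <- base_v
  for (i in seq_len(nrow(bands))) {
    sigma <- bands$fwhm[i] / (2 * sqrt(2 * log(2)))
    absorb <- absorb + bands$amplitude[i] * exp(-(wn - bands$center[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    absorb <- with_seed(seed, absorb + rnorm(length(wn), 0, noise_sd))
  }
  as_spectrum(wn, absorb, label = label)
}
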