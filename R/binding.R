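#' One-site saturation binding fit
#'
#' Specific binding is computed per replicate-matched concentration as
#' `total - nonspecific` (negative values from counting noise are kept,
#' not clipped, and flagged), then fit to the one-site model
#' `B = Bmax * L / (Kd + L)` by least squares. 95% confidence intervals
#' are asymptotic (covariance-based).
#'
#' @param binding data frame in the `binding` schema, `mode ==
#'   "saturation"`.
#' @return object of class `saturation_fit`: `bmax`, `kd` (molar), their
#'   `ci` (2 x 2 matrix), `rss`, `converged`, `negative_specific`
#'   (count).
#' @export
fit_saturation <- function(binding) {
  b <- binding[binding$mode == "saturation", , drop = FALSE]
  assert_that(nrow(b) >= 1L, "no saturation records")
  assert_that(length(unique(b$conc_M)) >= 4L, "need >= 4 radioligand concentrations")
  specific <- b$counts_total - b$counts_nonspecific
  n_neg <- sum(specific < 0)
  assert_that(any(specific > 0), "all specific counts are <= 0")
  L <- b$conc_M
  start_bmax <- max(specific)
  start_kd <- stats::median(L)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      specific ~ bmax * L / (kd + L),
      data = data.frame(L = L, specific = specific),
      start = list(bmax = start_bmax, kd = start_kd),
      lower = c(bmax = 0, kd = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(bmax = NA_real_, kd = NA_real_, ci = NULL, rss = NA_real_,
                converged = FALSE, negative_specific = n_neg)
    class(out) <- "saturation_fit"
    return(out)
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, kd = NA_real_))
  q <- qt(0.975, df = length(L) - 2)
  ci <- rbind(
    bmax = cf["bmax"] + c(-1, 1) * q * se["bmax"],
    kd = cf["kd"] + c(-1, 1) * q * se["kd"]
  )
  colnames(ci) <- c("lower", "upper")
  out <- list(
    bmax = unname(cf["bmax"]), kd = unname(cf["kd"]), ci = ci,
    rss = sum(residuals(fit)^2), converged = TRUE,
    negative_specific = n_neg
  )
  class(out) <- "saturation_fit"
  out
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> Bmax %.4g  Kd %.4g M (%.4g nM)%s\n",
              x$bmax, x$kd, x$kd * 1e9,
              if (x$negative_specific > 0)
                sprintf("  [%d negative specific point(s) retained]", x$negative_specific)
              else ""))
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for radioligand concentration `L` and
#' affinity `Kd`; the identity holds exactly by construction.
#'
#' @param ic50 fitted IC50 (molar).
#' @param L radioligand concentration (molar).
#' @param kd radioligand Kd (molar).
#' @return Ki in molar.
#' @export
cheng_prusoff <- function(ic50, L, kd) {
  assert_that(L > 0 && kd > 0, "radioligand concentration and Kd must be positive")
  assert_that(ic50 > 0, "IC50 must be positive")
  ic50 / (1 + L / kd)
}

#' Competition binding fit with Cheng-Prusoff Ki
#'
#' Specific counts (`total - nonspecific`) are fit to a descending
#' sigmoid in log10(inhibitor): `B = bottom + (top - bottom) /
#' (1 + 10^((log10 conc - log10 IC50) * hill))`; the fitted IC50 is
#' converted to Ki with [cheng_prusoff()].
#'
#' @param binding data frame in the `binding` schema, `mode ==
#'   "competition"`; `conc_M` is the inhibitor concentration.
#' @param L radioligand concentration (molar).
#' @param kd radioligand Kd (molar).
#' @param hill_bound Hill slope bound (default 2).
#' @return object of class `competition_fit`: `top`, `bottom`, `ic50`,
#'   `hill`, `ki` (molar), `rss`, `converged`.
#' @export
fit_competition <- function(binding, L, kd, hill_bound = 2) {
  assert_that(L > 0 && kd > 0, "radioligand concentration and Kd must be positive")
  b <- binding[binding$mode == "competition", , drop = FALSE]
  assert_that(nrow(b) >= 1L, "no competition records")
  assert_that(length(unique(b$conc_M)) >= 4L, "need >= 4 inhibitor concentrations")
  specific <- b$counts_total - b$counts_nonspecific
  x <- log10(b$conc_M)
  starts <- seq(min(x), max(x), length.out = 5)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        specific ~ bottom + (top - bottom) / (1 + 10^((x - logic50) * hill)),
        data = data.frame(x = x, specific = specific),
        start = list(top = max(specific), bottom = min(specific), logic50 = s, hill = 1),
        lower = c(top = -Inf, bottom = -Inf, logic50 = min(x) - 3, hill = 0),
        upper = c(top = Inf, bottom = Inf, logic50 = max(x) + 3, hill = hill_bound),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                hill = NA_real_, ki = NA_real_, rss = NA_real_, converged = FALSE)
    class(out) <- "competition_fit"
    return(out)
  }
  cf <- coef(best$fit)
  ic50 <- unname(10^cf["logic50"])
  out <- list(
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    ic50 = ic50, hill = unname(cf["hill"]),
    ki = cheng_prusoff(ic50, L, kd),
    rss = best$rss, converged = TRUE,
    L = L, kd = kd
  )
  class(out) <- "competition_fit"
  out
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("<competition_fit> IC50 %.4g M  Ki %.4g M (%.4g nM)  Hill %.3g\n",
              x$ic50, x$ki, x$ki * 1e9, x$hill))
  invisible(x)
}
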