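#' Normalize kinetic luminescence reads into a dose-response dataset
#'
#' For each well: the counts in the response window (default 5-10 min
#' after compound addition) are averaged and divided by the well's
#' baseline counts (reads at `time_s < 0`, i.e. before addition); that
#' fold-change is then divided by the mean fold-change of the vehicle
#' wells (`conc_M == 0`) of the same construct/replicate.
#'
#' @param kinetic data frame in the `kinetic_luminescence` schema.
#' @param response_window `c(lo, hi)` seconds after addition.
#' @param baseline_window `c(lo, hi)` seconds; default all reads before 0.
#' @return data frame in the `dose_response` schema.
#' @export
normalize_kinetic <- function(kinetic, response_window = c(300, 600),
                              baseline_window = c(-Inf, 0)) {
  need <- c("well", "time_s", "counts", "construct", "ligand", "conc_M", "replicate")
  assert_that(all(need %in% names(kinetic)), "kinetic table is missing columns: %s",
              paste(setdiff(need, names(kinetic)), collapse = ", "))
  wells <- split(kinetic, kinetic$well)
  per_well <- do.call(rbind, lapply(wells, function(w) {
    base <- w$counts[w$time_s >= baseline_window[1] & w$time_s < baseline_window[2]]
    resp <- w$counts[w$time_s >= response_window[1] & w$time_s <= response_window[2]]
    assert_that(length(base) >= 1L, "well %s has no baseline reads", w$well[1])
    assert_that(length(resp) >= 1L, "well %s has no reads in the response window", w$well[1])
    assert_that(mean(base) != 0, "well %s has zero baseline counts", w$well[1])
    data.frame(
      well = w$well[1], ligand = w$ligand[1], construct = w$construct[1],
      conc_M = w$conc_M[1], replicate = w$replicate[1],
      fold = mean(resp) / mean(base)
    )
  }))
  grp <- paste(per_well$construct, per_well$replicate)
  out <- do.call(rbind, lapply(split(per_well, grp), function(g) {
    veh <- g$fold[g$conc_M == 0]
    assert_that(length(veh) >= 1L,
                "no vehicle wells (conc_M == 0) for construct %s replicate %s",
                g$construct[1], g$replicate[1])
    g$response <- g$fold / mean(veh)
    g[g$conc_M > 0,
      c("ligand", "construct", "conc_M", "response", "replicate")]
  }))
  out$pathway <- NA_character_
  rownames(out) <- NULL
  out[, c("ligand", "pathway", "construct", "conc_M", "response", "replicate")]
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of [fourpl()] with the Hill slope box-bounded to
#' `|Hill| <= 2`. The fit is multi-started across a grid of log10 EC50
#' values spanning the tested concentration range (both Hill signs); the
#' best converged start wins. Degenerate flat data are flagged
#' (`span_zero`) rather than failed.
#'
#' @param curve data frame with `conc_M` and `response` for one curve
#'   (>= 4 distinct concentrations).
#' @param hill_bound Hill slope bound (default 2).
#' @param n_starts number of log10 EC50 starting values.
#' @return object of class `fourpl_fit`: list with `top`, `bottom`,
#'   `span`, `pec50`, `ec50`, `hill`, `rss`, `converged`, `span_zero`,
#'   `n`.
#' @export
fit_4pl <- function(curve, hill_bound = 2, n_starts = 5) {
  assert_that(all(c("conc_M", "response") %in% names(curve)),
              "curve needs conc_M and response columns")
  assert_that(length(unique(curve$conc_M)) >= 4L,
              "need >= 4 distinct concentrations for a 4PL fit")
  assert_that(all(curve$conc_M > 0), "concentrations must be positive")
  x <- log10(curve$conc_M)
  y <- curve$response
  span_zero <- var(y) < .Machine$double.eps^0.5 * max(1, mean(y)^2)
  if (span_zero) {
    out <- list(
      top = mean(y), bottom = mean(y), span = 0,
      pec50 = -mean(x), ec50 = 10^mean(x), hill = 1,
      rss = sum((y - mean(y))^2), converged = TRUE, span_zero = TRUE,
      n = length(y)
    )
    class(out) <- "fourpl_fit"
    return(out)
  }
  starts <- seq(min(x), max(x), length.out = n_starts)
  ylo <- min(y); yhi <- max(y)
  best <- NULL
  for (s in starts) {
    for (h0 in c(1, -1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^((logec50 - x) * hill)),
          data = data.frame(x = x, y = y),
          start = list(top = yhi, bottom = ylo, logec50 = s, hill = h0),
          lower = c(top = -Inf, bottom = -Inf, logec50 = min(x) - 3, hill = -hill_bound),
          upper = c(top = Inf, bottom = Inf, logec50 = max(x) + 3, hill = hill_bound),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(top = NA_real_, bottom = NA_real_, span = NA_real_,
                pec50 = NA_real_, ec50 = NA_real_, hill = NA_real_,
                rss = NA_real_, converged = FALSE, span_zero = FALSE,
                n = length(y))
    class(out) <- "fourpl_fit"
    return(out)
  }
  cf <- coef(best$fit)
  # the 4PL has an exact (top/bottom swap, Hill negation) symmetry at the
  # same EC50; canonicalize to span >= 0 so Span/EC50 ratios are defined
  if (cf["top"] < cf["bottom"]) {
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf["hill"] <- -cf["hill"]
  }
  out <- list(
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    span = unname(cf["top"] - cf["bottom"]),
    pec50 = unname(-cf["logec50"]), ec50 = unname(10^cf["logec50"]),
    hill = unname(cf["hill"]), rss = best$rss,
    converged = TRUE, span_zero = FALSE, n = length(y)
  )
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> Top %.4g  Bottom %.4g  Span %.4g  pEC50 %.4g  Hill %.3g  (rss %.3g, n %d%s)\n",
    x$top, x$bottom, x$span, x$pec50, x$hill, x$rss, x$n,
    if (x$span_zero) ", flat" else if (!x$converged) ", NOT converged" else ""
  ))
  invisible(x)
}

#' Fit one 4PL per replicate of a curve
#'
#' @param curves data frame in the `dose_response` schema for a single
#'   (ligand, pathway, construct).
#' @return list of `fourpl_fit`, named by replicate.
#' @export
fit_4pl_by_replicate <- function(curves) {
  lapply(split(curves, curves$replicate), fit_4pl)
}

#' Wild-type-normalized activity parameters
#'
#' Per replicate `r` (test and reference fits matched by experiment
#' index, the parallel-experiment pairing): `Emax = Span_test/Span_ref`,
#' `delta_pEC50 = pEC50_test - pEC50_ref`, `RAi =
#' (Span/EC50)_test / (Span/EC50)_ref`; the summary is the mean across
#' replicates.
#'
#' @param test_fits,ref_fits lists of `fourpl_fit` with matching names
#'   (replicate ids).
#' @return list with `per_replicate` data frame and `mean` named vector.
#' @export
relative_activity <- function(test_fits, ref_fits) {
  assert_that(length(test_fits) == length(ref_fits),
              "test and reference must have the same number of replicate fits")
  reps <- names(test_fits) %||% as.character(seq_along(test_fits))
  assert_that(
    is.null(names(ref_fits)) || identical(sort(names(test_fits)), sort(names(ref_fits))),
    "replicate ids of test and reference fits do not match"
  )
  per <- do.call(rbind, lapply(reps, function(r) {
    tf <- test_fits[[r]]
    rf <- ref_fits[[r]]
    assert_that(tf$converged && rf$converged, "replicate %s: unconverged fit", r)
    assert_that(rf$span > 0, "replicate %s: reference span is not positive", r)
    data.frame(
      replicate = r,
      emax = tf$span / rf$span,
      delta_pec50 = tf$pec50 - rf$pec50,
      rai = (tf$span / tf$ec50) / (rf$span / rf$ec50)
    )
  }))
  list(
    per_replicate = per,
    mean = c(
      emax = mean(per$emax),
      delta_pec50 = mean(per$delta_pec50),
      rai = mean(per$rai)
    )
  )
}

significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Ligand bias as delta-delta-log(Emax/EC50)
#'
#' Within each pathway and replicate, `DeltaLog = log10(Span/EC50)_test -
#' log10(Span/EC50)_reference` (the log relative activity of the test
#' ligand against the reference ligand, replicates matched by experiment
#' index). The bias statistic is `DeltaDeltaLog = DeltaLog(pathway A) -
#' DeltaLog(pathway B)`; its per-replicate values are tested against zero
#' with a two-sided one-sample t-test and starred at 0.05 / 0.01 / 0.001.
#' A positive value means bias toward pathway A.
#'
#' @param test_fits,ref_fits named lists with one element per pathway,
#'   each a replicate-named list of `fourpl_fit` (as from
#'   [fit_4pl_by_replicate()]).
#' @param pathway_a,pathway_b the two pathway names to contrast.
#' @return object of class `bias_result`: list with `delta_log`
#'   (per-pathway per-replicate data frame), `ddl` (per-replicate
#'   DeltaDeltaLog), `ddl_mean`, `t`, `df`, `p`, `stars`.
#' @export
bias_factor <- function(test_fits, ref_fits, pathway_a, pathway_b) {
  assert_that(
    all(c(pathway_a, pathway_b) %in% names(test_fits)) &&
      all(c(pathway_a, pathway_b) %in% names(ref_fits)),
    "fits for both pathways are required"
  )
  dlog_pathway <- function(pw) {
    tf <- test_fits[[pw]]
    rf <- ref_fits[[pw]]
    assert_that(length(tf) == length(rf),
                "pathway %s: replicate counts differ between ligands", pw)
    reps <- names(tf) %||% as.character(seq_along(tf))
    vapply(reps, function(r) {
      a <- tf[[r]]; b <- rf[[r]]
      assert_that(a$converged && b$converged, "pathway %s replicate %s: unconverged fit", pw, r)
      log10(a$span / a$ec50) - log10(b$span / b$ec50)
    }, numeric(1))
  }
  dla <- dlog_pathway(pathway_a)
  dlb <- dlog_pathway(pathway_b)
  assert_that(length(dla) == length(dlb), "pathways have different replicate counts")
  ddl <- dla - dlb
  if (length(ddl) >= 2L && var(ddl) > 0) {
    tt <- t.test(ddl, mu = 0)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else if (length(ddl) >= 2L) {
    # all replicate values identical: t undefined unless exactly zero
    t_stat <- if (all(ddl == 0)) 0 else Inf
    df <- length(ddl) - 1
    p <- if (all(ddl == 0)) 1 else 0
  } else {
    t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  out <- list(
    delta_log = data.frame(
      replicate = rep(names(dla) %||% seq_along(dla), 2),
      pathway = rep(c(pathway_a, pathway_b), each = length(dla)),
      delta_log = c(dla, dlb)
    ),
    ddl = unname(ddl),
    ddl_mean = mean(ddl),
    t = t_stat, df = df, p = p,
    stars = significance_stars(p),
    pathways = c(pathway_a, pathway_b)
  )
  class(out) <- "bias_result"
  out
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "<bias_result> ddLog(Emax/EC50) [%s - %s] = %.3f (t = %.3g, df = %g, p = %.3g %s)\n",
    x$pathways[1], x$pathways[2], x$ddl_mean, x$t, x$df, x$p, x$stars
  ))
  invisible(x)
}
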