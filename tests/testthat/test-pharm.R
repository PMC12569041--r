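kinetic_fixture <- function() {
  # two wells of one construct/replicate plus a vehicle well
  mk <- function(well, conc, base, resp) {
    data.frame(
      well = well, time_s = c(-60, -30, 360, 480, 600),
      counts = c(base, base, resp, resp, resp),
      construct = "WT", ligand = ifelse(conc > 0, "nalfurafine", "vehicle"),
      conc_M = conc, replicate = 1
    )
  }
  rbind(
    mk("A1", 1e-8, 1000, 1500),
    mk("A2", 1e-9, 1000, 1200),
    mk("V1", 0, 1000, 1000)
  )
}

test_that("kinetic normalization divides the window fold-change by the vehicle", {
  d <- normalize_kinetic(kinetic_fixture())
  expect_equal(d$response[d$conc_M == 1e-8], 1.5)
  expect_equal(d$response[d$conc_M == 1e-9], 1.2)

  # a well matching the vehicle fold-change normalizes to exactly 1
  k <- kinetic_fixture()
  k$counts[k$well == "V1" & k$time_s > 0] <- 1200
  d2 <- normalize_kinetic(k)
  expect_equal(d2$response[d2$conc_M == 1e-9], 1.0)

  # response window with no reads errors
  expect_error(normalize_kinetic(kinetic_fixture(), response_window = c(1000, 2000)),
               "response window")
  # missing vehicle wells error
  k3 <- kinetic_fixture()
  expect_error(normalize_kinetic(k3[k3$conc_M > 0, ]), "vehicle")
})

test_that("noiseless 4PL data are recovered to 1e-6 relative accuracy", {
  for (tr in list(
    fourpl_truth(top = 100, bottom = 0, pec50 = 8, hill = 1),
    fourpl_truth(top = 2.4, bottom = 1.0, pec50 = 7.2, hill = 1.5),
    fourpl_truth(top = 1, bottom = 3, pec50 = 9, hill = -1)  # descending
  )) {
    d <- gen_dose_response(tr, dr_concs(9, -11.5, -4.5), 1, 0, seed = 1)
    f <- fit_4pl(d)
    expect_true(f$converged)
    # the 4PL has an exact (top/bottom swap, Hill negation) symmetry at
    # identical EC50; accept either parameterization of the same curve
    expect_equal(f$pec50, tr$pec50, tolerance = 1e-6)
    expect_equal(sort(c(f$top, f$bottom)), sort(c(tr$top, tr$bottom)),
                 tolerance = 1e-6)
    expect_equal(abs(f$hill), abs(tr$hill), tolerance = 1e-6)
    expect_equal(f$span, f$top - f$bottom)
  }
})

test_that("the Hill slope is box-bounded at |Hill| = 2", {
  d <- gen_dose_response(fourpl_truth(hill = 3), dr_concs(12, -11, -5), 1, 0, 1)
  f <- fit_4pl(d)
  expect_equal(f$hill, 2, tolerance = 1e-6)
  expect_true(abs(f$hill) <= 2 + 1e-9)
})

test_that("flat curves are flagged rather than failed", {
  d <- data.frame(conc_M = dr_concs(6), response = rep(1.7, 6))
  f <- fit_4pl(d)
  expect_true(f$span_zero)
  expect_equal(f$span, 0)
  expect_true(f$converged)
})

test_that("4PL fits are invariant to concentration rescaling up to the pEC50 shift", {
  tr <- fourpl_truth(top = 90, bottom = 5, pec50 = 7.5, hill = 1.2)
  d <- gen_dose_response(tr, dr_concs(8), 1, 0, 1)
  f1 <- fit_4pl(d)
  d2 <- d; d2$conc_M <- d2$conc_M * 1e3
  f2 <- fit_4pl(d2)
  expect_equal(f2$pec50, f1$pec50 - 3, tolerance = 1e-6)
  expect_equal(f2$top, f1$top, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
})

test_that("relative activity normalizes span, pEC50 and Span/EC50 per replicate", {
  mk_fit <- function(span, ec50) {
    structure(list(top = span, bottom = 0, span = span, pec50 = -log10(ec50),
                   ec50 = ec50, hill = 1, rss = 0, converged = TRUE,
                   span_zero = FALSE, n = 8), class = "fourpl_fit")
  }
  ra <- relative_activity(list(r1 = mk_fit(50, 1e-7)), list(r1 = mk_fit(100, 1e-8)))
  expect_equal(unname(ra$mean["emax"]), 0.5)
  expect_equal(unname(ra$mean["delta_pec50"]), -1)
  expect_equal(unname(ra$mean["rai"]), 0.05)

  same <- list(r1 = mk_fit(80, 3e-9), r2 = mk_fit(70, 5e-9), r3 = mk_fit(90, 2e-9))
  ra2 <- relative_activity(same, same)
  expect_equal(unname(ra2$mean), c(1, 0, 1))
  expect_equal(nrow(ra2$per_replicate), 3L)

  expect_error(relative_activity(list(r1 = mk_fit(50, 1e-7)),
                                 list(r1 = mk_fit(-1, 1e-8))),
               "not positive")
})

test_that("ligand bias is zero for the reference against itself and antisymmetric", {
  truths <- rbind(
    fourpl_truth("dyn", "Gprotein", top = 100, pec50 = 8.5),
    fourpl_truth("dyn", "barr2", top = 80, pec50 = 7.8)
  )
  ref <- fit_ligand_pathways(truths, noise_sd = 2, seed = 10)
  bias_self <- bias_factor(ref, ref, "Gprotein", "barr2")
  expect_equal(bias_self$ddl, rep(0, 3))
  expect_equal(bias_self$ddl_mean, 0)

  test_tr <- rbind(
    fourpl_truth("nalf", "Gprotein", top = 95, pec50 = 9.1),
    fourpl_truth("nalf", "barr2", top = 60, pec50 = 7.5)
  )
  tst <- fit_ligand_pathways(test_tr, noise_sd = 2, seed = 20)
  b_ab <- bias_factor(tst, ref, "Gprotein", "barr2")
  b_ba <- bias_factor(tst, ref, "barr2", "Gprotein")
  expect_equal(b_ab$ddl, -b_ba$ddl)
  expect_equal(b_ab$ddl_mean, -b_ba$ddl_mean)
})

test_that("the one-sample t-test matches the closed-form textbook statistic", {
  mk_fit <- function(span, ec50) {
    structure(list(top = span, bottom = 0, span = span, pec50 = -log10(ec50),
                   ec50 = ec50, hill = 1, rss = 0, converged = TRUE,
                   span_zero = FALSE, n = 8), class = "fourpl_fit")
  }
  # engineer per-replicate ddl values of exactly {0.1, -0.1, 0.02}:
  # pathway A carries the offset, pathway B is identical to the reference
  ddl_target <- c(0.1, -0.1, 0.02)
  ref_a <- list(r1 = mk_fit(100, 1e-8), r2 = mk_fit(100, 1e-8), r3 = mk_fit(100, 1e-8))
  tst_a <- lapply(setNames(ddl_target, names(ref_a)), function(d) {
    mk_fit(100 * 10^d, 1e-8)
  })
  tst <- list(A = tst_a, B = ref_a)
  ref <- list(A = ref_a, B = ref_a)
  b <- bias_factor(tst, ref, "A", "B")
  expect_equal(b$ddl, ddl_target)
  m <- mean(ddl_target); s <- sd(ddl_target); n <- 3
  t_oracle <- m / (s / sqrt(n))
  p_oracle <- 2 * pt(-abs(t_oracle), df = n - 1)
  expect_equal(b$t, t_oracle)
  expect_equal(b$df, n - 1)
  expect_equal(b$p, p_oracle)
  expect_equal(b$stars, "ns")

  # delta-log values of +0.5 / -0.5 per replicate give ddl exactly 1
  tst2 <- list(
    A = lapply(ref_a, function(f) mk_fit(f$span * 10^0.5, f$ec50)),
    B = lapply(ref_a, function(f) mk_fit(f$span * 10^-0.5, f$ec50))
  )
  b2 <- bias_factor(tst2, ref, "A", "B")
  expect_equal(b2$ddl, rep(1, 3))

  # a single replicate reports values but no test
  b3 <- bias_factor(list(A = tst_a[1], B = ref_a[1]),
                    list(A = ref_a[1], B = ref_a[1]), "A", "B")
  expect_equal(b3$ddl, 0.1)
  expect_true(is.na(b3$p))
})

test_that("noisy 4PL recovery stays within the expected pEC50 error", {
  # 40-seed spot check of the full 200-seed acceptance property
  tr <- fourpl_truth(top = 100, bottom = 0, pec50 = 8, hill = 1)
  errs <- vapply(1:40, function(s) {
    d <- gen_dose_response(tr, dr_concs(8), 3, noise_sd = 5, seed = s)
    abs(fit_4pl(d)$pec50 - 8)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})
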