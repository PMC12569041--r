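toy_boundaries <- function() {
  new_state_boundaries <- getFromNamespace("new_state_boundaries", "korbias")
  new_state_boundaries(
    data.frame(
      base = c(1L, 3L),
      d_min = c(5, 10), d_max = c(10, 15),
      chi_min = c(-180, 40), chi_max = c(-60, 120)
    ),
    split_by_r = c(2L, 3L)
  )
}

test_that("classification is region containment plus the R3.50 sub-label", {
  b <- toy_boundaries()
  f <- data.frame(
    d = c(7, 12, 30),
    chi = c(-90, 80, 0),
    r_down = c(FALSE, TRUE, FALSE)
  )
  expect_equal(classify(f, b), c("S1", "S3A", "UNASSIGNED"))
})

test_that("overlapping regions are rejected at validation time", {
  new_state_boundaries <- getFromNamespace("new_state_boundaries", "korbias")
  expect_error(
    new_state_boundaries(data.frame(
      base = c(1L, 2L),
      d_min = c(5, 8), d_max = c(10, 12),
      chi_min = c(-90, -70), chi_max = c(-30, 0)
    )),
    "overlap"
  )
  # wrapped chi interval overlap is detected too
  expect_error(
    new_state_boundaries(data.frame(
      base = c(1L, 2L),
      d_min = c(5, 5), d_max = c(10, 10),
      chi_min = c(160, -175), chi_max = c(-170, -160)
    )),
    "overlap"
  )
})

test_that("the default scheme enumerates six states besides UNASSIGNED", {
  b <- default_state_boundaries()
  expect_equal(state_labels(b), c("S1", "S2A", "S2B", "S3A", "S3B", "S4"))
  expect_length(state_labels(b, include_unassigned = TRUE), 7L)
})

test_that("featurize recovers the generator's feature values in frame order", {
  g <- gen_trajectory(list(S1 = list(n = 25), S2A = list(n = 10),
                           S4 = list(n = 15)), seed = 21)
  f <- featurize(g$trajectory)
  expect_equal(nrow(f), 50L)
  expect_equal(f$d, g$features$d, tolerance = 1e-9)
  expect_equal(f$chi, g$features$chi, tolerance = 1e-7)
  expect_equal(f$r_down, g$features$r_down)

  single <- gen_trajectory(list(S1 = list(n = 1)), seed = 22)
  expect_equal(nrow(featurize(single$trajectory)), 1L)
})

test_that("features are invariant under residue renumbering via the map", {
  g <- gen_trajectory(list(S3A = list(n = 8)), seed = 23)
  f0 <- featurize(g$trajectory)
  tr <- g$trajectory
  remap <- c("153" = 1001L, "156" = 1002L, "330" = 1003L)
  tr$topology$atoms$residue_number <-
    remap[as.character(tr$topology$atoms$residue_number)]
  map <- list(
    S153 = list(chain = "A", resno = 1001),
    R156 = list(chain = "A", resno = 1002),
    Y330 = list(chain = "A", resno = 1003)
  )
  f1 <- featurize(tr, residue_map = map)
  expect_equal(f1$d, f0$d)
  expect_equal(f1$chi, f0$chi)
  expect_equal(f1$r_down, f0$r_down)
})

test_that("population fractions conserve and pool correctly across replicates", {
  labs <- c(rep("S1", 6), rep("S3A", 4))
  pops <- state_populations(labs, r_down = grepl("A$", labs))
  expect_equal(unname(pops$pooled["S1"]), 0.6)
  expect_equal(unname(pops$pooled["S3A"]), 0.4)
  expect_equal(sum(pops$pooled), 1)

  # base-3 r_down proportion from mixed substates
  labs2 <- c("S3A", "S3A", "S3A", "S3B")
  pops2 <- state_populations(labs2, r_down = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(pops2$r_down_by_base["S3"]), 0.75)

  # all-unassigned input still conserves
  pops3 <- state_populations(rep("UNASSIGNED", 5), r_down = rep(FALSE, 5))
  expect_equal(unname(pops3$pooled["UNASSIGNED"]), 1)

  # pooled fraction equals the frame-weighted mean of per-replicate fractions
  labs4 <- c(rep("S1", 8), rep("S2B", 2), rep("S1", 3), rep("S2B", 7))
  rep4 <- rep(c(1, 2), each = 10)
  pops4 <- state_populations(labs4, r_down = rep(FALSE, 20), replicate = rep4)
  per <- pops4$per_replicate
  weighted <- sum(per$fraction[per$label == "S1"] * per$n_frames[per$label == "S1"]) /
    pops4$n_frames
  expect_equal(unname(pops4$pooled["S1"]), weighted)

  expect_error(state_populations(character(0), logical(0)), "no labeled")
})

test_that("occupancy histogram conserves counts with half-open bins", {
  f <- data.frame(d = c(7, 7.5, 8), chi = c(-90, -95, -100), r_down = FALSE)
  h <- occupancy_histogram(f, d_breaks = c(5, 10), chi_breaks = c(-180, -60))
  expect_equal(sum(h), 3L)
  expect_equal(h[1, 1], 3L)

  # value exactly on an interior edge lands in the upper bin
  f2 <- data.frame(d = 10, chi = 0)
  h2 <- occupancy_histogram(f2, d_breaks = c(5, 10, 15), chi_breaks = c(-10, 0, 10))
  expect_equal(h2[2, 2], 1L)
  expect_equal(sum(h2), 1L)

  g <- gen_trajectory(list(S1 = list(n = 40), S3B = list(n = 20)), seed = 31)
  ff <- featurize(g$trajectory)
  hh <- occupancy_histogram(ff, seq(0, 30, by = 1), seq(-180, 180, by = 10))
  expect_equal(sum(hh), 60L)

  expect_error(occupancy_histogram(f, c(5), c(-180, 0)), "bin edges")
})

test_that("contact fingerprints follow the inclusive 6-A heavy-atom rule", {
  cs <- data.frame(resno = c(227, 291, 312), resname = c("LYS", "HIS", "TYR"),
                   p_contact = c(0.7, 1.0, 0.0))
  g <- gen_trajectory(list(S1 = list(n = 10)), seed = 41, contact_spec = cs)
  fp <- contact_fingerprint(g$trajectory, "LIG", cutoff = 6)
  freq <- setNames(fp$frequency, paste0(fp$residue_name, fp$residue_number))
  expect_equal(unname(freq["LYS227"]), mean(g$contact_truth[, "LYS227"]))
  expect_equal(unname(freq["HIS291"]), 1)
  expect_equal(unname(freq["TYR312"]), 0)
  expect_equal(attr(fp, "cutoff"), 6)
  expect_true(all(fp$frequency >= 0 & fp$frequency <= 1))
  # generator geometry: contacts at 4.0 A (inside) or 9.0 A (outside), so
  # the inclusive boundary is what separates them at cutoffs 4 and 3.9
  fp_in <- contact_fingerprint(g$trajectory, "LIG", cutoff = 4.0)
  fp_out <- contact_fingerprint(g$trajectory, "LIG", cutoff = 3.9)
  f_in <- setNames(fp_in$frequency, paste0(fp_in$residue_name, fp_in$residue_number))
  f_out <- setNames(fp_out$frequency, paste0(fp_out$residue_name, fp_out$residue_number))
  expect_equal(unname(f_in["HIS291"]), 1)
  expect_equal(unname(f_out["HIS291"]), 0)
  expect_error(contact_fingerprint(g$trajectory, "NOPE"), "hetero")
})

test_that("fingerprint equals the brute-force all-pairs oracle", {
  cs <- data.frame(resno = c(115, 138, 320), resname = c("GLN", "ASP", "TYR"),
                   p_contact = c(0.5, 0.9, 0.1))
  g <- gen_trajectory(list(S1 = list(n = 12), S2B = list(n = 8)),
                      seed = 43, contact_spec = cs)
  fp <- contact_fingerprint(g$trajectory, "LIG", cutoff = 6)
  oracle <- bruteforce_fingerprint(g$trajectory, "LIG", cutoff = 6)
  got <- setNames(fp$frequency, paste(fp$chain_id, fp$residue_number))
  expect_equal(got[names(oracle)], oracle)
})

test_that("delta fingerprints subtract over the residue union with sign wt - mutant", {
  fp <- function(resno, freq, cutoff = 6) {
    structure(
      data.frame(chain_id = "A", residue_number = resno,
                 residue_name = "RES", frequency = freq),
      cutoff = cutoff, class = c("contact_fingerprint", "data.frame")
    )
  }
  d <- delta_fingerprint(fp(c(115, 291), c(0.9, 0.5)), fp(c(115, 320), c(0.4, 0.3)))
  dd <- setNames(d$delta, d$residue_number)
  expect_equal(unname(dd["115"]), 0.5)    # reduced by the mutation -> positive
  expect_equal(unname(dd["291"]), 0.5)
  expect_equal(unname(dd["320"]), -0.3)   # present only in the mutant
  expect_true(all(d$delta >= -1 & d$delta <= 1))
  same <- fp(c(1, 2), c(0.3, 0.7))
  expect_equal(delta_fingerprint(same, same)$delta, c(0, 0))
  expect_error(delta_fingerprint(fp(1, 0.5, cutoff = 6), fp(1, 0.5, cutoff = 4)),
               "cutoff")
})
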