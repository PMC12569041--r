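test_that("minimal PDB parses with exact fields and hetero flags", {
  path <- write_minimal_pdb()
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(1.234, -4.321), tolerance = 1e-3)
  expect_equal(m$atoms$y, c(2.345, 0.250), tolerance = 1e-3)
  expect_equal(m$atoms$z, c(3.456, 12.000), tolerance = 1e-3)
  expect_equal(m$atoms$atom_name, c("CA", "C1"))
  expect_equal(m$atoms$residue_number, c(153L, 401L))
  expect_equal(m$atoms$is_hetero, c(FALSE, TRUE))
  expect_equal(m$atoms$element, c("C", "C"))
})

test_that("the same content read via the mmCIF dialect gives an identical model", {
  m <- read_structure(write_minimal_pdb())
  cif <- tempfile(fileext = ".cif")
  write_structure(m, cif, format = "cif")
  m2 <- suppressWarnings(read_structure(cif))
  expect_identical(m$atoms, m2$atoms)
})

test_that("write-then-read round trip preserves identity and coordinates to 0.001 A", {
  pocket <- gen_pocket_model(3.3)
  for (fmt in c("pdb", "cif")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_structure(pocket, f, format = fmt)
    back <- suppressWarnings(read_structure(f))
    expect_identical(
      back$atoms[, c("chain_id", "residue_number", "residue_name",
                     "atom_name", "is_hetero")],
      pocket$atoms[, c("chain_id", "residue_number", "residue_name",
                       "atom_name", "is_hetero")]
    )
    expect_equal(
      as.matrix(back$atoms[, c("x", "y", "z")]),
      as.matrix(pocket$atoms[, c("x", "y", "z")]),
      tolerance = 1e-3, ignore_attr = TRUE
    )
  }
})

test_that("files without coordinate records are rejected", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), path)
  expect_error(read_structure(path), "ATOM|parse")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("multi-model PDB and XYZ trajectories load with correct frame counts", {
  g <- gen_trajectory(list(S1 = list(n = 3)), seed = 11)
  pdb <- tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, pdb, "pdb")
  tr <- read_trajectory(pdb)
  expect_equal(n_frames(tr), 3L)
  expect_equal(tr$frames[[2]], round(g$trajectory$frames[[2]], 3),
               tolerance = 1e-6, ignore_attr = TRUE)

  g10 <- gen_trajectory(list(S1 = list(n = 10)), seed = 12)
  xyz <- tempfile(fileext = ".xyz")
  write_trajectory(g10$trajectory, xyz, "xyz")
  trx <- read_trajectory(xyz, topology = g10$trajectory$topology)
  expect_equal(n_frames(trx), 10L)
  expect_equal(nrow(trx$frames[[1]]), nrow(g10$trajectory$topology$atoms))
  expect_equal(trx$frames[[7]], g10$trajectory$frames[[7]],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("a frame with a missing atom is reported with its frame index", {
  g <- gen_trajectory(list(S1 = list(n = 3)), seed = 13)
  pdb <- tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, pdb, "pdb")
  lines <- readLines(pdb)
  second_model <- grep("^MODEL", lines)[2]
  atoms_after <- grep("^ATOM", lines)
  lines <- lines[-atoms_after[atoms_after > second_model][1]]
  writeLines(lines, pdb)
  expect_error(read_trajectory(pdb), "frame 2")
})

test_that("assay tables are typed, unit-converted and validated", {
  f <- tempfile(fileext = ".csv")
  conc <- 10^seq(-10, -6, length.out = 8)
  writeLines(c(
    "ligand,pathway,construct,conc_M,response,replicate",
    sprintf("nalfurafine,Gprotein,WT,%.15g,%.15g,1", conc, seq(0.1, 1.5, length.out = 8))
  ), f)
  d <- read_assay_table(f, "dose_response")
  expect_equal(nrow(d), 8L)
  expect_equal(d$conc_M, conc)

  # nanomolar header divides by 1e9
  writeLines(c(
    "ligand,pathway,construct,conc_nM,response,replicate",
    "nalfurafine,Gprotein,WT,10,1.5,1"
  ), f)
  expect_equal(read_assay_table(f, "dose_response")$conc_M, 1e-8)

  # unknown unit suffix is an error, not a guess
  writeLines(c(
    "ligand,pathway,construct,conc_units,response,replicate",
    "nalfurafine,Gprotein,WT,10,1.5,1"
  ), f)
  expect_error(read_assay_table(f, "dose_response"), "unit|conc")

  # missing required column names the expectation
  writeLines(c("ligand,conc_M,response", "x,1e-9,1"), f)
  expect_error(read_assay_table(f, "dose_response"), "replicate")

  # non-numeric cell is reported with its row
  writeLines(c(
    "ligand,pathway,construct,conc_M,response,replicate",
    "nalfurafine,Gprotein,WT,1e-9,oops,1"
  ), f)
  expect_error(read_assay_table(f, "dose_response"), "row 1")
})

test_that("descending spectrum files are re-ordered ascending with values preserved", {
  f <- tempfile(fileext = ".csv")
  wn <- seq(1800, 1600, by = -2)
  ab <- seq_along(wn) / 10
  writeLines(c("wavenumber_cm-1,absorbance", sprintf("%g,%g", wn, ab)), f)
  d <- read_assay_table(f, "spectrum")
  expect_equal(d$wavenumber, rev(wn))
  expect_equal(d$absorbance, rev(ab))
})
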