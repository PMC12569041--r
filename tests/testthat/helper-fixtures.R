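# shared fixture builders; everything is generated in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal two-atom PDB text, coordinates chosen to exercise the fixed-width
# 0.001-A precision
minimal_pdb_lines <- function() {
  c(
    "ATOM      1  CA  SER A 153       1.234   2.345   3.456  1.00  0.00           C",
    "HETATM    2  C1  NLF L 401      -4.321   0.250  12.000  1.00  0.00           C",
    "END"
  )
}

write_minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(minimal_pdb_lines(), path)
  path
}

# absolute absorbance spectra for the ligand-exchange worked example:
# a shared protein/lipid envelope plus small state-specific component bands
ftir_band_tables <- function() {
  shared <- data.frame(
    center = c(1656, 1548, 1240),
    amplitude = c(1.0, 0.6, 0.3),
    fwhm = c(40, 35, 30)
  )
  list(
    naltrexone = rbind(shared, data.frame(
      center = c(1651, 2550, 1130), amplitude = c(0.02, 0.004, 0.001),
      fwhm = c(10, 12, 10)
    )),
    nalfurafine = rbind(shared, data.frame(
      center = c(1666, 2570, 1130), amplitude = c(0.02, 0.004, 0.003),
      fwhm = c(10, 12, 10)
    )),
    u50488h = rbind(shared, data.frame(
      center = c(1663, 2565, 1130), amplitude = c(0.02, 0.004, 0.001),
      fwhm = c(10, 12, 10)
    ))
  )
}

# one 4PL truth row
fourpl_truth <- function(ligand = "test", pathway = "Gprotein",
                         construct = "WT", top = 100, bottom = 0,
                         pec50 = 8, hill = 1) {
  data.frame(ligand = ligand, pathway = pathway, construct = construct,
             top = top, bottom = bottom, pec50 = pec50, hill = hill)
}

dr_concs <- function(n = 8, lo = -10.5, hi = -5.5) 10^seq(lo, hi, length.out = n)

# replicate-named 4PL fit lists for both pathways of one ligand
fit_ligand_pathways <- function(truths, concs = dr_concs(), n_rep = 3,
                                noise_sd = 0, seed = 1) {
  out <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    dd <- gen_dose_response(tr, concs, n_rep, noise_sd,
                            seed = seed + i)
    out[[tr$pathway]] <- fit_4pl_by_replicate(dd)
  }
  out
}

# brute-force all-pairs contact oracle, independent of the package's
# vectorized implementation
bruteforce_fingerprint <- function(trajectory, ligand_resname, cutoff) {
  at <- trajectory$topology$atoms
  lig <- which(at$is_hetero & at$residue_name == ligand_resname & at$element != "H")
  prot <- which(!at$is_hetero & at$element != "H")
  keys <- unique(paste(at$chain_id[prot], at$residue_number[prot]))
  hits <- setNames(numeric(length(keys)), keys)
  for (co in trajectory$frames) {
    for (key in keys) {
      idx <- prot[paste(at$chain_id[prot], at$residue_number[prot]) == key]
      mind <- Inf
      for (i in idx) for (j in lig) {
        mind <- min(mind, sqrt(sum((co[i, ] - co[j, ])^2)))
      }
      if (mind <= cutoff) hits[key] <- hits[key] + 1
    }
  }
  hits / length(trajectory$frames)
}
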