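#' Synthetic receptor backbone model
#'
#' Deterministically builds an idealized alpha-helical backbone (N, CA,
#' C, O per residue; 1.5 Angstrom rise and 100 degrees twist per residue)
#' as a stand-in receptor chain for superposition and RMSD exercises.
#' Purely geometric - no side chains, no physics.
#'
#' @param n_res number of residues.
#' @param chain_id chain identifier.
#' @param start_resno first author residue number.
#' @return a `structure_model`.
#' @export
gen_helix_model <- function(n_res = 100, chain_id = "R", start_resno = 55L) {
  assert_that(n_res >= 3L, "need at least 3 residues")
  rows <- list()
  for (i in seq_len(n_res)) {
    ang <- deg2rad(100 * (i - 1))
    z <- 1.5 * (i - 1)
    ca <- c(2.3 * cos(ang), 2.3 * sin(ang), z)
    # flanking backbone atoms offset along the local helix tangent
    n_at <- ca + c(0.8 * cos(ang - 0.5), 0.8 * sin(ang - 0.5), -0.6)
    c_at <- ca + c(0.8 * cos(ang + 0.5), 0.8 * sin(ang + 0.5), 0.6)
    o_at <- c_at + c(0.4 * cos(ang + 1.2), 0.4 * sin(ang + 1.2), 0.9)
    resno <- start_resno + i - 1L
    rows[[i]] <- data.frame(
      chain_id = chain_id, residue_number = resno, insert = "",
      residue_name = "ALA",
      atom_name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(n_at[1], ca[1], c_at[1], o_at[1]),
      y = c(n_at[2], ca[2], c_at[2], o_at[2]),
      z = c(n_at[3], ca[3], c_at[3], o_at[3]),
      is_hetero = FALSE
    )
  }
  new_structure_model(do.call(rbind, rows),
                      metadata = list(generator = "gen_helix_model"))
}

#' Rigidly transform and perturb a structure model
#'
#' Applies a rotation (degrees about the z axis), a translation, and
#' independent Gaussian coordinate noise - the synthetic analogue of
#' comparing two independently determined models of the same molecule.
#' With component noise s.d. `sigma`, the expected all-atom RMSD to the
#' original (after optimal re-superposition) is close to
#' `sqrt(3) * sigma`.
#'
#' @param model a `structure_model`.
#' @param rotate_z rotation about z in degrees.
#' @param translate 3-vector translation (Angstrom).
#' @param noise_sd per-component Gaussian noise s.d. (Angstrom).
#' @param seed integer seed.
#' @return perturbed `structure_model`.
#' @export
perturb_model <- function(model, rotate_z = 0, translate = c(0, 0, 0),
                          noise_sd = 0, seed = 1L) {
  th <- deg2rad(rotate_z)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  co <- as.matrix(model$atoms[, c("x", "y", "z")])
  co <- t(R %*% t(co)) + matrix(translate, nrow(co), 3, byrow = TRUE)
  if (noise_sd > 0) {
    co <- co + with_seed(seed, matrix(rnorm(length(co), 0, noise_sd), nrow(co), 3))
  }
  out <- model
  out$atoms$x <- co[, 1]; out$atoms$y <- co[, 2]; out$atoms$z <- co[, 3]
  out
}

#' Synthetic agonist binding-pocket model
#'
#' Builds a minimal synthetic stand-in for the TM7-side agonist pocket:
#' a tyrosine at position 312 (7.34) whose hydroxyl oxygen sits at a
#' prescribed distance from the nearest ligand heavy atom, a second
#' pocket residue, and a multi-atom hetero ligand. The prescribed
#' distance is realized exactly by construction, so measuring it back
#' through [named_distance()] is a recovery test, not a lookup.
#'
#' @param oh_ligand_distance target Y312-OH to nearest-ligand-heavy-atom
#'   distance (Angstrom).
#' @param ligand_resname hetero residue name for the ligand.
#' @param chain_id receptor chain.
#' @return a `structure_model` (synthetic; not a deposited structure).
#' @export
gen_pocket_model <- function(oh_ligand_distance = 3.3,
                             ligand_resname = "NLF", chain_id = "R") {
  assert_that(oh_ligand_distance > 0, "distance must be positive")
  oh <- c(0, 0, 0)
  u <- vunit(c(0.6, 0.5, 0.63))
  nearest <- oh + oh_ligand_distance * u
  prot <- data.frame(
    chain_id = chain_id,
    residue_number = c(312L, 312L, 312L, 138L, 138L),
    insert = "",
    residue_name = c("TYR", "TYR", "TYR", "ASP", "ASP"),
    atom_name = c("OH", "CZ", "CA", "CA", "OD1"),
    element = c("O", "C", "C", "C", "O"),
    x = c(oh[1], -1.4, -4.0, -6.0, -5.2),
    y = c(oh[2], 0.2, 1.0, -4.0, -3.1),
    z = c(oh[3], -0.3, -1.5, 2.0, 1.1),
    is_hetero = FALSE
  )
  lig <- data.frame(
    chain_id = "L",
    residue_number = 401L,
    insert = "",
    residue_name = ligand_resname,
    atom_name = c("C1", "C2", "N1", "O1"),
    element = c("C", "C", "N", "O"),
    x = c(nearest[1], nearest[1] + 1.5, nearest[1] + 2.4, nearest[1] + 1.1),
    y = c(nearest[2], nearest[2] + 0.4, nearest[2] + 1.6, nearest[2] - 1.2),
    z = c(nearest[3], nearest[3] + 0.8, nearest[3] + 0.2, nearest[3] + 1.9),
    is_hetero = TRUE
  )
  new_structure_model(rbind(prot, lig),
                      metadata = list(generator = "gen_pocket_model", synthetic = TRUE))
}
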