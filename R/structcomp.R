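#' Superpose two structure models (Kabsch)
#'
#' Matches residues by chain + author residue number (+ insertion code)
#' over the backbone atoms (N, CA, C, O by default) of the selected
#' chains, drops unpaired atoms pairwise with a logged count, and
#' computes the least-squares optimal rigid transform by the Kabsch/SVD
#' method (with determinant correction, so the rotation is always proper).
#'
#' @param mobile,target `structure_model`s.
#' @param chain_id optional chain restriction (e.g. the receptor chain,
#'   excluding G-protein and scFv chains).
#' @param atom_names atoms used for matching (default backbone).
#' @param residue_range optional `c(lo, hi)` author-number window.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_pairs`, `n_dropped`,
#'   `selection` description.
#' @export
superpose <- function(mobile, target, chain_id = NULL,
                      atom_names = c("N", "CA", "C", "O"),
                      residue_range = NULL) {
  pick <- function(model) {
    at <- model$atoms
    sel <- !at$is_hetero & at$atom_name %in% atom_names & at$element != "H"
    if (!is.null(chain_id)) sel <- sel & at$chain_id %in% chain_id
    if (!is.null(residue_range)) {
      sel <- sel & at$residue_number >= residue_range[1] &
        at$residue_number <= residue_range[2]
    }
    at <- at[sel, , drop = FALSE]
    key <- paste(at$chain_id, at$residue_number, at$insert, at$atom_name)
    list(atoms = at, key = key)
  }
  a <- pick(mobile)
  b <- pick(target)
  common <- intersect(a$key, b$key)
  n_dropped <- (length(a$key) - length(common)) + (length(b$key) - length(common))
  assert_that(length(common) >= 3L,
              "fewer than 3 matched atom pairs (found %d)", length(common))
  X <- as.matrix(a$atoms[match(common, a$key), c("x", "y", "z")])
  Y <- as.matrix(b$atoms[match(common, b$key), c("x", "y", "z")])
  kab <- kabsch(X, Y)
  assert_that(!is.null(kab), "matched atoms are collinear; superposition undefined")
  structure(
    list(
      rotation = kab$R, translation = kab$t, rmsd = kab$rmsd,
      n_pairs = length(common), n_dropped = n_dropped,
      selection = sprintf(
        "backbone {%s}%s%s, residues matched by chain+author number",
        paste(atom_names, collapse = ","),
        if (is.null(chain_id)) "" else paste0(", chain ", paste(chain_id, collapse = "/")),
        if (is.null(residue_range)) "" else
          sprintf(", residues %d-%d", residue_range[1], residue_range[2])
      )
    ),
    class = "superposition"
  )
}

# least-squares rigid transform Y ~ R X + t; returns NULL for degenerate
# (collinear) point sets
kabsch <- function(X, Y) {
  xc <- colMeans(X)
  yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc)
  Yc <- sweep(Y, 2, yc)
  # collinearity check: rank of the centered coordinates
  if (sum(svd(Xc)$d > 1e-8) < 2L) return(NULL)
  H <- t(Xc) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- unname(yc - as.numeric(R %*% xc))
  fitted <- t(R %*% t(X)) + matrix(t_vec, nrow(X), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d atom pairs (%d dropped); %s\n",
              x$rmsd, x$n_pairs, x$n_dropped, x$selection))
  invisible(x)
}

#' Apply a superposition transform to a structure model
#' @param model a `structure_model`.
#' @param sup a `superposition`.
#' @return transformed `structure_model`.
#' @export
apply_superposition <- function(model, sup) {
  co <- as.matrix(model$atoms[, c("x", "y", "z")])
  co2 <- t(sup$rotation %*% t(co)) +
    matrix(sup$translation, nrow(co), 3, byrow = TRUE)
  out <- model
  out$atoms$x <- co2[, 1]; out$atoms$y <- co2[, 2]; out$atoms$z <- co2[, 3]
  out
}

#' Per-residue minimum heavy-atom distance to a ligand
#'
#' @param model a `structure_model` containing the ligand as a hetero
#'   residue.
#' @param ligand_resname ligand residue name.
#' @param cutoff contact cutoff in Angstrom (default 4.0, the
#'   stick-display convention for binding-pocket figures).
#' @return data frame: `chain_id`, `residue_number`, `residue_name`,
#'   `min_distance`, `within_cutoff`.
#' @export
residue_ligand_contacts <- function(model, ligand_resname, cutoff = 4.0) {
  at <- model$atoms
  lig <- which(at$is_hetero & at$residue_name == ligand_resname & at$element != "H")
  assert_that(length(lig) >= 1L,
              "ligand '%s' not found; hetero residues present: %s",
              ligand_resname,
              paste(unique(at$residue_name[at$is_hetero]), collapse = ", "))
  prot <- which(!at$is_hetero & at$element != "H")
  assert_that(length(prot) >= 1L, "no protein heavy atoms in model")
  p <- as.matrix(at[prot, c("x", "y", "z")])
  l <- as.matrix(at[lig, c("x", "y", "z")])
  d2 <- outer(rowSums(p^2), rowSums(l^2), "+") - 2 * (p %*% t(l))
  min_d <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- paste(at$chain_id[prot], at$residue_number[prot], at$insert[prot])
  res_min <- tapply(min_d, key, min)
  first <- prot[!duplicated(key)]
  ord_key <- key[!duplicated(key)]
  data.frame(
    chain_id = at$chain_id[first],
    residue_number = at$residue_number[first],
    residue_name = at$residue_name[first],
    min_distance = unname(res_min[ord_key]),
    within_cutoff = unname(res_min[ord_key]) <= cutoff,
    stringsAsFactors = FALSE
  )
}

#' Distance between a named atom and another atom or the nearest ligand
#' heavy atom
#'
#' @param model a `structure_model`.
#' @param residue_number,atom_name,chain_id spec of atom A (e.g. the
#'   Y312 7.34 hydroxyl: residue 312, atom `"OH"`).
#' @param to either a list(`residue_number`, `atom_name`, `chain_id`) for
#'   an explicit atom B, or a ligand residue name: the distance to the
#'   ligand's nearest heavy atom is returned.
#' @return distance in Angstrom (full precision; round to 0.1 A in
#'   summaries).
#' @export
named_distance <- function(model, residue_number, atom_name, to,
                           chain_id = NULL) {
  a <- select_atom(model, residue_number, atom_name, chain_id)
  pa <- as.numeric(a[, c("x", "y", "z")])
  if (is.list(to)) {
    b <- select_atom(model, to$residue_number, to$atom_name, to$chain_id %||% NULL)
    return(point_distance(pa, as.numeric(b[, c("x", "y", "z")])))
  }
  at <- model$atoms
  lig <- which(at$is_hetero & at$residue_name == to & at$element != "H")
  assert_that(length(lig) >= 1L,
              "ligand '%s' not found; hetero residues present: %s",
              to, paste(unique(at$residue_name[at$is_hetero]), collapse = ", "))
  l <- as.matrix(at[lig, c("x", "y", "z")])
  min(sqrt(rowSums(sweep(l, 2, pa)^2)))
}
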