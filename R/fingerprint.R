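#' Ligand-residue interaction fingerprint
#'
#' For each protein residue, the fraction of frames in which any of its
#' heavy atoms lies within `cutoff` of any ligand heavy atom (inclusive
#' boundary, <=). This is the distance-only reading of an interaction
#' fingerprint at the conventional 6 Angstrom cutoff; interaction-type
#' subclassification (H-bonds, pi-stacking) is out of scope.
#'
#' @param trajectory a `kor_trajectory`.
#' @param ligand_resname residue name of the ligand (hetero records).
#' @param cutoff contact distance in Angstrom (default 6.0).
#' @return a `contact_fingerprint`: data frame (`chain_id`,
#'   `residue_number`, `residue_name`, `frequency`) with the cutoff and
#'   frame count as attributes.
#' @export
contact_fingerprint <- function(trajectory, ligand_resname, cutoff = 6.0) {
  at <- trajectory$topology$atoms
  lig <- which(at$is_hetero & at$residue_name == ligand_resname & at$element != "H")
  assert_that(
    length(lig) >= 1L,
    "no heavy atoms found for ligand '%s'; hetero residues present: %s",
    ligand_resname,
    paste(unique(at$residue_name[at$is_hetero]), collapse = ", ")
  )
  prot <- which(!at$is_hetero & at$element != "H")
  assert_that(length(prot) >= 1L, "no protein heavy atoms in topology")
  res_key <- paste(at$chain_id[prot], at$residue_number[prot], at$insert[prot])
  res_levels <- unique(res_key)
  res_group <- match(res_key, res_levels)
  n_res <- length(res_levels)
  contact_frames <- integer(n_res)
  for (co in trajectory$frames) {
    p <- co[prot, , drop = FALSE]
    l <- co[lig, , drop = FALSE]
    # squared distances protein-heavy x ligand-heavy
    d2 <- outer(rowSums(p^2), rowSums(l^2), "+") - 2 * (p %*% t(l))
    min_d2 <- apply(d2, 1L, min)
    res_min <- tapply(min_d2, res_group, min)
    hit <- sqrt(pmax(res_min, 0)) <= cutoff
    contact_frames[as.integer(names(res_min))[hit]] <-
      contact_frames[as.integer(names(res_min))[hit]] + 1L
  }
  first <- prot[!duplicated(res_group)]
  out <- data.frame(
    chain_id = at$chain_id[first],
    residue_number = at$residue_number[first],
    residue_name = at$residue_name[first],
    frequency = contact_frames / length(trajectory$frames),
    stringsAsFactors = FALSE
  )
  structure(out,
    cutoff = cutoff, n_frames = length(trajectory$frames),
    class = c("contact_fingerprint", "data.frame")
  )
}

#' Wild-type minus mutant fingerprint difference
#'
#' Per-residue `wt - mutant` contact frequency over the union of residues
#' (a residue absent from one fingerprint contributes frequency 0).
#' Positive values mean the mutation reduced the interaction; negative
#' values mean it increased it.
#'
#' @param wt,mutant `contact_fingerprint` objects computed at the same
#'   cutoff.
#' @return data frame with `residue_number`, `residue_name`, `delta`.
#' @export
delta_fingerprint <- function(wt, mutant) {
  assert_that(
    isTRUE(all.equal(attr(wt, "cutoff"), attr(mutant, "cutoff"))),
    "fingerprints were computed at different cutoffs (%.2f vs %.2f)",
    attr(wt, "cutoff"), attr(mutant, "cutoff")
  )
  key <- function(fp) paste(fp$chain_id, fp$residue_number)
  all_keys <- union(key(wt), key(mutant))
  freq_of <- function(fp) {
    f <- setNames(fp$frequency, key(fp))
    out <- setNames(numeric(length(all_keys)), all_keys)
    out[names(f)] <- f
    out
  }
  fw <- freq_of(wt)
  fm <- freq_of(mutant)
  name_src <- rbind(
    data.frame(k = key(wt), chain_id = wt$chain_id,
               residue_number = wt$residue_number, residue_name = wt$residue_name),
    data.frame(k = key(mutant), chain_id = mutant$chain_id,
               residue_number = mutant$residue_number, residue_name = mutant$residue_name)
  )
  name_src <- name_src[!duplicated(name_src$k), ]
  name_src <- name_src[match(all_keys, name_src$k), ]
  data.frame(
    chain_id = name_src$chain_id,
    residue_number = name_src$residue_number,
    residue_name = name_src$residue_name,
    delta = unname(fw - fm),
    stringsAsFactors = FALSE
  )
}
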