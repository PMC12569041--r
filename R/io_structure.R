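#' Structure and trajectory containers
#'
#' A `structure_model` is a list with an `atoms` data frame (one row per
#' atom: `chain_id`, `residue_number`, `insert`, `residue_name`,
#' `atom_name`, `element`, `x`, `y`, `z`, `is_hetero`), an integer
#' `model_id` and a free-form `metadata` list. Coordinates are in Angstrom
#' and residue numbers follow author numbering throughout; no renumbering
#' is ever applied. A `kor_trajectory` couples one topology model with an
#' ordered list of per-frame coordinate matrices (n_atoms x 3).
#'
#' @name structure-containers
NULL

new_structure_model <- function(atoms, model_id = 1L, metadata = list()) {
  required <- c(
    "chain_id", "residue_number", "insert", "residue_name",
    "atom_name", "element", "x", "y", "z", "is_hetero"
  )
  assert_that(
    all(required %in% names(atoms)),
    "atoms table is missing columns: %s",
    paste(setdiff(required, names(atoms)), collapse = ", ")
  )
  assert_that(nrow(atoms) >= 1L, "a structure model must contain at least one atom")
  assert_that(
    all(is.finite(atoms$x)) && all(is.finite(atoms$y)) && all(is.finite(atoms$z)),
    "non-finite coordinates in atoms table"
  )
  assert_that(all(nzchar(atoms$atom_name)), "empty atom_name in atoms table")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insert, atoms$atom_name)
  dup <- duplicated(key)
  assert_that(
    !any(dup),
    "duplicate atom identity within model (first: %s)", key[which(dup)[1]]
  )
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, model_id = as.integer(model_id), metadata = metadata),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d atoms, %d residues, chains: %s\n",
    nrow(x$atoms),
    nrow(unique(x$atoms[, c("chain_id", "residue_number", "insert")])),
    paste(unique(x$atoms$chain_id), collapse = ", ")
  ))
  invisible(x)
}

# derive the element symbol from a PDB atom name when the element column
# is blank (common in minimal fixtures)
guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", atom_name)
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")
  up <- toupper(nm)
  ifelse(substr(up, 1, 2) %in% two, substr(up, 1, 2), substr(up, 1, 1))
}

bio3d_to_atoms <- function(atom_df) {
  alt <- atom_df$alt
  alt[is.na(alt)] <- ""
  # first altloc only: among alternates of the same atom keep the first row
  key <- paste(atom_df$chain, atom_df$resno, atom_df$insert, atom_df$elety)
  keep <- !duplicated(key)
  atom_df <- atom_df[keep, , drop = FALSE]
  ins <- atom_df$insert
  ins[is.na(ins)] <- ""
  elem <- atom_df$elesy
  if (is.null(elem)) elem <- rep("", nrow(atom_df))
  elem[is.na(elem) | !nzchar(elem)] <-
    guess_element(atom_df$elety[is.na(elem) | !nzchar(elem)])
  chain <- atom_df$chain
  chain[is.na(chain)] <- ""
  data.frame(
    chain_id = chain,
    residue_number = as.integer(atom_df$resno),
    insert = ins,
    residue_name = atom_df$resid,
    atom_name = atom_df$elety,
    element = toupper(elem),
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    is_hetero = atom_df$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

#' Read a structure model from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}; the result is converted to the
#' package's atom table. Hetero records (ligands, waters) are retained and
#' flagged `is_hetero`. Only the first alternate location of each atom is
#' kept; insertion codes are part of the residue identity.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param model model index to extract from a multi-model file (default 1).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), model = 1L) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, verbose = FALSE, multi = TRUE)
    },
    error = function(e) stopf("cannot parse %s file '%s': %s", format, path, conditionMessage(e))
  )
  assert_that(
    !is.null(parsed$atom) && nrow(parsed$atom) >= 1L,
    "no ATOM/HETATM records in '%s'", path
  )
  atoms <- bio3d_to_atoms(parsed$atom)
  n_models <- max(1L, nrow(parsed$xyz))
  assert_that(
    model >= 1L && model <= n_models,
    "model index %d out of range (file has %d model(s))", model, n_models
  )
  if (model > 1L) {
    co <- matrix(parsed$xyz[model, ], ncol = 3L, byrow = TRUE)
    # bio3d keeps all altlocs in xyz; map through the same filter
    keep <- !duplicated(paste(
      parsed$atom$chain, parsed$atom$resno, parsed$atom$insert, parsed$atom$elety
    ))
    co <- co[keep, , drop = FALSE]
    atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
  }
  new_structure_model(atoms, model_id = model, metadata = list(source = path, format = format))
}

new_trajectory <- function(topology, frames, frame_interval = NA_real_) {
  assert_that(inherits(topology, "structure_model"), "topology must be a structure_model")
  assert_that(length(frames) >= 1L, "a trajectory needs at least one frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    assert_that(
      is.matrix(fr) && ncol(fr) == 3L && nrow(fr) == n,
      "frame %d has %d atoms; topology has %d", i, NROW(frames[[i]]), n
    )
  }
  structure(
    list(topology = topology, frames = frames, frame_interval = frame_interval),
    class = "kor_trajectory"
  )
}

#' @export
print.kor_trajectory <- function(x, ...) {
  cat(sprintf(
    "<kor_trajectory> %d frames x %d atoms\n",
    length(x$frames), nrow(x$topology$atoms)
  ))
  invisible(x)
}

n_frames <- function(trajectory) length(trajectory$frames)

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    assert_that(
      !is.na(nat) && nat > 0L,
      "malformed XYZ atom-count line %d in '%s'", i, path
    )
    assert_that(
      i + 1L + nat <= length(lines),
      "truncated XYZ frame starting at line %d in '%s'", i, path
    )
    block <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(block), "\\s+")
    co <- t(vapply(
      fields,
      function(f) {
        assert_that(length(f) >= 4L, "malformed XYZ atom line in '%s'", path)
        as.numeric(f[2:4])
      },
      numeric(3)
    ))
    assert_that(all(is.finite(co)), "non-numeric coordinate in XYZ file '%s'", path)
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + nat
  }
  assert_that(length(frames) >= 1L, "no frames found in XYZ file '%s'", path)
  frames
}

# count atoms in each MODEL block so a mismatch is reported with its frame
# index before the heavyweight parser runs
pdb_model_atom_counts <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(NULL)
  ends <- grep("^ENDMDL", lines)
  assert_that(
    length(ends) == length(starts),
    "unbalanced MODEL/ENDMDL records"
  )
  vapply(seq_along(starts), function(k) {
    sum(grepl("^(ATOM  |HETATM)", lines[starts[k]:ends[k]]))
  }, integer(1))
}

#' Read a trajectory from a multi-model PDB or an XYZ series
#'
#' @param paths one multi-model PDB path, or one or more XYZ paths whose
#'   frames are concatenated in order.
#' @param topology a `structure_model` supplying atom identities; required
#'   for XYZ input, defaults to the first model for multi-model PDB.
#' @param frame_interval informational time between frames.
#' @return a `kor_trajectory`.
#' @export
read_trajectory <- function(paths, topology = NULL, frame_interval = NA_real_) {
  assert_that(length(paths) >= 1L, "no input paths given")
  ext <- tolower(tools::file_ext(paths[1]))
  if (ext == "xyz") {
    assert_that(
      inherits(topology, "structure_model"),
      "XYZ trajectories need an explicit topology structure_model"
    )
    frames <- do.call(c, lapply(paths, read_xyz_frames))
    n <- nrow(topology$atoms)
    for (i in seq_along(frames)) {
      assert_that(
        nrow(frames[[i]]) == n,
        "frame %d has %d atoms but topology has %d", i, nrow(frames[[i]]), n
      )
    }
    return(new_trajectory(topology, frames, frame_interval))
  }
  assert_that(length(paths) == 1L, "multi-model PDB input must be a single file")
  lines <- readLines(paths[1])
  counts <- pdb_model_atom_counts(lines)
  if (!is.null(counts) && length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stopf(
      "frame %d of '%s' has %d atoms; frame 1 has %d",
      bad, paths[1], counts[bad], counts[1]
    )
  }
  parsed <- tryCatch(
    bio3d::read.pdb(paths[1], verbose = FALSE, multi = TRUE),
    error = function(e) stopf("cannot parse PDB file '%s': %s", paths[1], conditionMessage(e))
  )
  assert_that(nrow(parsed$atom) >= 1L, "no ATOM/HETATM records in '%s'", paths[1])
  atoms <- bio3d_to_atoms(parsed$atom)
  topo <- topology %||%
    new_structure_model(atoms, metadata = list(source = paths[1]))
  nmod <- nrow(parsed$xyz)
  keep <- !duplicated(paste(
    parsed$atom$chain, parsed$atom$resno, parsed$atom$insert, parsed$atom$elety
  ))
  frames <- lapply(seq_len(nmod), function(k) {
    co <- matrix(parsed$xyz[k, ], ncol = 3L, byrow = TRUE)
    co[keep, , drop = FALSE]
  })
  new_trajectory(topo, frames, frame_interval)
}

pdb_atom_line <- function(serial, a) {
  name <- a$atom_name
  # PDB columns 13-16: names shorter than 4 start in column 14
  name <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    if (a$is_hetero) "HETATM" else "ATOM", serial, name, "",
    a$residue_name, a$chain_id, a$residue_number, a$insert,
    a$x, a$y, a$z, 1, 0, a$element
  )
}

#' Write a structure model to PDB or minimal mmCIF
#'
#' The mmCIF writer emits a plain `atom_site` loop (no deposition
#' metadata); it exists so that format round-trips can be exercised.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  at <- model$atoms
  if (format == "pdb") {
    lines <- vapply(
      seq_len(nrow(at)),
      function(i) pdb_atom_line(i, at[i, ]),
      character(1)
    )
    writeLines(c(lines, "END"), path)
  } else {
    ins <- ifelse(nzchar(at$insert), at$insert, "?")
    rows <- sprintf(
      "%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      ifelse(at$is_hetero, "HETATM", "ATOM"), seq_len(nrow(at)),
      at$element, at$atom_name, at$residue_name, at$chain_id,
      at$residue_number, ins, at$x, at$y, at$z,
      at$residue_number, at$residue_name, at$chain_id, at$atom_name
    )
    writeLines(c(
      "data_korbias",
      "#",
      "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
        "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
        "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
      )),
      rows,
      "#"
    ), path)
  }
  invisible(path)
}

#' Write a trajectory as a multi-model PDB or an XYZ series
#'
#' @param trajectory a `kor_trajectory`.
#' @param path output path.
#' @param format `"pdb"` (MODEL/ENDMDL blocks) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  at <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(trajectory$frames)) {
    co <- trajectory$frames[[k]]
    if (format == "pdb") {
      writeLines(sprintf("MODEL     %4d", k), con)
      a <- at
      a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
      writeLines(
        vapply(seq_len(nrow(a)), function(i) pdb_atom_line(i, a[i, ]), character(1)),
        con
      )
      writeLines("ENDMDL", con)
    } else {
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("frame %d", k), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", at$element, co[, 1], co[, 2], co[, 3]), con)
    }
  }
  if (format == "pdb") writeLines("END", con)
  invisible(path)
}

#' Select one atom row from a structure model
#'
#' @param model a `structure_model`.
#' @param residue_number author residue number.
#' @param atom_name atom name, e.g. `"CA"`, `"CZ"`, `"OH"`.
#' @param chain_id chain, or `NULL` to match any single chain.
#' @return one-row data frame of the atom.
#' @export
select_atom <- function(model, residue_number, atom_name, chain_id = NULL) {
  at <- model$atoms
  hit <- at$residue_number == residue_number & at$atom_name == atom_name
  if (!is.null(chain_id)) hit <- hit & at$chain_id == chain_id
  idx <- which(hit)
  assert_that(
    length(idx) >= 1L,
    "atom %s of residue %s%s not found",
    atom_name, residue_number, if (is.null(chain_id)) "" else paste0(" (chain ", chain_id, ")")
  )
  assert_that(
    length(idx) == 1L,
    "atom %s of residue %d is ambiguous across chains; give chain_id",
    atom_name, residue_number
  )
  at[idx, , drop = FALSE]
}

# row index version used by trajectory featurization (coordinates come from
# frames, identity from topology)
atom_index <- function(model, residue_number, atom_name, chain_id = NULL) {
  as.integer(rownames(select_atom(model, residue_number, atom_name, chain_id)))
}
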