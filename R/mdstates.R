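#' Default marker-residue map
#'
#' Reads the packaged map of Ballesteros-Weinstein markers (S153 = 3.47,
#' R156 = 3.50, Y330 = 7.53) in author numbering. Supply your own list of
#' the same shape for renumbered constructs: features are invariant under
#' renumbering as long as the map points at the same atoms.
#'
#' @return named list with `S153`, `R156`, `Y330`, each `list(chain, resno)`.
#' @export
default_residue_map <- function() {
  yaml::read_yaml(
    system.file("extdata", "residue_map.yaml", package = "korbias")
  )
}

#' Featurize a trajectory into the state-classification coordinates
#'
#' Per frame: `d`, the distance from the 3.47 Calpha to the 7.53 Czeta;
#' `chi`, the C-Ca-Cg-Cz dihedral of the 7.53 tyrosine (degrees,
#' (-180, 180]); and `r_down`, whether the 3.50 arginine side chain
#' (Ca -> Cz) points intracellularly relative to the membrane normal.
#'
#' @param trajectory a `kor_trajectory` whose topology contains the marker
#'   atoms.
#' @param residue_map marker map as from [default_residue_map()].
#' @param normal membrane normal, +z = extracellular.
#' @param threshold orientation angle threshold in degrees.
#' @return data frame with one row per frame: `frame`, `d`, `chi`, `r_down`.
#' @export
featurize <- function(trajectory, residue_map = default_residue_map(),
                      normal = c(0, 0, 1), threshold = 90) {
  topo <- trajectory$topology
  idx <- function(res, atom) {
    atom_index(topo, res$resno, atom, res$chain)
  }
  i_s_ca <- idx(residue_map$S153, "CA")
  i_y_c <- idx(residue_map$Y330, "C")
  i_y_ca <- idx(residue_map$Y330, "CA")
  i_y_cg <- idx(residue_map$Y330, "CG")
  i_y_cz <- idx(residue_map$Y330, "CZ")
  i_r_ca <- idx(residue_map$R156, "CA")
  i_r_cz <- idx(residue_map$R156, "CZ")
  out <- lapply(seq_along(trajectory$frames), function(k) {
    co <- trajectory$frames[[k]]
    c(
      d = point_distance(co[i_s_ca, ], co[i_y_cz, ]),
      chi = torsion_angle(co[i_y_c, ], co[i_y_ca, ], co[i_y_cg, ], co[i_y_cz, ]),
      r_down = as.numeric(r_orientation(co[i_r_ca, ], co[i_r_cz, ], normal, threshold))
    )
  })
  out <- as.data.frame(do.call(rbind, out))
  data.frame(
    frame = seq_along(trajectory$frames),
    d = out$d, chi = out$chi, r_down = as.logical(out$r_down)
  )
}

# membership of chi values in a possibly wrapped half-open interval
chi_in <- function(chi, lo, hi) {
  if (lo < hi) chi >= lo & chi < hi else chi >= lo | chi < hi
}

#' Classify frames into conformational states
#'
#' Each frame is assigned the base state whose (d, chi) region contains
#' it, then sub-labelled A/B by `r_down` where the scheme splits that base
#' state. Frames outside every region get the first-class label
#' `UNASSIGNED`, so population fractions conserve exactly.
#'
#' @param features data frame from [featurize()] (`d`, `chi`, `r_down`).
#' @param boundaries a `state_boundaries` object.
#' @return character vector of labels, one per row of `features`.
#' @export
classify <- function(features, boundaries = default_state_boundaries()) {
  assert_that(inherits(boundaries, "state_boundaries"), "boundaries must be a state_boundaries object")
  assert_that(
    all(c("d", "chi", "r_down") %in% names(features)),
    "features must have columns d, chi, r_down"
  )
  base <- rep(NA_integer_, nrow(features))
  rg <- boundaries$regions
  for (i in seq_len(nrow(rg))) {
    hit <- features$d >= rg$d_min[i] & features$d < rg$d_max[i] &
      chi_in(features$chi, rg$chi_min[i], rg$chi_max[i])
    base[hit] <- rg$base[i]
  }
  lab <- ifelse(
    is.na(base),
    "UNASSIGNED",
    ifelse(
      base %in% boundaries$split_by_r,
      paste0("S", base, ifelse(features$r_down, "A", "B")),
      paste0("S", base)
    )
  )
  lab
}

#' State population table
#'
#' Computes pooled state fractions across replicates, per-replicate
#' fractions, and per-base-state proportions of frames with the 3.50
#' arginine facing intracellularly. The study legend reports pooled
#' percentages; whether pooling or per-replicate averaging was used is not
#' stated, so both are emitted (pooled equals the frame-weighted mean of
#' the per-replicate fractions).
#'
#' @param labels character labels from [classify()].
#' @param r_down logical orientation flags (one per frame).
#' @param replicate replicate identifier per frame (default: single pool).
#' @param boundaries boundary scheme used, for the label enumeration.
#' @return list with `pooled`, `per_replicate`, `r_down_by_base`,
#'   `n_frames`, `boundary_hash`.
#' @export
state_populations <- function(labels, r_down,
                              replicate = rep(1L, length(labels)),
                              boundaries = default_state_boundaries()) {
  assert_that(length(labels) >= 1L, "no labeled frames")
  assert_that(
    length(r_down) == length(labels) && length(replicate) == length(labels),
    "labels, r_down and replicate must have equal length"
  )
  all_labels <- state_labels(boundaries, include_unassigned = TRUE)
  frac <- function(lab) {
    tab <- table(factor(lab, levels = all_labels))
    as.numeric(tab) / length(lab) -> f
    setNames(f, all_labels)
  }
  pooled <- frac(labels)
  reps <- split(seq_along(labels), replicate)
  per_replicate <- do.call(rbind, lapply(names(reps), function(r) {
    data.frame(
      replicate = r, label = all_labels,
      fraction = unname(frac(labels[reps[[r]]])),
      n_frames = length(reps[[r]])
    )
  }))
  base <- suppressWarnings(as.integer(sub("^S([0-9]).*$", "\\1", labels)))
  bases <- sort(unique(base[!is.na(base)]))
  r_down_by_base <- vapply(bases, function(b) {
    mean(r_down[!is.na(base) & base == b])
  }, numeric(1))
  names(r_down_by_base) <- if (length(bases)) paste0("S", bases) else character(0)
  list(
    pooled = pooled,
    per_replicate = per_replicate,
    r_down_by_base = r_down_by_base,
    n_frames = length(labels),
    boundary_hash = boundaries$source_hash
  )
}

#' 2-D occupancy histogram over the (d, chi) plane
#'
#' Counts frames in half-open bins `[lo, hi)`; a feature exactly on an
#' interior edge falls in the upper bin. Features outside the grid are not
#' counted.
#'
#' @param features data frame with `d` and `chi`.
#' @param d_breaks,chi_breaks ascending bin edges.
#' @return integer matrix (d bins x chi bins) with `dimnames` giving the
#'   lower edges.
#' @export
occupancy_histogram <- function(features, d_breaks, chi_breaks) {
  assert_that(
    length(d_breaks) >= 2L && length(chi_breaks) >= 2L,
    "need at least two bin edges per axis"
  )
  assert_that(
    !is.unsorted(d_breaks, strictly = TRUE) && !is.unsorted(chi_breaks, strictly = TRUE),
    "bin edges must be strictly ascending"
  )
  di <- findInterval(features$d, d_breaks)
  ci <- findInterval(features$chi, chi_breaks)
  nd <- length(d_breaks) - 1L
  nc <- length(chi_breaks) - 1L
  ok <- di >= 1L & di <= nd & ci >= 1L & ci <= nc
  grid <- matrix(0L, nd, nc,
    dimnames = list(
      d = format(d_breaks[-length(d_breaks)]),
      chi = format(chi_breaks[-length(chi_breaks)])
    )
  )
  for (k in which(ok)) grid[di[k], ci[k]] <- grid[di[k], ci[k]] + 1L
  grid
}
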