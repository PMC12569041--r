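#' Conformational state boundaries
#'
#' The six-state scheme partitions the (d, chi) plane - d the
#' S153(3.47) Calpha to Y330(7.53) Czeta distance, chi the C-Ca-Cg-Cz
#' dihedral of Y330(7.53) - into four base regions; the base states listed
#' in `split_by_r` (default 2 and 3) are sub-labelled A/B by the R156(3.50)
#' orientation flag. Regions use half-open intervals `[lo, hi)`; chi
#' intervals may wrap across +/-180 (declared as `chi_min > chi_max`).
#' Regions must be pairwise disjoint: overlap is a configuration error,
#' not a runtime tie-break.
#'
#' Numeric boundaries are not printed in the source study (the state
#' clusters appear only as heatmaps), so they ship as a required
#' configuration; the packaged default is annotated as a qualitative
#' reading of those clusters. Reports record the config file's MD5 hash.
#'
#' @name state-boundaries
NULL

# expand a possibly wrapped chi interval into plain subintervals on
# [-180, 180]
chi_subintervals <- function(lo, hi) {
  if (lo < hi) list(c(lo, hi)) else list(c(lo, 180), c(-180, hi))
}

new_state_boundaries <- function(regions, split_by_r = c(2L, 3L), source_hash = NA_character_) {
  required <- c("base", "d_min", "d_max", "chi_min", "chi_max")
  assert_that(
    all(required %in% names(regions)),
    "regions table needs columns: %s", paste(required, collapse = ", ")
  )
  assert_that(nrow(regions) >= 1L, "at least one state region is required")
  assert_that(all(regions$base %in% 1:4), "base state labels must be in 1..4")
  assert_that(all(regions$d_min < regions$d_max), "empty d interval in boundaries")
  assert_that(
    all(regions$chi_min != regions$chi_max),
    "empty chi interval in boundaries"
  )
  # pairwise disjointness (wrap-aware on chi)
  n <- nrow(regions)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d_overlap <- regions$d_min[i] < regions$d_max[j] &&
          regions$d_min[j] < regions$d_max[i]
        if (!d_overlap) next
        ci <- chi_subintervals(regions$chi_min[i], regions$chi_max[i])
        cj <- chi_subintervals(regions$chi_min[j], regions$chi_max[j])
        for (a in ci) for (b in cj) {
          assert_that(
            !(a[1] < b[2] && b[1] < a[2]),
            "state regions %d and %d overlap; boundaries must be disjoint", i, j
          )
        }
      }
    }
  }
  structure(
    list(
      regions = regions,
      split_by_r = as.integer(split_by_r),
      source_hash = source_hash
    ),
    class = "state_boundaries"
  )
}

#' Read a state-boundary configuration from YAML
#'
#' @param path YAML file with a `states` list (`base`, `d`, `chi` interval
#'   pairs) and a `split_by_r` vector; see the packaged default
#'   `system.file("extdata", "state_boundaries.yaml", package = "korbias")`.
#' @return a `state_boundaries` object carrying the file's MD5 hash.
#' @export
read_state_boundaries <- function(path) {
  assert_that(file.exists(path), "boundary config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$states), "boundary config has no 'states' entry")
  regions <- do.call(rbind, lapply(cfg$states, function(s) {
    data.frame(
      base = as.integer(s$base),
      d_min = s$d[[1]], d_max = s$d[[2]],
      chi_min = s$chi[[1]], chi_max = s$chi[[2]]
    )
  }))
  new_state_boundaries(
    regions,
    split_by_r = as.integer(cfg$split_by_r %||% c(2L, 3L)),
    source_hash = unname(tools::md5sum(path))
  )
}

#' Default packaged state boundaries
#' @return a `state_boundaries` object.
#' @export
default_state_boundaries <- function() {
  read_state_boundaries(
    system.file("extdata", "state_boundaries.yaml", package = "korbias")
  )
}

#' Enumerate the labels a boundary scheme can produce
#'
#' @param boundaries a `state_boundaries` object.
#' @param include_unassigned include the `UNASSIGNED` catch-all label.
#' @return character vector of labels, e.g. `S1 S2A S2B S3A S3B S4`.
#' @export
state_labels <- function(boundaries, include_unassigned = FALSE) {
  bases <- sort(unique(boundaries$regions$base))
  labs <- unlist(lapply(bases, function(b) {
    if (b %in% boundaries$split_by_r) paste0("S", b, c("A", "B")) else paste0("S", b)
  }))
  if (include_unassigned) labs <- c(labs, "UNASSIGNED")
  labs
}

#' @export
print.state_boundaries <- function(x, ...) {
  cat(sprintf(
    "<state_boundaries> %d regions, split by R3.50: %s, labels: %s\n",
    nrow(x$regions), paste(x$split_by_r, collapse = ","),
    paste(state_labels(x, TRUE), collapse = " ")
  ))
  invisible(x)
}
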