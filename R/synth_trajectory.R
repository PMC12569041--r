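#' Synthetic state-resolved trajectory generator
#'
#' Builds a marker-atom trajectory whose frames realize prescribed
#' feature values exactly, by analytic construction rather than physics:
#' the four dihedral atoms of Y330 (7.53) are placed with fixed bond
#' lengths/angles and the prescribed torsion, the S153 (3.47) Calpha is
#' placed on the sphere of the prescribed distance about the Y330 Czeta,
#' and the R156 (3.50) Czeta is placed above or below its Calpha along
#' the membrane normal (+z = extracellular) according to the orientation
#' draw. Featurization is therefore exactly invertible and the classifier
#' recovers the generated labels whenever the targets sit strictly inside
#' the state regions.
#'
#' @param spec named list keyed by state label (e.g. `S1`, `S3A`); each
#'   entry is a list with `n` (frame count) and optionally `d` and `chi`
#'   target ranges (defaults: the state's region shrunk by 10\% per side)
#'   and `p_down`, the probability that R3.50 faces intracellular
#'   (defaults: 1 for A substates, 0 for B substates and unsplit states).
#' @param boundaries a `state_boundaries` object the targets are
#'   validated against.
#' @param seed integer seed; fixed seed gives identical output.
#' @param contact_spec optional data frame (`resno`, `resname`,
#'   `p_contact`) of probe residues placed in contact with a synthetic
#'   ligand (`LIG`) with the given per-frame probability, for fingerprint
#'   testing.
#' @param frame_interval informational time between frames.
#' @return list: `trajectory` (`kor_trajectory`), `labels` (ground-truth
#'   state per frame, in frame order after the deterministic shuffle),
#'   `features` (the realized d/chi/r_down targets), and `contact_truth`
#'   (per-probe-residue contact indicator matrix, or `NULL`).
#' @export
gen_trajectory <- function(spec, boundaries = default_state_boundaries(),
                           seed = 1L, contact_spec = NULL,
                           frame_interval = 10) {
  assert_that(length(spec) >= 1L, "spec must request at least one state")
  labs_avail <- state_labels(boundaries)
  counts <- vapply(spec, function(s) as.integer(s$n), integer(1))
  assert_that(any(counts > 0L), "at least one state must have a positive frame count")
  assert_that(all(counts >= 0L), "negative frame count in spec")

  rg <- boundaries$regions
  interval_len <- function(lo, hi) if (lo < hi) hi - lo else (hi - lo) %% 360

  targets <- lapply(names(spec), function(lab) {
    assert_that(lab %in% labs_avail, "unknown state label '%s' (scheme has: %s)",
                lab, paste(labs_avail, collapse = " "))
    base <- as.integer(sub("^S([0-9]).*$", "\\1", lab))
    region <- rg[rg$base == base, , drop = FALSE][1, ]
    s <- spec[[lab]]
    d_tgt <- s$d %||% {
      w <- region$d_max - region$d_min
      c(region$d_min + 0.1 * w, region$d_max - 0.1 * w)
    }
    chi_tgt <- s$chi %||% {
      w <- interval_len(region$chi_min, region$chi_max)
      c(wrap_angle(region$chi_min + 0.1 * w), wrap_angle(region$chi_min + 0.9 * w))
    }
    # validate targets strictly inside the region (wrap-aware for chi)
    assert_that(
      d_tgt[1] >= region$d_min && d_tgt[2] <= region$d_max && d_tgt[1] <= d_tgt[2],
      "d target for %s lies outside its state region", lab
    )
    off1 <- (chi_tgt[1] - region$chi_min) %% 360
    len_t <- (chi_tgt[2] - chi_tgt[1]) %% 360
    assert_that(
      off1 + len_t <= interval_len(region$chi_min, region$chi_max),
      "chi target for %s lies outside its state region", lab
    )
    split <- base %in% boundaries$split_by_r
    p_down <- s$p_down %||%
      if (!split) 0 else if (grepl("A$", lab)) 1 else 0
    if (split) {
      want_down <- grepl("A$", lab)
      assert_that(
        (want_down && p_down == 1) || (!want_down && p_down == 0),
        "p_down for split substate %s must match its A/B identity", lab
      )
    }
    assert_that(p_down >= 0 && p_down <= 1, "p_down must lie in [0, 1]")
    list(label = lab, n = as.integer(spec[[lab]]$n), d = d_tgt, chi = chi_tgt,
         p_down = p_down)
  })

  with_seed(seed, {
    rows <- do.call(rbind, lapply(targets, function(t) {
      if (t$n == 0L) return(NULL)
      len <- (t$chi[2] - t$chi[1]) %% 360
      data.frame(
        label = t$label,
        d = runif(t$n, t$d[1], t$d[2]),
        chi = wrap_angle(t$chi[1] + runif(t$n, 0, len)),
        r_down = runif(t$n) < t$p_down
      )
    }))
    ord <- sample.int(nrow(rows))
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL

    n_probe <- if (is.null(contact_spec)) 0L else nrow(contact_spec)
    contact_truth <- if (n_probe > 0L) {
      matrix(runif(nrow(rows) * n_probe) <
               rep(contact_spec$p_contact, each = nrow(rows)),
             nrow(rows), n_probe,
             dimnames = list(NULL, paste0(contact_spec$resname, contact_spec$resno)))
    } else NULL

    topo_atoms <- rbind(
      data.frame(chain_id = "A", residue_number = 153L, insert = "",
                 residue_name = "SER", atom_name = "CA", element = "C",
                 x = 0, y = 0, z = 0, is_hetero = FALSE),
      data.frame(chain_id = "A", residue_number = 156L, insert = "",
                 residue_name = "ARG", atom_name = c("CA", "CZ"), element = "C",
                 x = 0, y = 0, z = 0, is_hetero = FALSE),
      data.frame(chain_id = "A", residue_number = 330L, insert = "",
                 residue_name = "TYR", atom_name = c("C", "CA", "CG", "CZ"),
                 element = "C", x = 0, y = 0, z = 0, is_hetero = FALSE)
    )
    if (n_probe > 0L) {
      topo_atoms <- rbind(
        topo_atoms,
        data.frame(chain_id = "A", residue_number = as.integer(contact_spec$resno),
                   insert = "", residue_name = contact_spec$resname,
                   atom_name = "CA", element = "C",
                   x = 0, y = 0, z = 0, is_hetero = FALSE),
        data.frame(chain_id = "L", residue_number = 401L, insert = "",
                   residue_name = "LIG", atom_name = "C1", element = "C",
                   x = 0, y = 0, z = 0, is_hetero = TRUE)
      )
    }

    # fixed internal geometry of the Y330 marker group
    y_ca <- c(0, 0, 0)
    y_cg <- c(2.5, 0, 0)                       # Ca->Cg pseudo-bond
    y_c <- 1.52 * c(cos(deg2rad(110)), sin(deg2rad(110)), 0)
    r_ca <- c(-6, -3, 0)
    lig_center <- c(25, 20, 5)   # well clear of the marker-atom cluster
    # per-frame tilt of the R3.50 side chain off the membrane normal; the
    # z sign alone decides the orientation flag at the default threshold
    tilt <- runif(nrow(rows), 0, 60)
    azim <- runif(nrow(rows), 0, 360)

    frames <- lapply(seq_len(nrow(rows)), function(k) {
      chi <- rows$chi[k]
      y_cz <- place_atom(y_c, y_ca, y_cg, r = 2.78, theta = 120, phi = chi)
      s_ca <- y_cz + rows$d[k] * vunit(c(0.3, 0.6, 0.74))
      st <- sin(deg2rad(tilt[k])); ct <- cos(deg2rad(tilt[k]))
      dirz <- if (rows$r_down[k]) -ct else ct
      v <- c(st * cos(deg2rad(azim[k])), st * sin(deg2rad(azim[k])), dirz)
      r_cz <- r_ca + 4.1 * v
      co <- rbind(s_ca, r_ca, r_cz, y_c, y_ca, y_cg, y_cz)
      if (n_probe > 0L) {
        for (j in seq_len(n_probe)) {
          u <- vunit(c(cos(j), sin(j), 0.2))
          rad <- if (contact_truth[k, j]) 4.0 else 9.0
          co <- rbind(co, lig_center + rad * u)
        }
        co <- rbind(co, lig_center)
      }
      dimnames(co) <- NULL
      co
    })

    topo <- new_structure_model(topo_atoms, metadata = list(generator = "gen_trajectory", seed = seed))
    list(
      trajectory = new_trajectory(topo, frames, frame_interval),
      labels = rows$label,
      features = rows[, c("d", "chi", "r_down")],
      contact_truth = contact_truth
    )
  })
}
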