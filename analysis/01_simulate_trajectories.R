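#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study systems.
#
# Emulates the study design - a wild-type receptor and four binding-pocket
# mutants (K227A, Y312A, C286A, H291A), three independent replicate
# trajectories each - with state mixtures chosen so that every mutant
# shows the depleted alternative-state (S3A) population the study
# associates with reduced beta-arrestin recruitment. Frame counts are
# desk-scale (600 frames/replicate) rather than microsecond-scale.
#
# Writes: scratch/trajectories/<system>_rep<k>.pdb plus ground-truth JSON.

suppressPackageStartupMessages({
  library(korbias)
  library(jsonlite)
})

seed <- 20260925L
out_dir <- file.path("scratch", "trajectories")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# per-system state mixtures (fractions of 600 frames per replicate);
# WT carries the largest S3A (alternative conformation) population
mixtures <- list(
  WT = list(S1 = 180, S2A = 60, S2B = 90, S3A = 150, S3B = 60, S4 = 60),
  K227A = list(S1 = 180, S2A = 40, S2B = 110, S3A = 60, S3B = 130, S4 = 80),
  Y312A = list(S1 = 200, S2A = 30, S2B = 120, S3A = 30, S3B = 140, S4 = 80),
  C286A = list(S1 = 90, S2A = 50, S2B = 120, S3A = 70, S3B = 150, S4 = 120),
  H291A = list(S1 = 100, S2A = 50, S2B = 110, S3A = 60, S3B = 120, S4 = 160)
)

truth <- list()
for (system in names(mixtures)) {
  spec <- lapply(mixtures[[system]], function(n) list(n = n))
  for (rep_i in 1:3) {
    g <- gen_trajectory(spec, seed = seed + match(system, names(mixtures)) * 10 + rep_i)
    path <- file.path(out_dir, sprintf("%s_rep%d.pdb", system, rep_i))
    write_trajectory(g$trajectory, path, "pdb")
    truth[[sprintf("%s_rep%d", system, rep_i)]] <- list(
      labels = g$labels, n_frames = length(g$labels)
    )
    message(sprintf("%s replicate %d: %d frames -> %s",
                    system, rep_i, length(g$labels), path))
  }
}
write_json(truth, file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
message("Ground truth written; state classification can now be scored exactly.")
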