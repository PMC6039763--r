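#!/usr/bin/env Rscript
# Rigid-body integrative placement: a bound-state kinase pose from the
# wild-type ensemble is superimposed onto pairs of anchor frames emulating
# the two ectodomain-dimer arrangements (a "parallel/close" pair of TM
# anchors and an "upright/far" pair), and the kinase-kinase centre-of-mass
# separations and steric clashes are reported.  The close arrangement must
# give the smaller separation.
#
# Requires: analysis/01_simulate_ensembles.R
# Output:   results/assembly/separations.csv, results/assembly/dimer_*.pdb

suppressMessages(library(membmode))

in_dir <- "results/ensembles"
out_dir <- "results/assembly"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

st <- read_structure(file.path(in_dir, "wildtype_102.gro"),
                     species_map = list(
                       POPC = list(species = "PC", headgroup_names = "PO4"),
                       POPS = list(species = "PS", headgroup_names = "PO4"),
                       POP2 = list(species = "PIP2", headgroup_names = "PO4"),
                       POP3 = list(species = "PIP3", headgroup_names = "PO4")),
                     domain_map = data.frame(
                       from = c(590L, 601L, 641L), to = c(590L, 640L, 680L),
                       domain = c("JM", "NLOBE", "CLOBE")))
traj <- read_trajectory(file.path(in_dir, "wildtype_102.trj"), st$topology)
sels <- synth_selections(traj$topology)

# last frame's protein coordinates as the bound pose; the JM-anchor bead
# plus the four lowest N-lobe beads act as the TM-anchor frame
prot_rows <- sels$protein$indices + 1
pose_xyz <- traj$frames[[length(traj$frames)]]$coordinates[prot_rows, ]
anchor_ids <- order(pose_xyz[, 3])[1:5] - 1L
pose <- domain_pose(pose_xyz, selection(anchor_ids), label = "bound kinase")

a0 <- pose$coordinates[anchor_ids + 1, ]
arrangements <- list(
  close = list(A = a0, B = sweep(a0, 2, c(6, 0, 0), "+")),
  far   = list(A = a0, B = sweep(a0, 2, c(10, 0, 0), "+"))
)

rows <- list()
for (nm in names(arrangements)) {
  fit <- assemble_copies(pose, arrangements[[nm]])
  rows[[nm]] <- data.frame(arrangement = nm,
                           separation_nm = fit$separations$distance_nm,
                           clash_pairs = fit$clashes$n_pairs)
  # write the composite as a multi-model PDB (one MODEL per copy)
  ptop <- st$topology[prot_rows, ]
  class(ptop) <- c("topology", "data.frame")
  ptop$particle_id <- seq_len(nrow(ptop)) - 1L
  frames <- lapply(fit$placed, function(x)
    frame(x, box = c(50, 50, 50), time = 0))
  frames[[2]]$time <- 1
  write_pdb(file.path(out_dir, paste0("dimer_", nm, ".pdb")), ptop, frames)
  message(sprintf("%-5s arrangement: kinase-kinase separation %.2f nm, %d clash pairs",
                  nm, fit$separations$distance_nm, fit$clashes$n_pairs))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "separations.csv"),
          row.names = FALSE)
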