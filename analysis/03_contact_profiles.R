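#!/usr/bin/env Rscript
# Per-residue lipid contact profiles of the bound wild-type ensemble at the
# 0.8 nm cutoff, normalized per species to the top residue, plus the
# juxtamembrane <-> kinase intramolecular contact frequencies on the
# tethered runs.  The strongest PIP2 contacts should sit on the basic
# N-lobe patches (P1: 609/615/617, P2: 629/633/638/639).
#
# Requires: analysis/01_simulate_ensembles.R
# Output:   results/contacts/profile_wildtype.csv,
#           results/contacts/jm_kinase_tethered.csv

suppressMessages(library(membmode))

in_dir <- "results/ensembles"
out_dir <- "results/contacts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seeds <- 101:105

read_run <- function(stem) {
  st <- read_structure(file.path(in_dir, paste0(stem, ".gro")),
                       species_map = list(
                         POPC = list(species = "PC", headgroup_names = "PO4"),
                         POPS = list(species = "PS", headgroup_names = "PO4"),
                         POP2 = list(species = "PIP2", headgroup_names = "PO4"),
                         POP3 = list(species = "PIP3", headgroup_names = "PO4")),
                       domain_map = data.frame(
                         from = c(590L, 601L, 641L), to = c(590L, 640L, 680L),
                         domain = c("JM", "NLOBE", "CLOBE")))
  read_trajectory(file.path(in_dir, paste0(stem, ".trj")), st$topology)
}

raw_sum <- NULL
n_runs <- 0
for (s in seeds) {
  traj <- read_run(paste0("wildtype_", s))
  sels <- synth_selections(traj$topology)
  ser <- orientation_series(traj, sels$protein, sels$membrane)
  iv <- classify_bound(ser)
  if (nrow(iv) == 0) next
  kin <- selection(c(sels$nlobe$indices, sels$clobe$indices), "kinase")
  cc <- contact_counts(traj, kin, sels$headgroups, cutoff = 0.8,
                       frames = which(bound_frame_mask(iv, length(traj$frames))))
  rm <- apply(cc$counts, c(1, 2), mean)
  raw_sum <- if (is.null(raw_sum)) rm else raw_sum + rm
  n_runs <- n_runs + 1
}
raw_mean <- raw_sum / n_runs
norm <- sweep(raw_mean, 2, pmax(apply(raw_mean, 2, max), 1e-12), "/")
prof <- data.frame(residue_id = rep(as.integer(rownames(raw_mean)),
                                    ncol(raw_mean)),
                   species = rep(colnames(raw_mean), each = nrow(raw_mean)),
                   raw_mean = as.vector(raw_mean),
                   normalized = as.vector(norm))
write.csv(prof, file.path(out_dir, "profile_wildtype.csv"), row.names = FALSE)

pip2 <- prof[prof$species == "PIP2", ]
top5 <- pip2[order(pip2$normalized, decreasing = TRUE)[1:5], ]
message("top-5 PIP2 contact residues (bound wild-type, ", n_runs, " runs):")
for (i in seq_len(5))
  message(sprintf("  residue %d  normalized %.2f", top5$residue_id[i],
                  top5$normalized[i]))

# JM <-> kinase contacts on the tethered ensemble
freq <- NULL
freq_all <- list()
for (s in seeds) {
  traj <- read_run(paste0("tethered_", s))
  sels <- synth_selections(traj$topology)
  kin <- selection(c(sels$nlobe$indices, sels$clobe$indices), "kinase")
  f <- intramolecular_contacts(traj, sels$jm, kin, cutoff = 1.6)
  if (is.null(freq)) freq <- f
  freq_all[[as.character(s)]] <- f$frequency
}
freq$frequency <- rowMeans(do.call(cbind, freq_all))
write.csv(freq, file.path(out_dir, "jm_kinase_tethered.csv"),
          row.names = FALSE)
fN <- sum(freq$frequency[freq$side == "B" & freq$residue_id %in% 601:640])
fC <- sum(freq$frequency[freq$side == "B" & freq$residue_id %in% 641:680])
message(sprintf("JM contact weight: N-lobe %.1f vs C-lobe %.1f", fN, fC))
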