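# Fixture builders shared across test files.  Everything is generated in
# code; no stored data files.

# minimal lipid-only topology: n lipids, one headgroup bead each
toy_lipid_topology <- function(species = c("PC", "PS", "PIP2")) {
  n <- length(species)
  topology(
    particle_name = rep("PO4", n),
    residue_id = seq_len(n),
    residue_name = c(PC = "POPC", PS = "POPS", PIP2 = "POP2",
                     PIP3 = "POP3")[species],
    molecule_id = seq_len(n),
    domain_label = rep("LIPID", n),
    species = species,
    is_headgroup = rep(TRUE, n)
  )
}

# protein + lipid toy: np protein beads (given domains/residues) followed by
# nl single-bead lipids of the given species
toy_system <- function(prot_residues, prot_domains, lipid_species) {
  np <- length(prot_residues)
  nl <- length(lipid_species)
  topology(
    particle_name = c(rep("BB", np), rep("PO4", nl)),
    residue_id = c(prot_residues, 1000L + seq_len(nl)),
    residue_name = c(rep("KIN", np),
                     c(PC = "POPC", PS = "POPS", PIP2 = "POP2",
                       PIP3 = "POP3")[lipid_species]),
    molecule_id = c(rep(1L, np), 1L + seq_len(nl)),
    domain_label = c(prot_domains, rep("LIPID", nl)),
    species = c(rep("PROTEIN", np), lipid_species),
    is_headgroup = c(rep(FALSE, np), rep(TRUE, nl))
  )
}

# trajectory from a list of coordinate matrices
traj_from_coords <- function(top, coord_list, box = c(10, 10, 10), dt = 1) {
  trajectory(top, lapply(seq_along(coord_list), function(k)
    frame(coord_list[[k]], box, time = (k - 1) * dt)))
}

# brute-force minimum-image distance over all 27 periodic images
dist27 <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# random proper rotation matrix
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# all-pairs per-residue, per-species contact counts with the 27-image oracle
brute_counts <- function(traj, top, prows, lrows, cutoff) {
  res_ids <- sort(unique(top$residue_id[prows]))
  spp <- sort(unique(top$species[lrows]))
  out <- array(0L, c(length(res_ids), length(spp), length(traj$frames)),
               dimnames = list(res_ids, spp, NULL))
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    for (l in lrows) {
      for (r in seq_along(res_ids)) {
        beads <- prows[top$residue_id[prows] == res_ids[r]]
        hit <- FALSE
        for (p in beads)
          if (dist27(f$coordinates[p, ], f$coordinates[l, ], f$box) <= cutoff)
            hit <- TRUE
        if (hit) {
          s <- match(top$species[l], spp)
          out[r, s, k] <- out[r, s, k] + 1L
        }
      }
    }
  }
  out
}

rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}
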