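# Cutoff-based contact statistics: per-residue, per-lipid-species contact
# counts and normalized contact profiles, plus intramolecular (JM <-> kinase)
# contact frequencies.  All distances use the minimum-image convention; the
# default cutoff is 0.8 nm, the single contact cutoff used throughout.

#' Raw per-residue, per-species lipid contact counts
#'
#' For every frame, protein residue and lipid species: the number of target
#' particles (by default lipid headgroup beads) within \code{cutoff} of any
#' particle of that residue.  Counting is per target particle, so one residue
#' touching three headgroups in a frame scores 3.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param protein_sel \code{\link{selection}} of protein particles, grouped
#'   internally by residue id.
#' @param lipid_sel \code{\link{selection}} of lipid target particles
#'   (typically headgroup beads; pass a whole-lipid selection to widen).
#' @param cutoff contact cutoff in nm (> 0), default 0.8.
#' @param frames optional integer vector of frame indices to analyze.
#' @return list of class \code{"contact_counts"}: \code{residues} (ordered
#'   residue ids), \code{species}, \code{counts} (3-D array residue x species
#'   x frame), \code{cutoff}, \code{frames}.
#' @export
contact_counts <- function(traj, protein_sel, lipid_sel, cutoff = 0.8,
                           frames = NULL) {
  stopifnot(cutoff > 0)
  top <- traj$topology
  prows <- sel_rows(protein_sel)
  lrows <- sel_rows(lipid_sel)
  if (length(prows) == 0L || length(lrows) == 0L)
    stop("contact_counts: empty selection")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  res_ids <- sort(unique(top$residue_id[prows]))
  res_of <- match(top$residue_id[prows], res_ids)
  spp <- sort(unique(top$species[lrows]))
  sp_of <- match(top$species[lrows], spp)
  counts <- array(0L, dim = c(length(res_ids), length(spp), length(frames)),
                  dimnames = list(res_ids, spp, NULL))
  for (fk in seq_along(frames)) {
    f <- traj$frames[[frames[fk]]]
    P <- f$coordinates[prows, , drop = FALSE]
    L <- f$coordinates[lrows, , drop = FALSE]
    hit <- contact_pairs(P, L, cutoff, f$box)   # logical nP x nL
    if (!any(hit)) next
    # a target particle counts for residue r when ANY bead of r touches it
    for (r in seq_along(res_ids)) {
      rb <- which(res_of == r)
      if (length(rb) == 0L) next
      touched <- if (length(rb) == 1L) hit[rb, ] else colSums(hit[rb, , drop = FALSE]) > 0
      if (!any(touched)) next
      tab <- tabulate(sp_of[touched], nbins = length(spp))
      counts[r, , fk] <- counts[r, , fk] + tab
    }
  }
  structure(list(residues = res_ids, species = spp, counts = counts,
                 cutoff = cutoff, frames = frames),
            class = "contact_counts")
}

# logical contact matrix between two coordinate sets under minimum image,
# with a z-slab prefilter (membrane-normal) to avoid the full pair set
contact_pairs <- function(A, B, cutoff, box) {
  hit <- matrix(FALSE, nrow(A), nrow(B))
  zc <- (min(B[, 3]) + max(B[, 3])) / 2
  halfspan <- (max(B[, 3]) - min(B[, 3])) / 2 + cutoff
  dzw <- abs(A[, 3] - zc)
  dzw <- pmin(dzw, box[3] - dzw)
  cand <- which(dzw <= halfspan)
  for (i in cand) {
    d <- A[rep(i, nrow(B)), , drop = FALSE] - B
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    hit[i, ] <- rowSums(d * d) <= cutoff^2
  }
  hit
}

#' Normalized per-residue contact profile
#'
#' Time-averages raw contact counts and, per species, divides by the maximum
#' time-averaged count over residues, so the top residue of each species sits
#' at 1 (a species with no contacts anywhere stays all-zero).  This
#' reproduces a "relative number of interacting particles" normalized
#' frequency in [0, 1].
#'
#' @param counts a \code{"contact_counts"} object.
#' @return list of class \code{"contact_profile"}: \code{residues},
#'   \code{species}, \code{raw_mean} (residue x species matrix of mean
#'   interacting-particle counts per frame), \code{normalized} (same shape,
#'   in [0, 1]), \code{cutoff}, \code{n_frames}.
#' @export
normalized_contact_profile <- function(counts) {
  raw_mean <- apply(counts$counts, c(1, 2), mean)
  norm <- raw_mean
  for (j in seq_len(ncol(norm))) {
    mx <- max(raw_mean[, j])
    norm[, j] <- if (mx > 0) raw_mean[, j] / mx else 0
  }
  structure(list(residues = counts$residues, species = counts$species,
                 raw_mean = raw_mean, normalized = norm,
                 cutoff = counts$cutoff, n_frames = dim(counts$counts)[3]),
            class = "contact_profile")
}

#' Intramolecular contact frequencies between two protein selections
#'
#' For each residue of either selection, the fraction of frames in which any
#' particle pair across the two selections involving that residue is within
#' \code{cutoff} (minimum image).  Used for juxtamembrane <-> kinase contact
#' bars.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selA,selB disjoint \code{\link{selection}}s (e.g. JM and kinase).
#' @param cutoff contact cutoff in nm, default 0.8.
#' @return data.frame with columns \code{residue_id}, \code{side} ("A" or
#'   "B") and \code{frequency} in [0, 1].
#' @export
intramolecular_contacts <- function(traj, selA, selB, cutoff = 0.8) {
  stopifnot(cutoff > 0)
  if (length(intersect(selA$indices, selB$indices)) > 0)
    stop("intramolecular_contacts: selections overlap")
  top <- traj$topology
  arows <- sel_rows(selA); brows <- sel_rows(selB)
  resA <- sort(unique(top$residue_id[arows]))
  resB <- sort(unique(top$residue_id[brows]))
  ra <- match(top$residue_id[arows], resA)
  rb <- match(top$residue_id[brows], resB)
  hitsA <- matrix(0, length(resA), n_frames(traj))
  hitsB <- matrix(0, length(resB), n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    A <- f$coordinates[arows, , drop = FALSE]
    B <- f$coordinates[brows, , drop = FALSE]
    hit <- matrix(FALSE, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) {
      d <- A[rep(i, nrow(B)), , drop = FALSE] - B
      d <- d - sweep(round(sweep(d, 2, f$box, "/")), 2, f$box, "*")
      hit[i, ] <- rowSums(d * d) <= cutoff^2
    }
    anyA <- rowSums(hit) > 0
    anyB <- colSums(hit) > 0
    for (r in which(tabulate(ra[anyA], length(resA)) > 0)) hitsA[r, k] <- 1
    for (r in which(tabulate(rb[anyB], length(resB)) > 0)) hitsB[r, k] <- 1
  }
  rbind(
    data.frame(residue_id = resA, side = "A", frequency = rowMeans(hitsA)),
    data.frame(residue_id = resB, side = "B", frequency = rowMeans(hitsB))
  )
}
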