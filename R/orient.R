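# Orientation analysis: least-squares superposition onto a reference pose,
# per-frame (Rzz, dz), the normalized orientation-distance density map
# DeltaD = rho / rho0, bound-state detection and binding-mode classification.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rigid transform (rotation + translation, no reflection)
#' minimizing the weighted RMSD of \code{mobile} onto \code{reference}, via
#' SVD of the weighted covariance matrix with the usual sign correction that
#' forces a proper rotation (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3, not all
#'   collinear.
#' @param weights optional per-particle non-negative weights (e.g. masses).
#' @return list with \code{rotation} (3 x 3, orthogonal, det +1),
#'   \code{translation} (length 3, nm) such that the fitted coordinates are
#'   \code{mobile \%*\% t(rotation) + translation}, and \code{rmsd} (nm), the
#'   minimized weighted RMSD.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("superpose needs matching coordinate sets with at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B          # covariance, mobile -> reference
  s <- svd(H)
  if (s$d[2] < 1e-12)
    stop("superpose: degenerate (collinear) geometry")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)    # x_fit = R x
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Reference pose for orientation fitting
#'
#' @param coordinates n x 3 protein coordinates (nm) defining the reference
#'   orientation; at least 3 non-collinear points.
#' @param selection the \code{\link{selection}} these coordinates correspond
#'   to.
#' @return A \code{"reference_pose"} object.
#' @export
reference_pose <- function(coordinates, selection) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 3L) stop("reference pose needs >= 3 particles")
  structure(list(coordinates = unname(coordinates), selection = selection),
            class = "reference_pose")
}

#' Per-frame orientation and membrane separation
#'
#' For every frame, fits the protein selection onto a reference pose and
#' records Rzz (the zz element of the fitted rotation: +1 when the protein
#' sits in the reference orientation about the membrane normal, -1 when
#' flipped), dz (the perpendicular |z| separation between the protein and
#' membrane centres of mass, minimum-image wrapped along z) and d (the
#' minimum-image 3-D COM separation).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param protein_sel,membrane_sel \code{\link{selection}}s for the protein
#'   and the membrane.
#' @param ref a \code{\link{reference_pose}}; defaults to the protein's
#'   first-frame coordinates (the map's meaning is relative to it).
#' @return data.frame of class \code{"orientation_series"} with columns
#'   \code{time}, \code{Rzz}, \code{dz}, \code{d}.
#' @export
orientation_series <- function(traj, protein_sel, membrane_sel, ref = NULL) {
  top <- traj$topology
  rows <- sel_rows(protein_sel)
  if (length(rows) == 0L || length(membrane_sel$indices) == 0L)
    stop("orientation_series: empty selection")
  if (is.null(ref))
    ref <- reference_pose(traj$frames[[1]]$coordinates[rows, , drop = FALSE],
                          protein_sel)
  if (nrow(ref$coordinates) != length(rows))
    stop("reference pose particle count does not match protein selection")
  w <- top$mass[rows]
  out <- data.frame(time = numeric(n_frames(traj)), Rzz = NA_real_,
                    dz = NA_real_, d = NA_real_)
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    fit <- superpose(f$coordinates[rows, , drop = FALSE], ref$coordinates,
                     weights = w)
    com_p <- center_of_mass(f, protein_sel, top)
    com_m <- center_of_mass(f, membrane_sel, top)
    delta <- com_p - com_m
    delta_mi <- delta - f$box * round(delta / f$box)
    out$time[k] <- f$time
    out$Rzz[k]  <- max(-1, min(1, fit$rotation[3, 3]))
    out$dz[k]   <- abs(delta_mi[3])
    out$d[k]    <- sqrt(sum(delta_mi^2))
  }
  class(out) <- c("orientation_series", "data.frame")
  out
}

#' Normalized orientation-distance density map
#'
#' Bins the per-frame (Rzz, distance) observations into a 2-D normalized
#' histogram rho (sum 1) and forms the ratio map DeltaD = rho / rho0, where
#' rho0 is the global maximum bin probability, so max(DeltaD) = 1.
#'
#' @param series an \code{\link{orientation_series}}.
#' @param rzz_edges bin edges over [-1, 1] (default width 0.05).
#' @param d_edges distance bin edges in nm (default width 0.1 nm covering the
#'   observed range).
#' @param distance which separation to bin: \code{"dz"} (perpendicular,
#'   default) or \code{"d"} (3-D COM separation).
#' @return list of class \code{"orientation_density"} with \code{rzz_edges},
#'   \code{d_edges}, \code{rho}, \code{deltaD} (matrices, Rzz bins x distance
#'   bins) and \code{rho0}.
#' @export
density_map <- function(series, rzz_edges = seq(-1, 1, by = 0.05),
                        d_edges = NULL, distance = c("dz", "d")) {
  distance <- match.arg(distance)
  x <- series$Rzz
  y <- series[[distance]]
  if (is.null(d_edges)) {
    top <- ceiling(max(y) / 0.1) * 0.1 + 0.1
    d_edges <- seq(0, top, by = 0.1)
  }
  keep <- x >= rzz_edges[1] & x <= rzz_edges[length(rzz_edges)] &
    y >= d_edges[1] & y <= d_edges[length(d_edges)]
  if (!any(keep)) stop("density_map: all observations fall outside the grid")
  ix <- findInterval(x[keep], rzz_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(y[keep], d_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, length(rzz_edges) - 1L, length(d_edges) - 1L)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  rho <- counts / sum(counts)
  rho0 <- max(rho)
  structure(list(rzz_edges = rzz_edges, d_edges = d_edges, rho = rho,
                 deltaD = rho / rho0, rho0 = rho0),
            class = "orientation_density")
}

#' Detect membrane-bound intervals
#'
#' Maximal runs of frames with dz at or below a threshold, kept only when
#' they last at least \code{min_dwell} frames.  The default threshold 5 nm is
#' the upper edge of the 4-5 nm COM separation band that marks a stable
#' kinase-membrane interaction; the dwell requirement suppresses grazing
#' contacts.
#'
#' @param series an \code{\link{orientation_series}}.
#' @param d_threshold bound threshold on dz in nm.
#' @param min_dwell minimum run length in frames (>= 1).
#' @param distance use \code{"dz"} (default) or \code{"d"}.
#' @return data.frame with columns \code{start}, \code{end} (1-based frame
#'   indices, inclusive); zero rows when never bound.  Intervals are disjoint
#'   and ordered.
#' @export
classify_bound <- function(series, d_threshold = 5.0, min_dwell = 10,
                           distance = c("dz", "d")) {
  distance <- match.arg(distance)
  stopifnot(min_dwell >= 1)
  below <- series[[distance]] <= d_threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_dwell
  data.frame(start = starts[keep], end = ends[keep])
}

#' Expand bound intervals into a per-frame logical mask
#'
#' @param intervals data.frame with \code{start}, \code{end} columns (from
#'   \code{\link{classify_bound}}).
#' @param nf total number of frames.
#' @return Logical vector of length \code{nf}, TRUE inside any interval.
#' @export
bound_frame_mask <- function(intervals, nf) {
  mask <- rep(FALSE, nf)
  for (i in seq_len(nrow(intervals)))
    mask[intervals$start[i]:intervals$end[i]] <- TRUE
  mask
}

#' Classify binding mode per frame (mode 1 vs mode 2)
#'
#' Binding modes are defined by which kinase lobes engage the membrane:
#' mode 1 touches via the N-lobe only (activation loop exposed), mode 2 via
#' both lobes (activation loop masked).  A bound frame is MODE1 when the
#' N-lobe has membrane contacts and C-lobe contacts stay at or below
#' \code{clobe_contact_threshold} times the N-lobe count; it is MODE2 when
#' both lobes reach the one-bead contact floor, or when only the C-lobe
#' touches.  Frames outside bound intervals are UNBOUND, as are bound frames
#' in which neither lobe has any membrane contact (e.g. tether-suspended
#' poses).  A lobe "contact" is a lobe bead within \code{cutoff} of any
#' membrane headgroup bead (minimum image).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param nlobe_sel,clobe_sel \code{\link{selection}}s of the two kinase
#'   lobes.
#' @param membrane_headgroup_sel \code{\link{selection}} of membrane
#'   headgroup beads.
#' @param bound_intervals output of \code{\link{classify_bound}}.
#' @param cutoff contact cutoff in nm (default 0.8).
#' @param clobe_contact_threshold max C-lobe/N-lobe contact ratio tolerated
#'   in MODE1 (default 0.25, i.e. incidental single-bead grazing).
#' @return list with \code{labels} (character per frame: MODE1/MODE2/UNBOUND)
#'   and \code{dominant} (majority label over bound frames; UNBOUND when no
#'   frame is bound).
#' @export
classify_mode <- function(traj, nlobe_sel, clobe_sel, membrane_headgroup_sel,
                          bound_intervals, cutoff = 0.8,
                          clobe_contact_threshold = 0.25) {
  stopifnot(cutoff > 0)
  nf <- n_frames(traj)
  mask <- bound_frame_mask(bound_intervals, nf)
  labels <- rep("UNBOUND", nf)
  nrows <- sel_rows(nlobe_sel)
  crows <- sel_rows(clobe_sel)
  hrows <- sel_rows(membrane_headgroup_sel)
  for (k in which(mask)) {
    f <- traj$frames[[k]]
    heads <- f$coordinates[hrows, , drop = FALSE]
    nN <- beads_in_contact(f$coordinates[nrows, , drop = FALSE], heads,
                           cutoff, f$box)
    nC <- beads_in_contact(f$coordinates[crows, , drop = FALSE], heads,
                           cutoff, f$box)
    labels[k] <-
      if (nN >= 1 && nC <= clobe_contact_threshold * nN) "MODE1"
      else if (nC >= 1) "MODE2"
      else "UNBOUND"
  }
  bound_labels <- labels[mask & labels != "UNBOUND"]
  dominant <- if (length(bound_labels) == 0L) "UNBOUND" else
    names(which.max(table(bound_labels)))
  list(labels = labels, dominant = dominant)
}

# number of rows of `beads` with at least one of `targets` within cutoff
beads_in_contact <- function(beads, targets, cutoff, box) {
  if (nrow(beads) == 0L || nrow(targets) == 0L) return(0L)
  # prefilter in z (membrane normal, minimum-image) to keep the pair set small
  zc <- (min(targets[, 3]) + max(targets[, 3])) / 2
  halfspan <- (max(targets[, 3]) - min(targets[, 3])) / 2 + cutoff
  dzw <- abs(beads[, 3] - zc)
  dzw <- pmin(dzw, box[3] - dzw)
  cand <- which(dzw <= halfspan)
  cnt <- 0L
  for (i in cand) {
    d <- min_image_distance(matrix(beads[i, ], nrow(targets), 3, byrow = TRUE),
                            targets, box)
    if (any(d <= cutoff)) cnt <- cnt + 1L
  }
  cnt
}
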