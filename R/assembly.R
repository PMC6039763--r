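# Rigid-body integrative placement: superimpose domain poses onto shared
# anchor frames (e.g. the TM helix as the common reference frame) and measure
# inter-domain centre-of-mass distances.  Assembled composites carry no
# periodic box; steric clashes are reported, never resolved.

#' Domain pose with an anchor selection
#'
#' @param coordinates n x 3 particle positions in nm.
#' @param anchor_sel \code{\link{selection}} of anchor particles (>= 3,
#'   non-collinear) within these coordinates (0-based ids into the pose).
#' @param label text label.
#' @return A \code{"domain_pose"} object.
#' @export
domain_pose <- function(coordinates, anchor_sel, label = "pose") {
  coordinates <- as.matrix(coordinates)
  a <- coordinates[sel_rows(anchor_sel), , drop = FALSE]
  if (nrow(a) < 3L) stop("anchor needs >= 3 particles")
  if (svd(sweep(a, 2, colMeans(a)))$d[2] < 1e-10)
    stop("anchor particles are collinear")
  structure(list(coordinates = unname(coordinates), anchor_sel = anchor_sel,
                 label = label),
            class = "domain_pose")
}

#' Transform carrying a pose's anchor onto a target anchor
#'
#' Least-squares rigid transform (via \code{\link{superpose}}) mapping the
#' pose's anchor particles onto \code{target_anchor}.
#'
#' @param pose a \code{\link{domain_pose}}.
#' @param target_anchor m x 3 coordinates, same particle count and order as
#'   the pose's anchor.
#' @return A rigid transform list (\code{rotation}, \code{translation},
#'   \code{rmsd}) as returned by \code{\link{superpose}}.
#' @export
anchor_transform <- function(pose, target_anchor) {
  a <- pose$coordinates[sel_rows(pose$anchor_sel), , drop = FALSE]
  target_anchor <- as.matrix(target_anchor)
  if (nrow(target_anchor) != nrow(a))
    stop("anchor particle counts differ (", nrow(a), " vs ",
         nrow(target_anchor), ")")
  superpose(a, target_anchor)
}

#' Apply a rigid transform to all pose coordinates
#'
#' \code{x -> R x + t}; rigid, so all pairwise distances and chirality are
#' preserved.
#'
#' @param pose a \code{\link{domain_pose}}.
#' @param transform rigid transform from \code{\link{anchor_transform}} or
#'   \code{\link{superpose}}.
#' @return n x 3 matrix of placed coordinates (nm).
#' @export
place_domain <- function(pose, transform) {
  apply_transform(pose$coordinates, transform)
}

#' COM separation between two placed domains
#'
#' Plain Euclidean distance between the (uniform-weight) centres of mass of
#' two placed coordinate sets.  Assembled models are not periodic, so no
#' minimum-image wrapping applies.
#'
#' @param placedA,placedB n x 3 coordinate matrices (nm).
#' @return Distance in nm.
#' @export
pair_separation <- function(placedA, placedB) {
  if (nrow(placedA) == 0L || nrow(placedB) == 0L)
    stop("pair_separation: empty coordinates")
  sqrt(sum((colMeans(as.matrix(placedA)) - colMeans(as.matrix(placedB)))^2))
}

#' Assemble one pose onto several anchor frames
#'
#' Places a copy of \code{pose} on every anchor coordinate set and reports
#' all pairwise COM separations plus steric clashes (inter-copy particle
#' pairs closer than \code{clash_cutoff}; reported, never resolved).
#'
#' @param pose a \code{\link{domain_pose}}.
#' @param anchors named list of m x 3 anchor coordinate matrices.
#' @param clash_cutoff clash distance in nm (default 0.3).
#' @return list with \code{placed} (named list of coordinate matrices),
#'   \code{separations} (data.frame a, b, distance_nm) and \code{clashes}
#'   (data.frame a, b, n_pairs).
#' @export
assemble_copies <- function(pose, anchors, clash_cutoff = 0.3) {
  placed <- lapply(anchors, function(a)
    place_domain(pose, anchor_transform(pose, a)))
  nm <- names(placed)
  seps <- data.frame(); clashes <- data.frame()
  if (length(placed) >= 2) {
    cmb <- utils::combn(seq_along(placed), 2)
    seps <- data.frame(
      a = nm[cmb[1, ]], b = nm[cmb[2, ]],
      distance_nm = apply(cmb, 2, function(ij)
        pair_separation(placed[[ij[1]]], placed[[ij[2]]]))
    )
    clashes <- data.frame(
      a = nm[cmb[1, ]], b = nm[cmb[2, ]],
      n_pairs = apply(cmb, 2, function(ij) {
        A <- placed[[ij[1]]]; B <- placed[[ij[2]]]
        n <- 0L
        for (i in seq_len(nrow(A)))
          n <- n + sum(rowSums(sweep(B, 2, A[i, ])^2) < clash_cutoff^2)
        n
      })
    )
  }
  list(placed = placed, separations = seps, clashes = clashes)
}
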