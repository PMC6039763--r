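#' @keywords internal
"_PACKAGE"

DOMAIN_LEVELS  <- c("TM", "JM", "NLOBE", "CLOBE", "ACTLOOP", "LIPID", "OTHER")
SPECIES_LEVELS <- c("PROTEIN", "PC", "PS", "PIP2", "PIP3")
LIPID_SPECIES  <- c("PC", "PS", "PIP2", "PIP3")

#' Construct a particle topology
#'
#' A topology holds per-particle metadata for a protein + bilayer system:
#' identity, residue assignment, molecule grouping, domain label
#' (TM/JM/NLOBE/CLOBE/ACTLOOP/LIPID/OTHER), lipid species
#' (PROTEIN/PC/PS/PIP2/PIP3), a headgroup flag and a mass.  All downstream
#' analyses (orientation, contacts, clustering) consume this object together
#' with coordinate frames.
#'
#' @param particle_name character vector of particle (bead/atom) names.
#' @param residue_id integer vector of residue ids (1-based ids from input
#'   files are preserved, e.g. H609 stays 609).
#' @param residue_name character vector of residue names.
#' @param molecule_id integer vector; one id per lipid molecule or protein
#'   chain.
#' @param domain_label character vector over
#'   \code{c("TM","JM","NLOBE","CLOBE","ACTLOOP","LIPID","OTHER")}.
#' @param species character vector over
#'   \code{c("PROTEIN","PC","PS","PIP2","PIP3")}.
#' @param is_headgroup logical vector; may be TRUE only for lipid species.
#' @param mass numeric vector of particle masses in amu; defaults to the
#'   coarse-grained bead mass 72 for every particle.
#'
#' @return An object of class \code{"topology"}: a data.frame with one row per
#'   particle and a 0-based \code{particle_id} column.
#' @export
topology <- function(particle_name, residue_id, residue_name, molecule_id,
                     domain_label, species, is_headgroup,
                     mass = rep(72, length(particle_name))) {
  n <- length(particle_name)
  stopifnot(length(residue_id) == n, length(residue_name) == n,
            length(molecule_id) == n, length(domain_label) == n,
            length(species) == n, length(is_headgroup) == n,
            length(mass) == n)
  if (!all(domain_label %in% DOMAIN_LEVELS))
    stop("unknown domain_label: ",
         paste(unique(setdiff(domain_label, DOMAIN_LEVELS)), collapse = ", "))
  if (!all(species %in% SPECIES_LEVELS))
    stop("unknown species: ",
         paste(unique(setdiff(species, SPECIES_LEVELS)), collapse = ", "))
  if (any(is_headgroup & !(species %in% LIPID_SPECIES)))
    stop("is_headgroup may be TRUE only for lipid particles")
  if (any(species %in% LIPID_SPECIES & domain_label != "LIPID"))
    stop("lipid-species particles must carry domain_label LIPID")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("masses must be strictly positive and finite")
  top <- data.frame(
    particle_id  = seq_len(n) - 1L,
    particle_name = as.character(particle_name),
    residue_id   = as.integer(residue_id),
    residue_name = as.character(residue_name),
    molecule_id  = as.integer(molecule_id),
    domain_label = as.character(domain_label),
    species      = as.character(species),
    is_headgroup = as.logical(is_headgroup),
    mass         = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  top
}

#' Construct a single coordinate frame
#'
#' @param coordinates numeric n x 3 matrix of positions in nm.
#' @param box numeric length-3 vector of orthorhombic box lengths
#'   (Lx, Ly, Lz) in nm.
#' @param time frame time in ns.
#'
#' @return An object of class \code{"frame"}.
#' @export
frame <- function(coordinates, box, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stop("coordinates must be an n x 3 matrix")
  if (any(!is.finite(coordinates)))
    stop("coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three strictly positive lengths (orthorhombic only)")
  structure(list(coordinates = unname(coordinates), box = box,
                 time = as.numeric(time)),
            class = "frame")
}

#' Construct a trajectory
#'
#' @param topology a \code{\link{topology}}.
#' @param frames list of \code{\link{frame}} objects with strictly increasing
#'   times and a particle count matching the topology.
#'
#' @return An object of class \code{"trajectory"}.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1L)
  n <- nrow(topology)
  for (f in frames) {
    if (!inherits(f, "frame")) stop("frames must be frame objects")
    if (nrow(f$coordinates) != n)
      stop("frame particle count (", nrow(f$coordinates),
           ") does not match topology (", n, ")")
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d particles, %d frames, t = %g..%g ns\n",
              nrow(x$topology), length(x$frames),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Select particles by metadata predicates
#'
#' Builds an ordered, duplicate-free particle selection by intersecting
#' simple predicates on the topology columns.  All arguments are optional;
#' omitted predicates match everything, so \code{select_particles(top)}
#' selects all particles.
#'
#' @param topology a \code{\link{topology}}.
#' @param species optional character vector of species to keep.
#' @param domain optional character vector of domain labels to keep.
#' @param residue_id optional integer vector (or range) of residue ids.
#' @param headgroup optional logical; keep only particles whose
#'   \code{is_headgroup} equals it.
#' @param label text label attached to the selection.
#'
#' @return An object of class \code{"selection"}: a list with 0-based
#'   \code{indices} and a \code{label}.  An empty result is allowed and
#'   raises a warning.
#' @export
select_particles <- function(topology, species = NULL, domain = NULL,
                             residue_id = NULL, headgroup = NULL,
                             label = "selection") {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(species))   keep <- keep & topology$species %in% species
  if (!is.null(domain))    keep <- keep & topology$domain_label %in% domain
  if (!is.null(residue_id)) keep <- keep & topology$residue_id %in% residue_id
  if (!is.null(headgroup)) keep <- keep & topology$is_headgroup == headgroup
  idx <- topology$particle_id[keep]
  if (length(idx) == 0L) warning("selection '", label, "' is empty")
  selection(idx, label)
}

#' Construct a selection from explicit particle ids
#'
#' @param indices 0-based particle ids (duplicates removed, order kept).
#' @param label text label.
#' @return A \code{"selection"} object.
#' @export
selection <- function(indices, label = "selection") {
  indices <- as.integer(indices)
  indices <- indices[!duplicated(indices)]
  structure(list(indices = indices, label = label), class = "selection")
}

# 1-based row indices into a coordinate matrix for a selection
sel_rows <- function(sel) sel$indices + 1L

#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two positions under the minimum-image
#' convention: each Cartesian displacement component is wrapped to the
#' nearest periodic image before the norm is taken.  Used by every
#' cutoff-based analysis in the package.
#'
#' @param a,b numeric length-3 positions in nm (or n x 3 matrices of
#'   positions, compared row-wise).
#' @param box numeric length-3 box lengths in nm, all strictly positive.
#' @return Distance(s) in nm.
#' @export
min_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (any(box <= 0)) stop("box lengths must be strictly positive")
  if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, nrow(b), 3, byrow = TRUE)
    b <- if (is.matrix(b)) b else matrix(b, nrow(a), 3, byrow = TRUE)
    d <- a - b
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    sqrt(rowSums(d * d))
  } else {
    d <- a - b
    d <- d - box * round(d / box)
    sqrt(sum(d * d))
  }
}

# minimum-image displacement vectors (matrix rows), used by MSD unwrapping
min_image_disp <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Centre of mass of a selection in one frame
#'
#' Mass-weighted mean position of the selected particles.  With uniform
#' masses this is the centroid; bead-count weighting can be forced with
#' \code{weighted = FALSE}.
#'
#' @param frame a \code{\link{frame}}.
#' @param sel a \code{\link{selection}} (non-empty).
#' @param topology the matching \code{\link{topology}}.
#' @param weighted mass-weight (default) or plain centroid.
#' @return Numeric length-3 position in nm.
#' @export
center_of_mass <- function(frame, sel, topology, weighted = TRUE) {
  rows <- sel_rows(sel)
  if (length(rows) == 0L) stop("center_of_mass: empty selection")
  x <- frame$coordinates[rows, , drop = FALSE]
  if (weighted) {
    m <- topology$mass[rows]
    colSums(x * m) / sum(m)
  } else {
    colMeans(x)
  }
}
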