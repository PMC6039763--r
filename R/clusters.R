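# PIP nanoclustering statistics: per-frame interacting-lipid counts,
# count-distribution Gaussian fits, per-lipid interaction time courses and
# residence times, and species-resolved lateral diffusion from the mean
# squared displacement (MSD = 4 D t in two dimensions).

#' Per-frame interacting-lipid count
#'
#' Number of distinct lipid molecules of a species whose headgroup lies
#' within \code{cutoff} (minimum image) of any protein particle.  Counting is
#' per molecule: a lipid with three headgroup beads inside the cutoff counts
#' once.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param protein_sel \code{\link{selection}} of protein particles.
#' @param species lipid species (\code{"PC"}, \code{"PS"}, \code{"PIP2"},
#'   \code{"PIP3"}); must be present in the topology.
#' @param cutoff interaction cutoff in nm, default 0.8.
#' @return Integer vector, one count per frame.
#' @export
interacting_lipid_count <- function(traj, protein_sel, species, cutoff = 0.8) {
  tc <- lipid_timecourse(traj, protein_sel, species, cutoff)
  colSums(tc$matrix)
}

#' Per-lipid interaction time course
#'
#' Boolean lipid x frame matrix, TRUE when any headgroup bead of the lipid is
#' within \code{cutoff} of any protein particle in that frame.  Column sums
#' reproduce \code{\link{interacting_lipid_count}} exactly.
#'
#' @inheritParams interacting_lipid_count
#' @return list of class \code{"lipid_timecourse"} with \code{species},
#'   \code{lipid_ids} (molecule ids), \code{matrix} (logical lipid x frame),
#'   \code{cutoff}.
#' @export
lipid_timecourse <- function(traj, protein_sel, species, cutoff = 0.8) {
  stopifnot(cutoff > 0)
  top <- traj$topology
  hrow <- which(top$species == species & top$is_headgroup)
  if (length(hrow) == 0L)
    stop("no ", species, " headgroup particles in the topology")
  prows <- sel_rows(protein_sel)
  if (length(prows) == 0L) stop("empty protein selection")
  lipid_ids <- sort(unique(top$molecule_id[hrow]))
  mol_of <- match(top$molecule_id[hrow], lipid_ids)
  nf <- n_frames(traj)
  M <- matrix(FALSE, length(lipid_ids), nf)
  for (k in seq_len(nf)) {
    f <- traj$frames[[k]]
    H <- f$coordinates[hrow, , drop = FALSE]
    P <- f$coordinates[prows, , drop = FALSE]
    hit <- contact_pairs(H, P, cutoff, f$box)   # heads x protein
    touched <- rowSums(hit) > 0
    if (any(touched)) M[unique(mol_of[touched]), k] <- TRUE
  }
  structure(list(species = species, lipid_ids = lipid_ids, matrix = M,
                 cutoff = cutoff),
            class = "lipid_timecourse")
}

#' Moment-based Gaussian fit to a count distribution
#'
#' Fits a Gaussian to the distribution of per-frame interacting-lipid counts
#' by the method of moments (mean = sample mean, sd = sample standard
#' deviation), optionally restricted to membrane-bound frames.
#'
#' @param series per-frame count series (from
#'   \code{\link{interacting_lipid_count}}).
#' @param bound_intervals optional interval data.frame from
#'   \code{\link{classify_bound}}; when given only frames inside the
#'   intervals enter the fit.
#' @return list of class \code{"gaussian_fit"} with \code{mean}, \code{sd},
#'   \code{n}.
#' @export
count_distribution_fit <- function(series, bound_intervals = NULL) {
  x <- as.numeric(series)
  if (!is.null(bound_intervals))
    x <- x[bound_frame_mask(bound_intervals, length(x))]
  if (length(x) < 2L)
    stop("count_distribution_fit needs at least 2 observations")
  structure(list(mean = mean(x), sd = stats::sd(x), n = length(x)),
            class = "gaussian_fit")
}

#' Residence (dwell) times and persistent/transient labels
#'
#' Maximal interaction runs per lipid, merging interruptions of at most
#' \code{gap_tolerance} frames.  A lipid is labelled "persistent" when its
#' longest dwell covers at least \code{persistent_frac} of the analyzed
#' frames (interactions persisting throughout the trajectory), otherwise
#' "transient".
#'
#' @param tc a \code{\link{lipid_timecourse}}.
#' @param gap_tolerance gaps up to this many frames are bridged (default 1).
#' @param persistent_frac fraction of frames the longest dwell must reach for
#'   a "persistent" label (default 0.5).
#' @return list with \code{dwells} (named list per lipid id of dwell lengths
#'   in frames) and \code{labels} (data.frame: lipid_id, longest_dwell,
#'   label).
#' @export
residence_times <- function(tc, gap_tolerance = 1, persistent_frac = 0.5) {
  stopifnot(gap_tolerance >= 0)
  nf <- ncol(tc$matrix)
  dwells <- vector("list", nrow(tc$matrix))
  names(dwells) <- as.character(tc$lipid_ids)
  longest <- integer(nrow(tc$matrix))
  for (i in seq_len(nrow(tc$matrix))) {
    dwells[[i]] <- dwell_lengths(tc$matrix[i, ], gap_tolerance)
    longest[i] <- if (length(dwells[[i]]) > 0) max(dwells[[i]]) else 0L
  }
  labels <- data.frame(
    lipid_id = tc$lipid_ids,
    longest_dwell = longest,
    label = ifelse(longest >= persistent_frac * nf, "persistent", "transient"),
    stringsAsFactors = FALSE
  )
  list(dwells = dwells, labels = labels)
}

# maximal TRUE runs after merging FALSE gaps of length <= gap_tolerance;
# merged dwell length spans the bridged gaps (first to last TRUE of the run)
dwell_lengths <- function(row, gap_tolerance) {
  r <- rle(as.logical(row))
  if (!any(r$values)) return(integer(0))
  # bridge interior FALSE runs of length <= gap_tolerance
  if (gap_tolerance > 0 && length(r$lengths) > 2L) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    bridge <- interior[!r$values[interior] &
                         r$lengths[interior] <= gap_tolerance]
    r$values[bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  r$lengths[r$values]
}

#' Species-resolved lateral diffusion from MSD
#'
#' Ensemble-averaged 2-D mean squared displacement over xy for the headgroup
#' beads of each requested species, with periodic-boundary unwrapping
#' (accumulated minimum-image frame-to-frame displacements; exact for step
#' sizes below half the box length).  The diffusion coefficient comes from
#' the least-squares slope of MSD = 4 D t over a lag window expressed as
#' fractions of the maximum lag, avoiding the poorly-averaged long-lag
#' regime.
#'
#' @param traj a \code{\link{trajectory}} with uniform time step and >= 3
#'   frames.
#' @param species character vector of lipid species to analyze.
#' @param fit_window numeric length-2 fractions of the maximum lag over which
#'   the line is fitted (default \code{c(0.1, 0.5)}).
#' @param max_lags at most this many distinct lags are evaluated (evenly
#'   spaced), keeping the cost bounded on long trajectories.
#' @return list of class \code{"diffusion_result"} with \code{D} (named
#'   nm^2/ns per species), \code{msd} (data.frame lag_ns x species MSD nm^2)
#'   and \code{fit_window} (ns).
#' @export
lateral_diffusion <- function(traj, species, fit_window = c(0.1, 0.5),
                              max_lags = 100) {
  nf <- n_frames(traj)
  if (nf < 3L) stop("lateral_diffusion needs at least 3 frames")
  times <- vapply(traj$frames, `[[`, numeric(1), "time")
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("lateral_diffusion requires a uniform time step")
  dt <- dts[1]
  top <- traj$topology
  lags <- unique(round(seq(1, nf - 1, length.out = min(max_lags, nf - 1))))
  msd <- data.frame(lag_ns = c(0, lags * dt))
  D <- setNames(numeric(length(species)), species)
  for (sp in species) {
    rows <- which(top$species == sp & top$is_headgroup)
    if (length(rows) == 0L) stop("no ", sp, " headgroup particles present")
    # unwrapped cumulative xy positions: frames x lipids, per axis
    X <- matrix(0, nf, length(rows)); Y <- matrix(0, nf, length(rows))
    prev <- traj$frames[[1]]$coordinates[rows, 1:2, drop = FALSE]
    for (k in 2:nf) {
      cur <- traj$frames[[k]]$coordinates[rows, 1:2, drop = FALSE]
      box <- traj$frames[[k]]$box
      d <- cur - prev
      d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
      d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
      X[k, ] <- X[k - 1, ] + d[, 1]
      Y[k, ] <- Y[k - 1, ] + d[, 2]
      prev <- cur
    }
    m <- vapply(lags, function(L) {
      dx <- X[(L + 1):nf, , drop = FALSE] - X[1:(nf - L), , drop = FALSE]
      dy <- Y[(L + 1):nf, , drop = FALSE] - Y[1:(nf - L), , drop = FALSE]
      mean(dx * dx + dy * dy)
    }, numeric(1))
    msd[[sp]] <- c(0, m)
    tmax <- lags[length(lags)] * dt
    win <- msd$lag_ns >= fit_window[1] * tmax & msd$lag_ns <= fit_window[2] * tmax
    # through-origin weighted least squares: MSD(0) = 0 exactly and the MSD
    # sampling variance grows ~ t^2 over the window, so weights 1/t^2
    tt <- msd$lag_ns[win]
    yy <- msd[[sp]][win]
    slope <- sum(yy / tt) / length(tt)
    D[sp] <- max(0, slope / 4)
  }
  structure(list(D = D, msd = msd,
                 fit_window = fit_window * lags[length(lags)] * dt),
            class = "diffusion_result")
}
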