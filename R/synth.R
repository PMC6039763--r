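# Synthetic-data generator: an overdamped Brownian-dynamics toy model of a
# rigid two-lobe kinase with charged surface patches, an optional
# juxtamembrane tether, and a 2-D membrane of laterally diffusing
# PC/PS/PIP lipids.  It produces trajectories in the package's standard
# containers together with planted ground truth (bound intervals, engaged
# patch, recruited lipid ids, planted diffusion coefficients), so every
# analysis stage can be tested without molecular dynamics input.
#
# Geometry conventions: the membrane mid-plane is z = 0; each lipid carries
# an upper-leaflet headgroup bead at z = +2 nm, a tail bead at z = 0 and a
# lower-leaflet bead at z = -2 nm (all sharing the lipid's xy position), so
# the membrane centre of mass sits exactly at z = 0 and a protein whose
# N-lobe patch touches the headgroup plane has a COM-COM separation dz in
# the 4-5 nm band that marks a stable interaction.  The protein is a rigid
# body of two fused spherical bead shells (N-lobe and C-lobe) with the P1
# patch (residues 609/615/617) and P2 patch (629/633/638/639) on the N-lobe
# face pointing along the body -z axis, a weaker "C-face" patch on the
# C-lobe side, and a JM-anchor bead beyond the N-lobe pole.  Energies are in
# kT (kT = 1).

PATCH_P1_IDS <- c(609L, 615L, 617L)
PATCH_P2_IDS <- c(629L, 633L, 638L, 639L)

#' Parameters for the synthetic Brownian-dynamics generator
#'
#' Defaults define the package's reference study conditions: a 14 x 14 x 18
#' nm box, 300 lipids at 90:5:5 PC:PS:PIP2 (the main membrane composition; a
#' PIP3 variant would use 83:15:2), equal planted lateral diffusion of 0.05
#' nm^2/ns for every species (so any PIP2 slowdown measured downstream is an
#' emergent effect of binding, not an input), attraction of the basic N-lobe
#' patches to anionic headgroups (strongest for PIP2/PIP3, weak for PS, zero
#' for zwitterionic PC), a weaker C-lobe side face that supports the
#' secondary binding mode, and an optional harmonic juxtamembrane tether.
#' Aspartate-substitution mutants are emulated by flipping the sign of patch
#' weights.
#'
#' @param box box lengths (Lx, Ly, Lz) nm; z walls are reflecting, xy
#'   periodic.
#' @param n_lipids number of lipids (upper-leaflet sites).
#' @param composition named fractions over PC/PS/PIP2/PIP3 summing to 1;
#'   realized counts use largest-remainder rounding and are deterministic.
#' @param D_species named lateral diffusion coefficients nm^2/ns.
#' @param D_protein_trans,D_protein_rot protein translational (nm^2/ns) and
#'   rotational (rad^2/ns) diffusion coefficients.
#' @param patch_weights named list (P1, P2, CFACE) of named per-species
#'   attraction weights; positive attracts, negative repels (the in-silico
#'   aspartate mutant), the well depth is \code{epsilon * weight} kT.
#' @param epsilon attraction strength scale, kT.
#' @param interaction_range truncation range of the smooth attractive well,
#'   nm.
#' @param tether list \code{(enabled, k, anchor, rest)}: harmonic spring
#'   (kT/nm^2) between the JM-anchor bead and a fixed membrane anchor point.
#'   \code{anchor = NULL} places it at (Lx/2, Ly/2, headgroup plane).
#' @param dt time step ns.
#' @param n_steps number of integration steps.
#' @param save_every save a frame (and ground truth) every this many steps.
#' @param bound_threshold dz bound threshold nm used for the planted bound
#'   flag.
#' @param start_z initial protein COM height nm above the membrane
#'   mid-plane.
#' @param start_orientation \code{"random"} (seeded) or \code{"reference"}
#'   (patch face down).
#' @param seed RNG seed; identical params + seed give bit-identical output.
#' @return A validated \code{"synthetic_params"} list.
#' @export
synthetic_params <- function(
    box = c(14, 14, 18),
    n_lipids = 300,
    composition = c(PC = 0.90, PS = 0.05, PIP2 = 0.05, PIP3 = 0),
    D_species = c(PC = 0.05, PS = 0.05, PIP2 = 0.05, PIP3 = 0.05),
    D_protein_trans = 0.08,
    D_protein_rot = 0.12,
    patch_weights = list(
      P1    = c(PC = 0, PS = 0.25, PIP2 = 1.0, PIP3 = 1.0),
      P2    = c(PC = 0, PS = 0.25, PIP2 = 0.6, PIP3 = 0.6),
      CFACE = c(PC = 0, PS = 0.2, PIP2 = 0.5, PIP3 = 0.5)),
    epsilon = 6,
    interaction_range = 1.4,
    tether = list(enabled = FALSE, k = 2, anchor = NULL, rest = 1.0),
    dt = 0.05,
    n_steps = 24000,
    save_every = 100,
    bound_threshold = 5.0,
    start_z = 8,
    start_orientation = c("random", "reference"),
    seed = 42) {
  start_orientation <- match.arg(start_orientation)
  composition <- composition[c("PC", "PS", "PIP2", "PIP3")]
  composition[is.na(composition)] <- 0
  names(composition) <- c("PC", "PS", "PIP2", "PIP3")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  if (any(D_species < 0) || D_protein_trans < 0 || D_protein_rot < 0)
    stop("diffusion coefficients must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (is.null(tether$anchor))
    tether$anchor <- c(box[1] / 2, box[2] / 2, 2.0)
  p <- list(box = box, n_lipids = as.integer(n_lipids),
            composition = composition, D_species = D_species,
            D_protein_trans = D_protein_trans, D_protein_rot = D_protein_rot,
            patch_weights = patch_weights, epsilon = epsilon,
            interaction_range = interaction_range, tether = tether,
            dt = dt, n_steps = as.integer(n_steps),
            save_every = as.integer(save_every),
            bound_threshold = bound_threshold, start_z = start_z,
            start_orientation = start_orientation, seed = as.integer(seed))
  class(p) <- "synthetic_params"
  p
}

# deterministic largest-remainder rounding of composition fractions
species_counts <- function(composition, n) {
  raw <- composition * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)   # ties: PC,PS,PIP2,PIP3 order
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

# Rigid two-lobe protein model: Fibonacci-lattice bead shells for the N- and
# C-lobes (radius 1.1 nm, centres at body z = -1.1 / +1.1), P1/P2 beads as
# the shell beads nearest the body -z pole, a C-face patch on the C-lobe +x
# side, and a JM-anchor bead at body (0,0,-2.6).  Body coordinates are
# centred on the bead centroid.
build_protein_model <- function(n_per_lobe = 40, r_lobe = 1.1) {
  fib <- function(n) {
    i <- seq_len(n) - 1
    z <- 1 - 2 * (i + 0.5) / n
    phi <- i * pi * (3 - sqrt(5))
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  }
  shell <- fib(n_per_lobe) * r_lobe
  nl <- sweep(shell, 2, c(0, 0, -r_lobe), "+")   # N-lobe, lower
  cl <- sweep(shell, 2, c(0, 0, +r_lobe), "+")   # C-lobe, upper
  body <- rbind(nl, cl, c(0, 0, -(2 * r_lobe + 0.4)))  # + JM anchor bead
  n_total <- nrow(body)
  jm_row <- n_total

  # residue ids: N-lobe 601..640 with P1/P2 ids given to the beads nearest
  # the -z pole; C-lobe 641..680; JM anchor 590
  pole_rank <- order(nl[, 3])                    # lowest z first
  res_n <- integer(n_per_lobe)
  res_n[pole_rank[1:3]] <- PATCH_P1_IDS
  res_n[pole_rank[4:7]] <- PATCH_P2_IDS
  rest_ids <- setdiff(601:640, c(PATCH_P1_IDS, PATCH_P2_IDS))
  res_n[res_n == 0L] <- rest_ids
  res_c <- 641:680
  residue_id <- c(res_n, res_c, 590L)

  # C-face patch: the C-lobe beads nearest the +x side of the shell
  side_rank <- order(-cl[, 1])
  cface_rows <- n_per_lobe + side_rank[1:4]
  # activation loop marker: two C-lobe beads nearest the lobe interface
  act_rows <- n_per_lobe + order(cl[, 3])[1:2]

  domain <- c(rep("NLOBE", n_per_lobe), rep("CLOBE", n_per_lobe), "JM")
  domain[act_rows] <- "ACTLOOP"
  body <- sweep(body, 2, colMeans(body))
  list(body = body, residue_id = residue_id, domain = domain,
       patch_rows = list(P1 = pole_rank[1:3], P2 = pole_rank[4:7],
                         CFACE = cface_rows),
       jm_row = jm_row, n_beads = n_total)
}

# rotation matrix for a rotation vector (axis * angle)
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix, det corrected
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

build_synth_topology <- function(params, model, lipid_species) {
  n_lip <- params$n_lipids
  res_names <- c(PC = "POPC", PS = "POPS", PIP2 = "POP2", PIP3 = "POP3")
  prot_names <- rep("BB", model$n_beads)
  top <- topology(
    particle_name = c(prot_names,
                      rep(c("PO4", "C4A", "GL2"), n_lip)),
    residue_id   = c(model$residue_id, rep(1000L + seq_len(n_lip), each = 3)),
    residue_name = c(rep("KIN", model$n_beads),
                     rep(res_names[lipid_species], each = 3)),
    molecule_id  = c(rep(1L, model$n_beads), rep(1L + seq_len(n_lip), each = 3)),
    domain_label = c(model$domain, rep("LIPID", 3 * n_lip)),
    species      = c(rep("PROTEIN", model$n_beads),
                     rep(lipid_species, each = 3)),
    is_headgroup = c(rep(FALSE, model$n_beads),
                     rep(c(TRUE, FALSE, FALSE), n_lip))
  )
  top
}

assemble_coordinates <- function(model, com, Q, L) {
  prot <- sweep(model$body %*% t(Q), 2, com, "+")
  n_lip <- nrow(L)
  lip <- matrix(0, 3 * n_lip, 3)
  idx <- seq_len(n_lip)
  lip[3 * idx - 2, ] <- cbind(L, rep(2, n_lip))
  lip[3 * idx - 1, ] <- cbind(L, rep(0, n_lip))
  lip[3 * idx, ]     <- cbind(L, rep(-2, n_lip))
  rbind(prot, lip)
}

#' Simulate a protein-membrane encounter trajectory
#'
#' Overdamped Langevin dynamics: every particle or rigid-body degree of
#' freedom moves by \code{sqrt(2 D dt) xi + (D/kT) F dt} per step (kT = 1).
#' Lipids diffuse laterally with periodic wrapping; the protein is a rigid
#' body with translational and rotational diffusion (random rotation vectors
#' composed each step) plus force and torque from a truncated smooth
#' attractive well of depth \code{epsilon * weight(species)} between patch
#' beads and upper-leaflet headgroups within \code{interaction_range}
#' (cosine-ramped, zero at the truncation), and an optional harmonic tether
#' between the JM-anchor bead and a fixed anchor point.  The headgroup plane
#' is impenetrable (reflecting), as is the top of the box.  Identical params
#' and seed give bit-identical output.
#'
#' @param params a \code{\link{synthetic_params}}.
#' @return list with \code{trajectory} (a \code{\link{trajectory}} of the
#'   full system saved every \code{save_every} steps) and
#'   \code{ground_truth}: per-saved-frame \code{dz}, \code{bound} flag
#'   (dz <= bound_threshold), \code{engaged_patch} (NONE/P1/P2/P1P2/CFACE;
#'   a patch is engaged when it carries positive net weight and has a bead
#'   within interaction range of a headgroup), \code{recruited_ids}
#'   (molecule ids of lipids within interaction range of any patch bead),
#'   \code{bound_intervals}, and \code{D_planted}.
#' @export
simulate_encounter <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  model <- build_protein_model()
  box <- params$box
  rc <- params$interaction_range
  dt <- params$dt
  n_lip <- params$n_lipids

  cnt <- species_counts(params$composition, n_lip)
  lipid_species <- rep(c("PC", "PS", "PIP2", "PIP3"), times = cnt)
  top <- build_synth_topology(params, model, lipid_species)
  D_lip <- params$D_species[lipid_species]

  # per-patch, per-lipid attraction weight (depth in kT = epsilon * weight)
  patch_names <- names(model$patch_rows)
  wmat <- vapply(patch_names, function(pn)
    params$patch_weights[[pn]][lipid_species], numeric(n_lip))
  wmat[is.na(wmat)] <- 0

  L <- cbind(stats::runif(n_lip, 0, box[1]), stats::runif(n_lip, 0, box[2]))
  com <- c(box[1] / 2, box[2] / 2, params$start_z)
  Q <- if (params$start_orientation == "random") random_rotation() else diag(3)

  patch_body <- model$body[unlist(model$patch_rows), , drop = FALSE]
  patch_of <- rep(seq_along(patch_names), lengths(model$patch_rows))
  n_patch <- nrow(patch_body)
  jm_body <- model$body[model$jm_row, ]
  z_head <- 2.0
  # body extent used to decide when force evaluation can be skipped
  reach <- max(sqrt(rowSums(model$body^2))) + rc + 0.5

  saved <- seq(0, params$n_steps, by = params$save_every)
  frames <- vector("list", length(saved))
  gt_dz <- numeric(length(saved))
  gt_patch <- character(length(saved))
  gt_recruited <- vector("list", length(saved))
  save_k <- 1L

  pos_weight <- vapply(seq_along(patch_names), function(j)
    any(wmat[, j] > 0), logical(1))

  record <- function(k, step) {
    frames[[k]] <<- frame(assemble_coordinates(model, com, Q, L), box,
                          time = step * dt)
    gt_dz[k] <<- abs(com[3])
    Xp <- sweep(patch_body %*% t(Q), 2, com, "+")
    engaged <- logical(length(patch_names))
    recruited <- integer(0)
    for (i in seq_len(n_patch)) {
      dx <- Xp[i, 1] - L[, 1]; dx <- dx - box[1] * round(dx / box[1])
      dy <- Xp[i, 2] - L[, 2]; dy <- dy - box[2] * round(dy / box[2])
      r2 <- dx^2 + dy^2 + (Xp[i, 3] - z_head)^2
      inr <- which(r2 <= rc^2)
      if (length(inr) > 0) {
        recruited <- c(recruited, inr)
        if (pos_weight[patch_of[i]]) engaged[patch_of[i]] <- TRUE
      }
    }
    gt_recruited[[k]] <<- sort(unique(recruited)) + 1L   # molecule ids
    gt_patch[k] <<-
      if (engaged[1] && engaged[2]) "P1P2"
      else if (engaged[1]) "P1"
      else if (engaged[2]) "P2"
      else if (length(patch_names) >= 3 && engaged[3]) "CFACE"
      else "NONE"
  }

  record(save_k, 0L)
  for (step in seq_len(params$n_steps)) {
    F_lip <- NULL
    F_prot <- c(0, 0, 0)
    torque <- c(0, 0, 0)
    near <- (com[3] - z_head) < reach
    if (near && params$epsilon != 0) {
      Xp <- sweep(patch_body %*% t(Q), 2, com, "+")
      F_lip <- matrix(0, n_lip, 2)
      for (i in seq_len(n_patch)) {
        if (Xp[i, 3] - z_head > rc) next
        w <- wmat[, patch_of[i]]
        dx <- Xp[i, 1] - L[, 1]; dx <- dx - box[1] * round(dx / box[1])
        dy <- Xp[i, 2] - L[, 2]; dy <- dy - box[2] * round(dy / box[2])
        dz <- Xp[i, 3] - z_head
        r2 <- dx^2 + dy^2 + dz^2
        inr <- which(r2 <= rc^2 & w != 0 & r2 > 1e-12)
        if (length(inr) == 0L) next
        r <- sqrt(r2[inr])
        # U(r) = -eps*w/2 (1 + cos(pi r / rc));  F = -dU/dr along r-hat
        fmag <- -params$epsilon * w[inr] * pi / (2 * rc) * sin(pi * r / rc)
        # force on lipid points from lipid toward bead when attractive
        fx <- fmag * (-dx[inr] / r); fy <- fmag * (-dy[inr] / r)
        fz <- fmag * (-dz / r)
        F_lip[inr, 1] <- F_lip[inr, 1] + fx
        F_lip[inr, 2] <- F_lip[inr, 2] + fy
        fb <- c(-sum(fx), -sum(fy), -sum(fz))   # reaction on the patch bead
        F_prot <- F_prot + fb
        arm <- Xp[i, ] - com
        torque <- torque + c(arm[2] * fb[3] - arm[3] * fb[2],
                             arm[3] * fb[1] - arm[1] * fb[3],
                             arm[1] * fb[2] - arm[2] * fb[1])
      }
    }
    if (params$tether$enabled) {
      xj <- com + as.numeric(Q %*% jm_body)
      dvec <- xj - params$tether$anchor
      dlen <- sqrt(sum(dvec^2))
      if (dlen > 1e-9) {
        ft <- -params$tether$k * (dlen - params$tether$rest) * dvec / dlen
        F_prot <- F_prot + ft
        arm <- xj - com
        torque <- torque + c(arm[2] * ft[3] - arm[3] * ft[2],
                             arm[3] * ft[1] - arm[1] * ft[3],
                             arm[1] * ft[2] - arm[2] * ft[1])
      }
    }

    # lipid update: lateral Brownian step + drift, periodic wrap
    noise <- matrix(stats::rnorm(2 * n_lip), n_lip, 2)
    L <- L + sqrt(2 * D_lip * dt) * noise
    if (!is.null(F_lip)) L <- L + D_lip * dt * F_lip
    L[, 1] <- L[, 1] %% box[1]
    L[, 2] <- L[, 2] %% box[2]

    # protein rigid-body update
    com <- com + sqrt(2 * params$D_protein_trans * dt) * stats::rnorm(3) +
      params$D_protein_trans * dt * F_prot
    rotvec <- sqrt(2 * params$D_protein_rot * dt) * stats::rnorm(3) +
      params$D_protein_rot * dt * torque
    Q <- rotvec_to_matrix(rotvec) %*% Q
    com[1] <- com[1] %% box[1]
    com[2] <- com[2] %% box[2]

    # reflecting walls: headgroup plane below, box top above
    zb <- com[3] + (model$body %*% t(Q))[, 3]
    minz <- min(zb); maxz <- max(zb)
    if (minz < z_head) com[3] <- com[3] + 2 * (z_head - minz)
    else if (maxz > box[3]) com[3] <- com[3] - 2 * (maxz - box[3])

    if (step %% params$save_every == 0L) {
      save_k <- save_k + 1L
      record(save_k, step)
    }
  }

  bound <- gt_dz <= params$bound_threshold
  runs <- rle(bound)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  intervals <- data.frame(start = starts[runs$values], end = ends[runs$values])
  gt <- list(dz = gt_dz, bound = bound, engaged_patch = gt_patch,
             recruited_ids = gt_recruited, bound_intervals = intervals,
             D_planted = params$D_species, params = params)
  class(gt) <- "ground_truth"
  list(trajectory = trajectory(top, frames), ground_truth = gt)
}

#' Simulate a protein-free membrane (lipids only)
#'
#' Free 2-D lateral diffusion of every lipid at its planted per-species
#' diffusion coefficient, with periodic wrapping.  Species counts follow the
#' composition by largest-remainder rounding, so realized counts are
#' deterministic (e.g. 0.90/0.05/0.05 over 2000 lipids gives exactly
#' 1800/100/100).
#'
#' @param params a \code{\link{synthetic_params}} (protein-related fields are
#'   ignored).
#' @return list with \code{trajectory} and \code{ground_truth} (planted D
#'   values).
#' @export
simulate_membrane_only <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  box <- params$box
  n_lip <- params$n_lipids
  cnt <- species_counts(params$composition, n_lip)
  lipid_species <- rep(c("PC", "PS", "PIP2", "PIP3"), times = cnt)
  D_lip <- params$D_species[lipid_species]
  res_names <- c(PC = "POPC", PS = "POPS", PIP2 = "POP2", PIP3 = "POP3")
  top <- topology(
    particle_name = rep(c("PO4", "C4A", "GL2"), n_lip),
    residue_id   = rep(1000L + seq_len(n_lip), each = 3),
    residue_name = rep(res_names[lipid_species], each = 3),
    molecule_id  = rep(seq_len(n_lip), each = 3),
    domain_label = rep("LIPID", 3 * n_lip),
    species      = rep(lipid_species, each = 3),
    is_headgroup = rep(c(TRUE, FALSE, FALSE), n_lip)
  )
  L <- cbind(stats::runif(n_lip, 0, box[1]), stats::runif(n_lip, 0, box[2]))
  lip_coords <- function(L) {
    out <- matrix(0, 3 * n_lip, 3)
    idx <- seq_len(n_lip)
    out[3 * idx - 2, ] <- cbind(L, rep(2, n_lip))
    out[3 * idx - 1, ] <- cbind(L, rep(0, n_lip))
    out[3 * idx, ]     <- cbind(L, rep(-2, n_lip))
    out
  }
  saved <- seq(0, params$n_steps, by = params$save_every)
  frames <- vector("list", length(saved))
  frames[[1]] <- frame(lip_coords(L), box, time = 0)
  k <- 1L
  sig <- sqrt(2 * D_lip * params$dt)
  for (step in seq_len(params$n_steps)) {
    L <- L + sig * matrix(stats::rnorm(2 * n_lip), n_lip, 2)
    L[, 1] <- L[, 1] %% box[1]
    L[, 2] <- L[, 2] %% box[2]
    if (step %% params$save_every == 0L) {
      k <- k + 1L
      frames[[k]] <- frame(lip_coords(L), box, time = step * params$dt)
    }
  }
  gt <- list(dz = numeric(0), bound = logical(0),
             engaged_patch = character(0), recruited_ids = list(),
             bound_intervals = data.frame(start = integer(0), end = integer(0)),
             D_planted = params$D_species, params = params)
  class(gt) <- "ground_truth"
  list(trajectory = trajectory(top, frames), ground_truth = gt)
}

#' Summarize planted ground truth
#'
#' @param gt a \code{"ground_truth"} object from the generator.
#' @return list with \code{bound_fraction}, \code{dominant_patch} (majority
#'   engaged patch over bound frames; NONE when never bound),
#'   \code{mean_recruited} (mean per-frame recruited-lipid count) and
#'   \code{D_planted}.
#' @export
ground_truth_report <- function(gt) {
  nb <- sum(gt$bound)
  dom <- if (nb == 0) "NONE" else {
    tb <- table(gt$engaged_patch[gt$bound])
    tb <- tb[names(tb) != "NONE"]
    if (length(tb) == 0) "NONE" else names(which.max(tb))
  }
  list(
    bound_fraction = if (length(gt$bound) > 0) mean(gt$bound) else 0,
    dominant_patch = dom,
    mean_recruited = if (length(gt$recruited_ids) > 0)
      mean(lengths(gt$recruited_ids)) else 0,
    D_planted = gt$D_planted
  )
}

#' Reference patch-weight scenarios
#'
#' Named weight sets used throughout the package's analyses and tests:
#' \describe{
#'   \item{wildtype}{the \code{\link{synthetic_params}} defaults: both
#'     N-lobe patches attract anionic headgroups, plus the weaker C-lobe
#'     side face.}
#'   \item{p1_only}{attraction confined to the P1 patch (broad, moderate
#'     well: PS 0.5, PIP2 1.2), P2 and the C-face inert; plants unambiguous
#'     single-patch, N-lobe-down engagement.}
#'   \item{mutant_p1p2}{the aspartate-substitution emulation: the default P1
#'     and P2 weights with flipped sign (basic patches turned repulsive),
#'     C-face unchanged, so binding can only proceed through the C-lobe
#'     side face (mode 2 geometry).}
#' }
#'
#' @param name scenario name.
#' @return A patch-weight list for \code{\link{synthetic_params}}.
#' @export
patch_scenario <- function(name = c("wildtype", "p1_only", "mutant_p1p2")) {
  name <- match.arg(name)
  wt <- eval(formals(synthetic_params)$patch_weights)
  switch(name,
    wildtype = wt,
    p1_only = list(
      P1    = c(PC = 0, PS = 0.5, PIP2 = 1.2, PIP3 = 1.2),
      P2    = c(PC = 0, PS = 0, PIP2 = 0, PIP3 = 0),
      CFACE = c(PC = 0, PS = 0, PIP2 = 0, PIP3 = 0)),
    mutant_p1p2 = list(P1 = -wt$P1, P2 = -wt$P2, CFACE = wt$CFACE)
  )
}

#' Standard selections for generator output
#'
#' Convenience bundle of the selections every analysis stage needs on a
#' synthetic trajectory: protein, N-lobe (including patch/activation-loop
#' beads), C-lobe, JM anchor, membrane, and per-species headgroups.
#'
#' @param topology topology of a generator trajectory.
#' @return named list of \code{\link{selection}}s.
#' @export
synth_selections <- function(topology) {
  nlobe_res <- 601:640
  list(
    protein = select_particles(topology, species = "PROTEIN", label = "protein"),
    nlobe = selection(topology$particle_id[
      topology$species == "PROTEIN" & topology$residue_id %in% nlobe_res],
      "nlobe"),
    clobe = selection(topology$particle_id[
      topology$species == "PROTEIN" & topology$residue_id %in% 641:680],
      "clobe"),
    jm = select_particles(topology, domain = "JM", label = "jm"),
    membrane = select_particles(topology, domain = "LIPID", label = "membrane"),
    headgroups = select_particles(topology, headgroup = TRUE,
                                  label = "headgroups")
  )
}
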