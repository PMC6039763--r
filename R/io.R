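# Structure / trajectory I/O.
#
# Internal unit is nm throughout.  GRO files are already nm; PDB files are
# read and written in Angstrom with conversion at the boundary.  Orthorhombic
# boxes only: triclinic GRO box lines (9 numbers with nonzero off-diagonals)
# raise an explicit unsupported-feature error.

NM_PER_ANGSTROM <- 0.1

#' Read a structure file with species and domain assignment
#'
#' Parses a single-frame PDB or GRO file and assigns lipid species, headgroup
#' flags and protein domain labels from user-supplied maps.  Species and
#' headgroup identity are never inferred from chemistry; they always come
#' from \code{species_map}.
#'
#' @param path PDB (Angstrom) or GRO (nm) file; format chosen by extension.
#' @param species_map named list: \code{residue_name -> list(species =,
#'   headgroup_names = character())}.  Every lipid residue name in the file
#'   must appear; protein residues may be omitted (default species PROTEIN).
#'   Read one from YAML with \code{\link{read_species_map}}.
#' @param domain_map data.frame with columns \code{from}, \code{to},
#'   \code{domain} assigning protein residue-id ranges to domain labels
#'   (TM/JM/NLOBE/CLOBE/ACTLOOP); unmapped protein residues get OTHER.
#'   Read one from YAML with \code{\link{read_domain_map}}.
#' @param default_mass mass (amu) given to every particle; coarse-grained
#'   bead default 72.
#'
#' @return list with elements \code{topology} and \code{frame} (coordinates
#'   in nm regardless of the input dialect).
#' @export
read_structure <- function(path, species_map, domain_map = NULL,
                           default_mass = 72) {
  raw <- switch(tolower(tools::file_ext(path)),
    "gro" = read_gro_raw(path),
    "pdb" = read_pdb_raw(path, first_model_only = TRUE),
    stop("unsupported structure format: ", path)
  )
  top <- assign_metadata(raw, species_map, domain_map, default_mass)
  list(topology = top,
       frame = frame(raw$coordinates, raw$box, time = raw$time))
}

#' Read a multi-frame trajectory
#'
#' Supported formats: the package's plain-text one-frame-per-block dialect
#' (\code{.trj}, see \code{\link{write_traj_text}}), multi-model PDB, and DCD
#' (via the bio3d package).  XTC is not supported and raises an explicit
#' error.
#'
#' @param path trajectory file.
#' @param topology the \code{\link{topology}} the frames belong to; the frame
#'   particle count must match.
#' @return A \code{\link{trajectory}} with strictly increasing frame times.
#' @export
read_trajectory <- function(path, topology) {
  ext <- tolower(tools::file_ext(path))
  frames <- switch(ext,
    "trj" = read_traj_text_frames(path),
    "pdb" = read_pdb_frames(path),
    "dcd" = read_dcd_frames(path),
    "xtc" = stop("XTC reading is not supported; convert to the text ",
                 "trajectory dialect, multi-model PDB or DCD"),
    stop("unsupported trajectory format: ", path)
  )
  n <- nrow(topology)
  for (f in frames)
    if (nrow(f$coordinates) != n)
      stop("frame particle count mismatch: expected ", n,
           ", found ", nrow(f$coordinates))
  trajectory(topology, frames)
}

# ---- GRO ------------------------------------------------------------------

read_gro_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (too short): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file at line 2 (atom count): ", path)
  if (length(lines) < n + 3L)
    stop("malformed GRO file: ", n, " atoms declared, file truncated")
  at <- lines[3:(n + 2)]
  res_id  <- as.integer(substr(at, 1, 5))
  res_nm  <- trimws(substr(at, 6, 10))
  atom_nm <- trimws(substr(at, 11, 15))
  xyz <- matrix(NA_real_, n, 3)
  for (j in 1:3) {
    v <- suppressWarnings(as.numeric(substr(at, 21 + (j - 1) * 8, 28 + (j - 1) * 8)))
    if (any(is.na(v)))
      stop("malformed GRO coordinate at line ", which(is.na(v))[1] + 2)
    xyz[, j] <- v
  }
  boxv <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  if (length(boxv) >= 9 && any(abs(boxv[4:9]) > 1e-12))
    stop("triclinic boxes are not supported (orthorhombic only)")
  box <- boxv[1:3]
  list(residue_id = res_id, residue_name = res_nm, particle_name = atom_nm,
       coordinates = xyz, box = box, time = 0)
}

#' Write a single frame as GRO
#'
#' @param path output file.
#' @param topology a \code{\link{topology}}.
#' @param frame a \code{\link{frame}} (nm; GRO is written in nm).
#' @param title title line.
#' @export
write_gro <- function(path, topology, frame, title = "membmode frame") {
  n <- nrow(topology)
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                topology$residue_id %% 100000L,
                substr(topology$residue_name, 1, 5),
                substr(topology$particle_name, 1, 5),
                (topology$particle_id + 1L) %% 100000L,
                frame$coordinates[, 1], frame$coordinates[, 2],
                frame$coordinates[, 3])
  writeLines(c(title, sprintf("%5d", n), at,
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                       frame$box[3])), path)
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

read_pdb_raw <- function(path, first_model_only = TRUE) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  box <- c(10, 10, 10)
  if (length(cry) >= 1)
    box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33))) * NM_PER_ANGSTROM
  end1 <- grep("^ENDMDL", lines)[1]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (first_model_only && !is.na(end1)) sel <- sel & seq_along(lines) < end1
  at <- lines[sel]
  if (length(at) == 0L) stop("malformed PDB (no ATOM records): ", path)
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54))) * NM_PER_ANGSTROM
  if (any(is.na(xyz)))
    stop("malformed PDB coordinate at line ",
         which(sel)[which(is.na(rowSums(xyz)))[1]])
  list(residue_id = as.integer(substr(at, 23, 26)),
       residue_name = trimws(substr(at, 18, 21)),
       particle_name = trimws(substr(at, 13, 16)),
       coordinates = xyz, box = box, time = 0)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  box <- c(10, 10, 10)
  if (length(cry) >= 1)
    box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33))) * NM_PER_ANGSTROM
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) model_starts <- 1L
  bounds <- c(model_starts, length(lines) + 1L)
  frames <- vector("list", length(model_starts))
  for (k in seq_along(model_starts)) {
    rng <- seq(bounds[k], bounds[k + 1] - 1L)
    at <- lines[rng][is_atom[rng]]
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54))) * NM_PER_ANGSTROM
    frames[[k]] <- frame(xyz, box, time = k - 1)
  }
  frames
}

#' Write coordinates as a (multi-model) PDB
#'
#' Coordinates are converted from nm to Angstrom on output.
#'
#' @param path output file.
#' @param topology a \code{\link{topology}}.
#' @param frames a single \code{\link{frame}} or list of frames (one MODEL
#'   each).
#' @export
write_pdb <- function(path, topology, frames) {
  if (inherits(frames, "frame")) frames <- list(frames)
  box <- frames[[1]]$box / NM_PER_ANGSTROM
  out <- c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   box[1], box[2], box[3]))
  chain <- ifelse(topology$species == "PROTEIN", "A", "B")
  for (k in seq_along(frames)) {
    xyz <- frames[[k]]$coordinates / NM_PER_ANGSTROM
    out <- c(out, sprintf("MODEL     %4d", k),
             sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     (topology$particle_id + 1L) %% 100000L,
                     substr(topology$particle_name, 1, 4),
                     substr(topology$residue_name, 1, 4),
                     chain, topology$residue_id %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

read_dcd_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("DCD reading requires the bio3d package")
  x <- bio3d::read.dcd(path, verbose = FALSE)
  lapply(seq_len(nrow(x)), function(k)
    frame(matrix(x[k, ], ncol = 3, byrow = TRUE) * NM_PER_ANGSTROM,
          box = c(10, 10, 10), time = k - 1))
}

# ---- plain-text trajectory dialect ---------------------------------------
#
# One frame per block:
#   FRAME <time_ns>
#   BOX <Lx> <Ly> <Lz>
#   <n> coordinate lines "x y z" (%.6f)
# Deterministic formatting makes write -> read -> write byte-identical.

#' Write a trajectory in the plain-text dialect
#'
#' One block per frame (\code{FRAME time}, \code{BOX Lx Ly Lz}, then one
#' \code{x y z} line per particle, all \code{\%.6f}).  The formatting is
#' deterministic: write / read / write produces a byte-identical file, which
#' the test suite relies on.
#'
#' @param path output file (conventionally \code{.trj}).
#' @param traj a \code{\link{trajectory}}.
#' @export
write_traj_text <- function(path, traj) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("FRAME %.6f", f$time), con)
    writeLines(sprintf("BOX %.6f %.6f %.6f", f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%.6f %.6f %.6f", f$coordinates[, 1],
                       f$coordinates[, 2], f$coordinates[, 3]), con)
  }
  invisible(path)
}

read_traj_text_frames <- function(path) {
  lines <- readLines(path)
  starts <- grep("^FRAME ", lines)
  if (length(starts) == 0L) stop("malformed text trajectory (no FRAME): ", path)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(k) {
    i <- starts[k]
    tm <- as.numeric(sub("^FRAME ", "", lines[i]))
    box <- as.numeric(strsplit(sub("^BOX ", "", lines[i + 1]), " ")[[1]])
    coord_lines <- lines[(i + 2):(bounds[k + 1] - 1L)]
    xyz <- matrix(as.numeric(unlist(strsplit(coord_lines, " "))),
                  ncol = 3, byrow = TRUE)
    frame(xyz, box, time = tm)
  })
}

# ---- species / domain maps -----------------------------------------------

#' Read a species map from YAML
#'
#' Schema: top-level mapping \code{residue_name: {species: PC|PS|PIP2|PIP3,
#' headgroup_names: [bead names]}}.
#'
#' @param path YAML file.
#' @return Named list usable as \code{species_map} in
#'   \code{\link{read_structure}}.
#' @export
read_species_map <- function(path) yaml::read_yaml(path)

#' Read a domain map from YAML
#'
#' Schema: list of \code{{from: id, to: id, domain: LABEL}} entries.
#'
#' @param path YAML file.
#' @return data.frame with columns \code{from}, \code{to}, \code{domain}.
#' @export
read_domain_map <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(rbind, lapply(x, function(e)
    data.frame(from = as.integer(e$from), to = as.integer(e$to),
               domain = as.character(e$domain), stringsAsFactors = FALSE)))
}

#' Write species / domain maps as YAML
#' @param species_map named list (see \code{\link{read_species_map}}).
#' @param path output file.
#' @export
write_species_map <- function(species_map, path) {
  yaml::write_yaml(species_map, path); invisible(path)
}

#' @rdname write_species_map
#' @param domain_map data.frame with columns from, to, domain.
#' @export
write_domain_map <- function(domain_map, path) {
  yaml::write_yaml(lapply(seq_len(nrow(domain_map)), function(i)
    list(from = domain_map$from[i], to = domain_map$to[i],
         domain = domain_map$domain[i])), path)
  invisible(path)
}

assign_metadata <- function(raw, species_map, domain_map, default_mass) {
  n <- length(raw$residue_id)
  species <- rep("PROTEIN", n)
  head <- rep(FALSE, n)
  domain <- rep("OTHER", n)
  lipid_res <- raw$residue_name %in% names(species_map)
  for (rn in unique(raw$residue_name[lipid_res])) {
    ent <- species_map[[rn]]
    rows <- raw$residue_name == rn
    species[rows] <- ent$species
    head[rows] <- raw$particle_name[rows] %in% ent$headgroup_names
    domain[rows] <- "LIPID"
  }
  # residues that carry a lipid-like name but are missing from the map are a
  # hard error (species is never inferred); true protein residues fall
  # through to the domain map
  bad <- unique(raw$residue_name[!lipid_res])
  bad <- bad[grepl("^(PO|PI|DP|DO|PA|PG)", bad)]
  if (length(bad) > 0)
    stop("lipid residue name(s) absent from species_map: ",
         paste(bad, collapse = ", "))
  if (!is.null(domain_map)) {
    prot <- !lipid_res
    for (i in seq_len(nrow(domain_map))) {
      rows <- prot & raw$residue_id >= domain_map$from[i] &
        raw$residue_id <= domain_map$to[i]
      domain[rows] <- domain_map$domain[i]
    }
  }
  # molecule ids: consecutive runs of the same residue_id form one molecule
  mol <- cumsum(c(1L, as.integer(diff(raw$residue_id) != 0)))
  topology(particle_name = raw$particle_name, residue_id = raw$residue_id,
           residue_name = raw$residue_name, molecule_id = mol,
           domain_label = domain, species = species, is_headgroup = head,
           mass = rep(default_mass, n))
}
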