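# Topology and trajectory containers. Coordinates are stored the way the
# structural-bioinformatics R ecosystem (bio3d) stores them: one row per
# frame, columns interleaved x1,y1,z1,x2,... in Angstrom.

.infer_element <- function(name) {
  # PDB files without an element column: take the leading alphabetic
  # character(s) of the atom name; two-letter elements are only accepted
  # when they match a known table entry (e.g. CL), so CA stays carbon.
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG"), two, one)
}

#' Read a PDB topology
#'
#' Parses ATOM/HETATM records of a (possibly multi-model) PDB file into a
#' topology: an ordered atom table plus chain bookkeeping. Capping groups
#' (ACE/NHE/NME) are retained as ordinary residues. Elements missing from
#' the file are inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @return Object of class `topology`: list with `atoms` (data frame with
#'   columns `serial`, `name`, `element`, `residue_index`, `residue_name`,
#'   `chain_id`), `chains` (chain ids in file order), `n_models` (MODEL
#'   blocks detected; 1 for single-model files) and `xyz` (coordinates of
#'   the first model, interleaved).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse failure in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB file '", path, "' contains zero atoms")
  if (anyDuplicated(at$eleno)) {
    d <- at$eleno[duplicated(at$eleno)][1]
    stop("duplicate atom serial ", d, " in '", path, "'")
  }
  ele <- at$elesy
  miss <- is.na(ele) | !nzchar(trimws(ele))
  ele[miss] <- .infer_element(at$elety[miss])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial        = at$eleno,
    name          = at$elety,
    element       = toupper(trimws(ele)),
    residue_index = at$resno,
    residue_name  = at$resid,
    chain_id      = chain,
    stringsAsFactors = FALSE
  )
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  out <- list(atoms = atoms,
              chains = unique(chain),
              n_models = nmod,
              xyz = if (is.matrix(pdb$xyz)) pdb$xyz[1, ] else as.numeric(pdb$xyz),
              source = path)
  class(out) <- "topology"
  out
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ","), "],",
      x$n_models, "model(s)\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology A `topology` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Build a trajectory object
#'
#' @param xyz Numeric matrix, frames x (3 * n_atoms), interleaved
#'   coordinates in Angstrom.
#' @param topology The matching `topology`.
#' @param frame_interval_ps Time between stored frames in ps (> 0).
#' @param box_volume Optional per-frame box volume in Angstrom^3.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(xyz, topology, frame_interval_ps, box_volume = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x ",
         n_atoms(topology), " topology atoms")
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0)
    stop("frame_interval_ps must be > 0")
  out <- list(xyz = xyz, topology = topology,
              frame_interval_ps = frame_interval_ps,
              box_volume = box_volume)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.4g ps/frame (%.4g ns)\n",
              n_frames(x), n_atoms(x$topology), x$frame_interval_ps,
              n_frames(x) * x$frame_interval_ps / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory` object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj A `trajectory` object.
#' @param i Frame index.
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Simulation time axis of a trajectory
#' @param traj A `trajectory` object.
#' @return Numeric vector of frame times in ns (first frame at one
#'   interval, i.e. the time already simulated when the frame was stored).
#' @export
frame_times_ns <- function(traj) {
  seq_len(n_frames(traj)) * traj$frame_interval_ps / 1000
}

#' Read a coordinate trajectory
#'
#' Reads one or more DCD or multi-model PDB files and concatenates their
#' frames in file order. Atom counts are checked against the topology.
#'
#' @param paths Character vector of DCD or PDB file paths (format decided
#'   by extension; anything not ending in `.dcd` is parsed as PDB).
#' @param topology The matching `topology`.
#' @param frame_interval_ps Time between stored frames in ps.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(paths, topology, frame_interval_ps) {
  blocks <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read trajectory file: ", p)
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
    }
    if (ncol(xyz) != 3L * n_atoms(topology))
      stop("atom-count mismatch in '", p, "': file has ", ncol(xyz) / 3,
           " atoms, topology has ", n_atoms(topology))
    xyz
  })
  trajectory(do.call(rbind, blocks), topology, frame_interval_ps)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (no unit cell), sufficient to
#' round-trip coordinates through standard DCD readers.
#'
#' @param traj A `trajectory` object (or plain xyz matrix).
#' @param path Output file path.
#' @param frame_interval_ps Frame spacing recorded in the header; taken
#'   from `traj` when available.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path, frame_interval_ps = NULL) {
  xyz <- if (inherits(traj, "trajectory")) traj$xyz else as.matrix(traj)
  if (is.null(frame_interval_ps) && inherits(traj, "trajectory"))
    frame_interval_ps <- traj$frame_interval_ps
  nf <- nrow(xyz); na <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length markers fore and aft
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  rec(function(rc) {
    writeChar("CORD", rc, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
    icntrl[20] <- 24L  # CHARMM version flag
    writeBin(icntrl[1:9], rc, size = 4)
    writeBin(as.numeric(if (is.null(frame_interval_ps)) 1 else
      frame_interval_ps), rc, size = 4)  # DELTA as float32
    writeBin(icntrl[11:20], rc, size = 4)
  })
  rec(function(rc) {
    writeBin(1L, rc, size = 4)
    writeChar(formatC("written by idpbind", width = -80), rc,
              nchars = 80, eos = NULL)
  })
  rec(function(rc) writeBin(na, rc, size = 4))
  ix <- seq(1, 3 * na, by = 3)
  for (f in seq_len(nf)) {
    for (off in 0:2) {
      v <- xyz[f, ix + off]
      rec(function(rc) writeBin(as.numeric(v), rc, size = 4))
    }
  }
  invisible(path)
}

#' Write a (multi-model) PDB file
#'
#' Writes one MODEL block per frame using fixed-width ATOM records with
#' three-decimal coordinates.
#'
#' @param topology A `topology` object.
#' @param xyz Frames x (3 * n_atoms) coordinate matrix; defaults to the
#'   topology's own model-1 coordinates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(topology, xyz = NULL, path) {
  if (is.null(xyz)) xyz <- matrix(topology$xyz, nrow = 1)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  at <- topology$atoms
  if (ncol(xyz) != 3L * nrow(at)) stop("coordinate/atom-count mismatch")
  con <- file(path, "w")
  on.exit(close(con))
  pad_name <- function(n) ifelse(nchar(n) < 4, sprintf(" %-3s", n),
                                 substr(n, 1, 4))
  for (m in seq_len(nrow(xyz))) {
    crd <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000L, pad_name(at$name), "", at$residue_name,
      at$chain_id, at$residue_index, "", crd[, 1], crd[, 2], crd[, 3],
      1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Atom-index helpers -------------------------------------------------------

#' Select atom indices from a topology
#'
#' @param topology A `topology` object.
#' @param chain Optional chain id.
#' @param residue Optional residue index (within-chain numbering).
#' @param name Optional atom name(s), e.g. "CA".
#' @param element Optional element(s).
#' @return Integer vector of atom row indices.
#' @export
atom_select <- function(topology, chain = NULL, residue = NULL, name = NULL,
                        element = NULL) {
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain_id %in% chain
  if (!is.null(residue)) keep <- keep & at$residue_index %in% residue
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  which(keep)
}

# Calpha atom index of one residue; errors naming the residue if absent.
.ca_index <- function(topology, chain, residue) {
  i <- atom_select(topology, chain = chain, residue = residue, name = "CA")
  if (length(i) != 1)
    stop("residue ", residue, " (chain ", chain, ") lacks a unique CA atom")
  i
}
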