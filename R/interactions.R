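# Intermolecular interaction detection.

# Per-frame hydrogen-bond geometry: acceptor--donor-heavy distance below
# dist_max AND acceptor-hydrogen-donor angle (vertex at the hydrogen)
# above angle_min degrees.
.hbond_geometry <- function(xyz, acceptor, hydrogen, donor_heavy,
                            dist_max, angle_min) {
  d <- .pair_dist(xyz, acceptor, donor_heavy)
  va <- xyz[, .xyz_cols(acceptor), drop = FALSE] -
    xyz[, .xyz_cols(hydrogen), drop = FALSE]
  vd <- xyz[, .xyz_cols(donor_heavy), drop = FALSE] -
    xyz[, .xyz_cols(hydrogen), drop = FALSE]
  cosang <- rowSums(va * vd) /
    (sqrt(rowSums(va * va)) * sqrt(rowSums(vd * vd)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  d < dist_max & ang > angle_min
}

# Residue center-of-mass time series. Heavy atoms with unit masses
# (geometric center) unless a named element mass table is supplied.
# Returns list of frames x 3 matrices, one per residue.
.residue_com <- function(traj, chain, residues, masses = NULL) {
  topo <- traj$topology
  lapply(residues, function(r) {
    a <- atom_select(topo, chain = chain, residue = r)
    a <- a[topo$atoms$element[a] != "H"]
    if (!length(a)) stop("residue ", r, " (chain ", chain, ") has no heavy atoms")
    w <- if (is.null(masses)) rep(1, length(a)) else {
      m <- masses[topo$atoms$element[a]]
      if (anyNA(m)) stop("mass missing for element(s): ",
                         paste(unique(topo$atoms$element[a][is.na(m)]),
                               collapse = ", "))
      m
    }
    w <- w / sum(w)
    out <- matrix(0, n_frames(traj), 3)
    for (k in seq_along(a))
      out <- out + w[k] * traj$xyz[, .xyz_cols(a[k]), drop = FALSE]
    out
  })
}

#' Residue contact map
#'
#' A peptide and a domain residue are in contact in a frame when the
#' distance between their residue centers of mass (heavy atoms, unit
#' masses unless `masses` given) is at or below the cutoff (default 8 A).
#' The map entry is the fraction of the selected frames with the contact.
#'
#' @param traj A [trajectory()].
#' @param config An [analysis_config()].
#' @param peptide_chain,domain_chain Chain ids (auto-detected by default).
#' @param peptide_positions Peptide positions to include (default: all).
#' @param domain_residues Domain residue indices (default: all).
#' @param frames Optional frame subset defining the ensemble.
#' @param label Ensemble label stored with the map.
#' @param masses Optional named element mass table for the centers of mass.
#' @param keep_frames If `TRUE`, also return the per-frame boolean contact
#'   array (frames x peptide x domain).
#' @return Object of class `contact_map`: list with `fraction` (matrix,
#'   peptide positions x domain residues, entries in [0, 1]),
#'   `per_frame_counts` (total contacts per frame), `label`, and
#'   optionally `contacts`.
#' @export
contact_map <- function(traj, config = analysis_config(),
                        peptide_chain = NULL, domain_chain = NULL,
                        peptide_positions = NULL, domain_residues = NULL,
                        frames = NULL, label = "all", masses = NULL,
                        keep_frames = FALSE) {
  topo <- traj$topology
  ch <- .split_chains(topo, peptide_chain, domain_chain)
  pmap <- .peptide_residue_index(topo, ch$peptide, config$numbering)
  if (is.null(peptide_positions))
    peptide_positions <- config$numbering$positions
  if (!length(peptide_positions)) stop("empty peptide selection")
  pres <- pmap[as.character(peptide_positions)]
  at <- topo$atoms
  if (is.null(domain_residues))
    domain_residues <- sort(unique(at$residue_index[at$chain_id == ch$domain]))
  if (!length(domain_residues)) stop("empty domain selection")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  pcom <- .residue_com(traj, ch$peptide, pres, masses)
  dcom <- .residue_com(traj, ch$domain, domain_residues, masses)
  np <- length(pres); nd <- length(domain_residues); nf <- length(frames)
  contacts <- array(FALSE, c(nf, np, nd))
  for (i in seq_len(np)) for (j in seq_len(nd)) {
    d <- pcom[[i]][frames, , drop = FALSE] - dcom[[j]][frames, , drop = FALSE]
    contacts[, i, j] <- sqrt(rowSums(d * d)) <= config$contact_cutoff
  }
  frac <- apply(contacts, c(2, 3), mean)
  dimnames(frac) <- list(as.character(peptide_positions),
                         as.character(domain_residues))
  out <- list(fraction = frac,
              per_frame_counts = apply(contacts, 1, sum),
              peptide_positions = peptide_positions,
              domain_residues = domain_residues,
              label = label)
  if (keep_frames) {
    dimnames(contacts) <- list(NULL, as.character(peptide_positions),
                               as.character(domain_residues))
    out$contacts <- contacts
  }
  class(out) <- "contact_map"
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map [%s]: %d peptide x %d domain residues, mean %.1f contacts/frame\n",
              x$label, nrow(x$fraction), ncol(x$fraction),
              mean(x$per_frame_counts)))
  invisible(x)
}

#' Long-range electrostatic contacts
#'
#' Detects interactions between the charged-group atoms of peptide
#' lysines (N-zeta) and domain acidic residues (Asp C-gamma, Glu C-delta)
#' at or below the electrostatic cutoff (default 10 A). Reports per-pair
#' occupancies, the mean number of simultaneous interactions per frame,
#' and the pair list surviving the occupancy filter (pairs below the
#' filter are excluded from the report but still enter the counts).
#'
#' @param traj A [trajectory()].
#' @param config An [analysis_config()].
#' @param peptide_chain,domain_chain Chain ids (auto-detected by default).
#' @param frames Optional frame subset defining the ensemble.
#' @return List with `occupancy` (data frame: `peptide_position`,
#'   `domain_residue`, `domain_resname`, `occupancy`, `reported`),
#'   `per_frame_counts` and `mean_count`.
#' @export
electrostatic_contacts <- function(traj, config = analysis_config(),
                                   peptide_chain = NULL, domain_chain = NULL,
                                   frames = NULL) {
  topo <- traj$topology
  at <- topo$atoms
  ch <- .split_chains(topo, peptide_chain, domain_chain)
  pmap <- .peptide_residue_index(topo, ch$peptide, config$numbering)
  lys <- which(at$chain_id == ch$peptide & at$residue_name == "LYS" &
                 at$name == "NZ")
  acid <- which(at$chain_id == ch$domain &
                  ((at$residue_name == "ASP" & at$name == "CG") |
                     (at$residue_name == "GLU" & at$name == "CD")))
  if (!length(lys) || !length(acid))
    stop("no charged atoms found (peptide Lys NZ / domain Asp CG, Glu CD)")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  pairs <- expand.grid(p = lys, a = acid)
  inside <- matrix(FALSE, length(frames), nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    inside[, k] <- .pair_dist(traj$xyz, pairs$p[k], pairs$a[k])[frames] <=
      config$electrostatic_cutoff
  occ <- colMeans(inside)
  posn <- config$numbering$positions[match(at$residue_index[pairs$p], pmap)]
  df <- data.frame(
    peptide_position = posn,
    domain_residue = at$residue_index[pairs$a],
    domain_resname = at$residue_name[pairs$a],
    occupancy = occ,
    reported = occ >= config$electrostatic_occupancy_min
  )
  list(occupancy = df,
       per_frame_counts = rowSums(inside),
       mean_count = mean(rowSums(inside)))
}

# Bond inference by distance (no CONECT records in most inputs): heavy
# atoms within 1.9 A, hydrogens within 1.25 A of a heavy atom.
.bonded <- function(topology, xyz1) {
  crd <- matrix(xyz1, ncol = 3, byrow = TRUE)
  n <- nrow(crd)
  d <- as.matrix(stats::dist(crd))
  ele <- topology$atoms$element
  hmask <- outer(ele == "H", ele == "H", "|")
  lim <- ifelse(hmask, 1.25, 1.9)
  bonded <- d > 0 & d <= lim & !outer(ele == "H", ele == "H", "&")
  bonded
}

#' Hydrocarbon groups of a topology
#'
#' A hydrocarbon group is a carbon atom together with its bonded
#' hydrogens, where the carbon's heavy neighbours are all carbon (bonds
#' inferred from model-1 geometry). These are the groups entering the
#' hydrophobic-contact analysis.
#'
#' @param topology A `topology`.
#' @param chain Optional chain restriction.
#' @return Data frame with `group_id`, `carbon` (atom row index), `chain`,
#'   `residue_index`, `residue_name`, `name` and a list column `atoms`
#'   (carbon + bonded hydrogens).
#' @export
hydrocarbon_groups <- function(topology, chain = NULL) {
  at <- topology$atoms
  bonded <- .bonded(topology, topology$xyz)
  carbons <- which(at$element == "C")
  if (!is.null(chain)) carbons <- carbons[at$chain_id[carbons] %in% chain]
  rows <- list()
  for (ci in carbons) {
    nb <- which(bonded[ci, ])
    heavy <- nb[at$element[nb] != "H"]
    if (length(heavy) && !all(at$element[heavy] == "C")) next
    rows[[length(rows) + 1]] <- data.frame(
      carbon = ci, chain = at$chain_id[ci], residue_index = at$residue_index[ci],
      residue_name = at$residue_name[ci], name = at$name[ci])
  }
  if (!length(rows)) stop("no hydrocarbon groups in selection")
  out <- do.call(rbind, rows)
  out$group_id <- seq_len(nrow(out))
  out$atoms <- lapply(out$carbon, function(ci)
    c(ci, which(bonded[ci, ] & at$element == "H")))
  out[, c("group_id", "carbon", "chain", "residue_index", "residue_name",
          "name", "atoms")]
}

# min distance between two atom groups, per frame
.group_min_dist <- function(xyz, g1, g2) {
  m <- matrix(Inf, nrow(xyz), 1)
  best <- rep(Inf, nrow(xyz))
  for (a in g1) for (b in g2)
    best <- pmin(best, .pair_dist(xyz, a, b))
  best
}

#' Hydrophobic contact occupancies
#'
#' A hydrophobic contact is present in a frame when the minimum
#' atom-to-atom distance between two hydrocarbon groups is at or below
#' the cutoff (default 6 A).
#'
#' @param traj A [trajectory()].
#' @param pairs Data frame of group pairs as returned by
#'   [derive_reference_hydrophobic_pairs()] (columns `peptide_atoms`,
#'   `domain_atoms` list columns, plus identifying columns).
#' @param config An [analysis_config()].
#' @param frames Optional frame subset.
#' @return `pairs` with an added `occupancy` column.
#' @export
hydrophobic_contacts <- function(traj, pairs, config = analysis_config(),
                                 frames = NULL) {
  if (nrow(pairs) < 1) stop("empty hydrophobic pair list")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  occ <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d <- .group_min_dist(traj$xyz, pairs$peptide_atoms[[k]],
                         pairs$domain_atoms[[k]])[frames]
    occ[k] <- mean(d <= config$hydrophobic_cutoff)
  }
  pairs$occupancy <- occ
  pairs
}

#' Derive hydrophobic contact pairs from a reference ensemble
#'
#' For each peptide residue carrying hydrocarbon groups, selects the `k`
#' domain hydrocarbon group(s) with the smallest mean group-group
#' distance across the models of a reference ensemble (conventionally the
#' NMR ensemble of the bound complex).
#'
#' @param ref A [trajectory()] holding the reference ensemble (one frame
#'   per model) with both molecules.
#' @param config An [analysis_config()].
#' @param peptide_chain,domain_chain Chain ids (auto-detected by default).
#' @param peptide_positions Peptide positions to pair (default: all with
#'   hydrocarbon groups).
#' @param k Partners per peptide residue (default 1), sorted by mean
#'   distance.
#' @return Data frame with one row per pair: `peptide_position`,
#'   `peptide_group`, `domain_residue`, `domain_group`, `mean_dist`, and
#'   list columns `peptide_atoms`, `domain_atoms`.
#' @export
derive_reference_hydrophobic_pairs <- function(ref, config = analysis_config(),
                                               peptide_chain = NULL,
                                               domain_chain = NULL,
                                               peptide_positions = NULL,
                                               k = 1) {
  topo <- ref$topology
  ch <- .split_chains(topo, peptide_chain, domain_chain)
  pmap <- .peptide_residue_index(topo, ch$peptide, config$numbering)
  pg <- hydrocarbon_groups(topo, ch$peptide)
  dg <- hydrocarbon_groups(topo, ch$domain)
  if (is.null(peptide_positions))
    peptide_positions <- config$numbering$positions[
      pmap %in% unique(pg$residue_index)]
  rows <- list()
  for (pos in peptide_positions) {
    r <- pmap[[as.character(pos)]]
    pgr <- pg[pg$residue_index == r, ]
    if (!nrow(pgr)) next
    # best peptide-group/domain-group combination per domain group
    md <- matrix(NA_real_, nrow(pgr), nrow(dg))
    for (i in seq_len(nrow(pgr))) for (j in seq_len(nrow(dg)))
      md[i, j] <- mean(.group_min_dist(ref$xyz, pgr$atoms[[i]], dg$atoms[[j]]))
    for (kk in seq_len(min(k, length(md)))) {
      ij <- arrayInd(which.min(md), dim(md))
      rows[[length(rows) + 1]] <- data.frame(
        peptide_position = pos,
        peptide_group = pgr$name[ij[1]],
        domain_residue = dg$residue_index[ij[2]],
        domain_group = dg$name[ij[2]],
        mean_dist = md[ij[1], ij[2]])
      rows[[length(rows)]]$peptide_atoms <- list(pgr$atoms[[ij[1]]])
      rows[[length(rows)]]$domain_atoms <- list(dg$atoms[[ij[2]]])
      md[, ij[2]] <- NA  # next-best partner must be a different domain group
      if (all(is.na(md))) break
    }
  }
  if (!length(rows)) stop("no hydrocarbon groups in peptide selection")
  do.call(rbind, rows)
}

#' Short-range hydrogen bonds and salt bridges
#'
#' Hydrogen bonds: counted in a frame when the acceptor to donor-heavy
#' distance is under 3 A and the acceptor-hydrogen-donor angle exceeds
#' 135 degrees. Salt bridges: same geometry evaluated between the heavy
#' atoms of charged groups (Lys N-zeta against Asp/Glu carboxylate
#' oxygens), counted when any oxygen-hydrogen-nitrogen combination over
#' the N-zeta hydrogens passes. Only intermolecular (peptide-domain)
#' interactions are tallied. Donors without an attached hydrogen are
#' skipped with a warning.
#'
#' @param traj A [trajectory()].
#' @param kind `"hbond"` or `"saltbridge"`.
#' @param config An [analysis_config()].
#' @param peptide_chain,domain_chain Chain ids (auto-detected by default).
#' @param frames Optional frame subset.
#' @return Data frame of donor-acceptor pairs with columns `donor_chain`,
#'   `donor_residue`, `donor_name`, `acceptor_chain`, `acceptor_residue`,
#'   `acceptor_name`, `occupancy`.
#' @export
short_range_interactions <- function(traj, kind = c("hbond", "saltbridge"),
                                     config = analysis_config(),
                                     peptide_chain = NULL,
                                     domain_chain = NULL, frames = NULL) {
  kind <- match.arg(kind)
  topo <- traj$topology
  at <- topo$atoms
  ch <- .split_chains(topo, peptide_chain, domain_chain)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  bonded <- .bonded(topo, topo$xyz)
  if (kind == "hbond") {
    donors <- which(at$element %in% c("N", "O"))
    acceptors <- which(at$element == "O")
  } else {
    donors <- which(at$residue_name == "LYS" & at$name == "NZ")
    acceptors <- which(at$residue_name %in% c("ASP", "GLU") &
                         at$name %in% c("OD1", "OD2", "OE1", "OE2"))
  }
  rows <- list()
  for (d in donors) {
    hs <- which(bonded[d, ] & at$element == "H")
    if (!length(hs)) {
      if (kind == "saltbridge")
        warning("donor ", at$name[d], " of residue ", at$residue_index[d],
                " has no attached hydrogen; skipped")
      next
    }
    for (a in acceptors) {
      if (at$chain_id[a] == at$chain_id[d]) next  # intermolecular only
      ok <- rep(FALSE, length(frames))
      for (h in hs)
        ok <- ok | .hbond_geometry(traj$xyz, a, h, d, config$hbond_dist_max,
                                   config$hbond_angle_min)[frames]
      occ <- mean(ok)
      if (occ > 0)
        rows[[length(rows) + 1]] <- data.frame(
          donor_chain = at$chain_id[d], donor_residue = at$residue_index[d],
          donor_name = at$name[d], acceptor_chain = at$chain_id[a],
          acceptor_residue = at$residue_index[a], acceptor_name = at$name[a],
          occupancy = occ)
    }
  }
  if (!length(rows))
    return(data.frame(donor_chain = character(), donor_residue = integer(),
                      donor_name = character(), acceptor_chain = character(),
                      acceptor_residue = integer(), acceptor_name = character(),
                      occupancy = numeric()))
  do.call(rbind, rows)
}

# Deterministic near-uniform sphere points (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Sphere-sampling (Shrake-Rupley style) SASA: each atom's sphere of
#' radius (vdW + probe) is sampled at `points` near-uniform points; a
#' point is accessible when it lies outside every neighbouring atom's
#' expanded sphere. The atom's contribution is the accessible fraction
#' times its full sphere area.
#'
#' @param traj A [trajectory()] (each frame evaluated) or a single-frame
#'   xyz vector/matrix plus `topology`.
#' @param selection Atom row indices to include (default: all atoms).
#' @param config An [analysis_config()] supplying probe radius, point
#'   count and the vdW radius table.
#' @param topology Needed when `traj` is a bare coordinate vector.
#' @return Numeric vector, one area per frame, in nm^2.
#' @export
sasa <- function(traj, selection = NULL, config = analysis_config(),
                 topology = NULL) {
  if (inherits(traj, "trajectory")) {
    topology <- traj$topology
    xyz <- traj$xyz
  } else {
    if (is.null(topology)) stop("topology required for bare coordinates")
    xyz <- if (is.matrix(traj)) traj else matrix(traj, nrow = 1)
  }
  at <- topology$atoms
  if (is.null(selection)) selection <- seq_len(nrow(at))
  ele <- at$element[selection]
  rad <- config$vdw_radii[ele]
  if (anyNA(rad))
    stop("no vdW radius for element(s): ",
         paste(unique(ele[is.na(rad)]), collapse = ", "))
  rad <- unname(rad) + config$sasa_probe
  pts <- .sphere_points(config$sasa_points)
  vapply(seq_len(nrow(xyz)), function(f) {
    crd <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)[selection, , drop = FALSE]
    n <- nrow(crd)
    dmat <- as.matrix(stats::dist(crd))
    total <- 0
    for (i in seq_len(n)) {
      nb <- which(dmat[i, ] < rad[i] + rad & seq_len(n) != i)
      p <- sweep(pts * rad[i], 2, crd[i, ], "+")
      acc <- rep(TRUE, nrow(p))
      for (j in nb) {
        d2 <- (p[, 1] - crd[j, 1])^2 + (p[, 2] - crd[j, 2])^2 +
          (p[, 3] - crd[j, 3])^2
        acc <- acc & d2 >= rad[j]^2
        if (!any(acc)) break
      }
      total <- total + mean(acc) * 4 * pi * rad[i]^2
    }
    total / 100  # A^2 -> nm^2
  }, numeric(1))
}
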