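# Per-frame geometric observables.

#' Metric series container
#'
#' @param values Numeric vector, one value per frame.
#' @param time_ns Numeric vector of frame times in ns (strictly increasing).
#' @param label Metric name.
#' @return Object of class `metric_series`.
#' @export
metric_series <- function(values, time_ns, label = "metric") {
  if (length(values) != length(time_ns))
    stop("values and time_ns differ in length")
  if (length(time_ns) > 1 && any(diff(time_ns) <= 0))
    stop("time_ns must be strictly increasing")
  structure(list(values = as.numeric(values), time_ns = as.numeric(time_ns),
                 label = label), class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("Metric series '%s': %d frames, %.4g-%.4g ns, mean %.4g\n",
              x$label, length(x$values), min(x$time_ns), max(x$time_ns),
              mean(x$values)))
  invisible(x)
}

# column indices of atom a in an interleaved xyz matrix
.xyz_cols <- function(a) c(3 * (a - 1) + 1, 3 * (a - 1) + 2, 3 * (a - 1) + 3)

# per-frame Euclidean distance between atoms a and b (xyz: frames x 3N)
.pair_dist <- function(xyz, a, b) {
  d <- xyz[, .xyz_cols(a), drop = FALSE] - xyz[, .xyz_cols(b), drop = FALSE]
  sqrt(rowSums(d * d))
}

# Guess which chain is the peptide: the one with fewer residues.
.split_chains <- function(topology, peptide_chain = NULL, domain_chain = NULL) {
  at <- topology$atoms
  nres <- vapply(split(at$residue_index, at$chain_id),
                 function(r) length(unique(r)), integer(1))
  if (is.null(peptide_chain)) peptide_chain <- names(which.min(nres))
  if (is.null(domain_chain)) {
    rest <- setdiff(names(nres), peptide_chain)
    if (length(rest) < 1) stop("topology has no second chain for the domain")
    domain_chain <- rest[which.max(nres[rest])]
  }
  list(peptide = peptide_chain, domain = domain_chain)
}

# Map peptide positions to within-chain residue indices. Peptide chains may
# carry capping groups (ACE/NHE/NME) that are not numbered positions; the
# amino-acid residues in chain order correspond to positions N-to-C.
.peptide_residue_index <- function(topology, chain, numbering) {
  at <- topology$atoms[topology$atoms$chain_id == chain, ]
  res <- unique(at$residue_index)
  caps <- unique(at$residue_index[at$residue_name %in% c("ACE", "NHE", "NME",
                                                         "NH2")])
  res <- setdiff(res, caps)
  if (length(res) != length(numbering$positions))
    stop("peptide chain ", chain, " has ", length(res),
         " non-cap residues; numbering expects ", length(numbering$positions))
  stats::setNames(res, as.character(numbering$positions))
}

#' Binding surface distance
#'
#' The pipeline's principal reaction coordinate: the arithmetic mean of
#' the configured pairwise peptide-domain Calpha distances, per frame.
#'
#' @param traj A [trajectory()] object containing peptide and domain.
#' @param config An [analysis_config()]; `config$binding_surface_pairs`
#'   names the Calpha pairs (peptide position, domain residue index).
#' @param pairs Optional data frame overriding the configured pairs.
#' @param peptide_chain,domain_chain Chain ids; by default the chain with
#'   fewer residues is taken as the peptide.
#' @return A [metric_series()] in Angstrom.
#' @export
binding_surface_distance <- function(traj, config = analysis_config(),
                                     pairs = NULL,
                                     peptide_chain = NULL,
                                     domain_chain = NULL) {
  topo <- traj$topology
  ch <- .split_chains(topo, peptide_chain, domain_chain)
  if (is.null(pairs)) pairs <- config$binding_surface_pairs
  if (nrow(pairs) < 1) stop("need at least one Calpha pair")
  pmap <- .peptide_residue_index(topo, ch$peptide, config$numbering)
  d <- matrix(0, n_frames(traj), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ai <- .ca_index(topo, ch$peptide, pmap[[as.character(pairs$position[k])]])
    bi <- .ca_index(topo, ch$domain, pairs$domain_residue[k])
    d[, k] <- .pair_dist(traj$xyz, ai, bi)
  }
  metric_series(rowMeans(d), frame_times_ns(traj), "binding_surface_distance")
}

# Torsion angle (degrees, IUPAC sign) for atom quadruples, vectorized over
# frames. xyz: frames x 3N; quad: integer length-4 atom indices.
.dihedral <- function(xyz, quad) {
  p1 <- xyz[, .xyz_cols(quad[1]), drop = FALSE]
  p2 <- xyz[, .xyz_cols(quad[2]), drop = FALSE]
  p3 <- xyz[, .xyz_cols(quad[3]), drop = FALSE]
  p4 <- xyz[, .xyz_cols(quad[4]), drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  -atan2(y, x) * 180 / pi  # IUPAC sign (clockwise positive viewed B->C)
}

# wrap angular differences into [-180, 180]
.wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Backbone dihedral set
#'
#' Defines which phi/psi dihedrals enter the dihedral-angle RMSD and
#' records their reference values (in degrees) from a reference
#' conformation, conventionally the lowest-energy NMR model.
#'
#' @param topology A `topology`.
#' @param chain Peptide chain id.
#' @param residues Residue indices (within the chain) to include; default
#'   all amino-acid residues. Phi needs the preceding residue's C (an ACE
#'   cap counts), psi the following residue's N; dihedrals whose atoms are
#'   missing are dropped at the termini but raise an error mid-chain.
#' @param reference_xyz Interleaved coordinates of the reference
#'   conformation (default: the topology's model-1 coordinates).
#' @return Object of class `dihedral_set`: data frame with columns
#'   `residue_index`, `angle` ("phi"/"psi"), atom-index columns `a1..a4`
#'   and `reference_deg`.
#' @export
dihedral_set <- function(topology, chain, residues = NULL,
                         reference_xyz = NULL) {
  at <- topology$atoms
  catoms <- at[at$chain_id == chain, ]
  res <- sort(unique(catoms$residue_index))
  aa <- setdiff(res, unique(catoms$residue_index[
    catoms$residue_name %in% c("ACE", "NHE", "NME", "NH2")]))
  if (is.null(residues)) residues <- aa
  idx <- function(r, nm) {
    i <- atom_select(topology, chain = chain, residue = r, name = nm)
    if (length(i) == 1) i else NA_integer_
  }
  rows <- list()
  for (r in residues) {
    n <- idx(r, "N"); ca <- idx(r, "CA"); c <- idx(r, "C")
    if (anyNA(c(n, ca, c)))
      stop("residue ", r, " lacks backbone N/CA/C atoms")
    cprev <- idx(r - 1, "C"); nnext <- idx(r + 1, "N")
    if (!is.na(cprev))
      rows[[length(rows) + 1]] <- data.frame(residue_index = r, angle = "phi",
                                             a1 = cprev, a2 = n, a3 = ca, a4 = c)
    if (!is.na(nnext))
      rows[[length(rows) + 1]] <- data.frame(residue_index = r, angle = "psi",
                                             a1 = n, a2 = ca, a3 = c, a4 = nnext)
  }
  if (!length(rows)) stop("no computable dihedrals for chain ", chain)
  ds <- do.call(rbind, rows)
  if (is.null(reference_xyz)) reference_xyz <- topology$xyz
  refm <- matrix(reference_xyz, nrow = 1)
  ds$reference_deg <- vapply(seq_len(nrow(ds)), function(k)
    .dihedral(refm, unlist(ds[k, c("a1", "a2", "a3", "a4")])), numeric(1))
  class(ds) <- c("dihedral_set", "data.frame")
  ds
}

#' Compute phi/psi angles for a dihedral set
#'
#' @param traj A `trajectory` (or plain xyz matrix).
#' @param dset A [dihedral_set()].
#' @return Frames x dihedrals matrix of angles in degrees.
#' @export
dihedral_angles <- function(traj, dset) {
  xyz <- if (inherits(traj, "trajectory")) traj$xyz else as.matrix(traj)
  out <- matrix(NA_real_, nrow(xyz), nrow(dset))
  for (k in seq_len(nrow(dset)))
    out[, k] <- .dihedral(xyz, unlist(dset[k, c("a1", "a2", "a3", "a4")]))
  colnames(out) <- paste0(dset$angle, dset$residue_index)
  out
}

#' Dihedral-angle RMSD from a reference conformation
#'
#' Root-mean-square deviation over the backbone phi/psi angles of a
#' [dihedral_set()], each angular difference wrapped into [-180, 180]
#' degrees, so the result lies in [0, 180].
#'
#' @param traj A `trajectory` (or plain xyz matrix).
#' @param dset A [dihedral_set()] carrying the reference angles.
#' @return A [metric_series()] in degrees (plain numeric vector when
#'   `traj` is a bare matrix).
#' @export
dihedral_rmsd <- function(traj, dset) {
  ang <- dihedral_angles(traj, dset)
  dev <- .wrap180(sweep(ang, 2, dset$reference_deg))
  v <- sqrt(rowMeans(dev * dev))
  if (inherits(traj, "trajectory"))
    metric_series(v, frame_times_ns(traj), "dihedral_rmsd")
  else v
}

#' End-to-end distance of a peptide
#'
#' @param traj A `trajectory`.
#' @param chain Peptide chain id (default: auto-detected peptide chain).
#' @param atom_name Terminal atom name (default "CA": first and last
#'   amino-acid Calpha).
#' @return A [metric_series()] in Angstrom.
#' @export
end_to_end_distance <- function(traj, chain = NULL, atom_name = "CA") {
  topo <- traj$topology
  if (is.null(chain)) chain <- .split_chains(topo)$peptide
  at <- topo$atoms
  res <- sort(unique(at$residue_index[at$chain_id == chain &
    !at$residue_name %in% c("ACE", "NHE", "NME", "NH2")]))
  a <- atom_select(topo, chain = chain, residue = res[1], name = atom_name)
  b <- atom_select(topo, chain = chain, residue = res[length(res)],
                   name = atom_name)
  if (length(a) != 1 || length(b) != 1)
    stop("terminal atom '", atom_name, "' missing in chain ", chain)
  metric_series(.pair_dist(traj$xyz, a, b), frame_times_ns(traj),
                "end_to_end_distance")
}

#' Per-residue secondary-structure fractions
#'
#' Fraction of frames each peptide residue spends in a polyproline-II
#' conformation and in a 3-10 helix. PPII is assigned when the residue's
#' (phi, psi) falls inside the configured rectangular window (default
#' phi in [-110, -40], psi in [110, 180] degrees, around the canonical
#' (-75, 145)). The 3-10 assignment uses the defining i -> i+3 backbone
#' hydrogen bond, evaluated with the same geometric criterion as
#' [short_range_interactions()] (acceptor O(i) to donor N(i+3) under 3 A
#' and acceptor-hydrogen-donor angle over 135 degrees); the four residues
#' i..i+3 spanned by a bond are counted as helical in that frame.
#'
#' @param traj A `trajectory`.
#' @param config An [analysis_config()].
#' @param chain Peptide chain id (default auto-detected).
#' @return Data frame with one row per peptide residue: `position`,
#'   `residue_index`, `ppii`, `helix310` (fractions in [0, 1]).
#' @export
secondary_structure_fractions <- function(traj, config = analysis_config(),
                                          chain = NULL) {
  if (n_frames(traj) < 1) stop("trajectory has no frames")
  topo <- traj$topology
  if (is.null(chain)) chain <- .split_chains(topo)$peptide
  pmap <- .peptide_residue_index(topo, chain, config$numbering)
  res <- unname(pmap)
  ds <- dihedral_set(topo, chain)
  ang <- dihedral_angles(traj, ds)
  nf <- n_frames(traj)
  ppii <- helix <- stats::setNames(numeric(length(res)), res)
  for (r in res) {
    iphi <- which(ds$residue_index == r & ds$angle == "phi")
    ipsi <- which(ds$residue_index == r & ds$angle == "psi")
    if (length(iphi) && length(ipsi)) {
      inwin <- ang[, iphi] >= config$ppii_phi[1] &
        ang[, iphi] <= config$ppii_phi[2] &
        ang[, ipsi] >= config$ppii_psi[1] &
        ang[, ipsi] <= config$ppii_psi[2]
      ppii[as.character(r)] <- mean(inwin)
    } else {
      ppii[as.character(r)] <- NA_real_  # terminal residue: phi or psi missing
    }
  }
  # i -> i+3 backbone H-bonds
  helical <- matrix(FALSE, nf, length(res),
                    dimnames = list(NULL, as.character(res)))
  for (r in res) {
    if (!(r + 3) %in% res) next
    accO <- atom_select(topo, chain = chain, residue = r, name = "O")
    donN <- atom_select(topo, chain = chain, residue = r + 3, name = "N")
    donH <- atom_select(topo, chain = chain, residue = r + 3,
                        name = c("H", "HN", "H1"))
    if (length(accO) != 1 || length(donN) != 1 || length(donH) < 1) next
    bond <- rep(FALSE, nf)
    for (h in donH)
      bond <- bond | .hbond_geometry(traj$xyz, accO, h, donN,
                                     config$hbond_dist_max,
                                     config$hbond_angle_min)
    span <- as.character(r:(r + 3))
    helical[, span] <- helical[, span] | bond
  }
  helix[] <- colMeans(helical)
  data.frame(position = config$numbering$positions[match(res, pmap)],
             residue_index = res, ppii = unname(ppii),
             helix310 = unname(helix))
}

#' Running average of a series
#'
#' @param x Numeric vector or [metric_series()].
#' @return Numeric vector of cumulative means, same length as the input.
#' @export
running_average <- function(x) {
  v <- if (inherits(x, "metric_series")) x$values else as.numeric(x)
  cumsum(v) / seq_along(v)
}

#' Autocorrelation time of a series
#'
#' Estimates the relaxation time of a (replica-index or observable) series
#' from a least-squares exponential fit to the normalized autocorrelation
#' function over lags up to its first zero crossing.
#'
#' @param x Numeric vector or [metric_series()] (at least 10 samples).
#' @param dt_ns Time per sample in ns (taken from a metric series when
#'   available).
#' @return Autocorrelation time in ns; `NA` with a warning for a constant
#'   series (autocorrelation undefined).
#' @export
autocorrelation_time <- function(x, dt_ns = NULL) {
  if (inherits(x, "metric_series")) {
    if (is.null(dt_ns)) dt_ns <- diff(x$time_ns[1:2])
    x <- x$values
  }
  if (is.null(dt_ns)) dt_ns <- 1
  if (length(x) < 10) stop("need at least 10 samples")
  if (stats::sd(x) == 0) {
    warning("constant series: autocorrelation time undefined")
    return(NA_real_)
  }
  ac <- stats::acf(x, lag.max = min(length(x) - 1, 10000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  zero <- which(ac <= 0)[1]
  upto <- if (is.na(zero)) length(ac) else max(zero - 1, 2)
  lag <- (seq_len(upto) - 1) * dt_ns
  rho <- ac[seq_len(upto)]
  # log-linear start, refined by nonlinear least squares
  pos <- rho > 0
  tc0 <- -1 / stats::coef(stats::lm(log(rho[pos]) ~ 0 + lag[pos]))[[1]]
  if (!is.finite(tc0) || tc0 <= 0) tc0 <- dt_ns
  fit <- tryCatch(
    minpack.lm::nlsLM(rho ~ exp(-lag / tc), start = list(tc = tc0),
                      lower = 1e-12),
    error = function(e) NULL)
  if (is.null(fit)) tc0 else stats::coef(fit)[["tc"]]
}

#' Geometric replica-exchange temperature ladder
#'
#' @param t_min,t_max Lowest and highest temperature (K), `0 < t_min < t_max`.
#' @param n Number of replicas (>= 2).
#' @return Numeric vector `t_min * (t_max / t_min)^((0:(n-1)) / (n-1))`:
#'   exact endpoints, constant ratio between consecutive temperatures.
#' @export
temperature_ladder <- function(t_min, t_max, n) {
  if (!(t_min > 0 && t_max > t_min)) stop("need 0 < t_min < t_max")
  if (n < 2) stop("need n >= 2 replicas")
  t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
}
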