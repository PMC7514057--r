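#' Default van der Waals radius table
#'
#' Element radii (in Angstrom) used by [sasa()]. Values follow the Bondi
#' compilation commonly used for accessible-surface calculations.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
    MG = 1.73, ZN = 1.39, FE = 1.40, CA. = 2.31)
}

#' Peptide position numbering map
#'
#' Class II proline-rich peptides are conventionally numbered by position
#' relative to the PxxP motif, descending from the N- to the C-terminus.
#' For the 12-residue peptide studied here the positions run
#' +3, +2, ..., 0, -1, ..., -8 while sequential residue indices ascend
#' 1..12. The lysine at position -3 divides segment 1 (positions +3..-2,
#' the PxxP half) from segment 2 (positions -4..-8, the specificity half).
#'
#' @param positions Integer vector of peptide positions in N-to-C order.
#'   Default `3:-8` (12 positions).
#' @param pivot Position of the dividing residue between the two segments
#'   (default -3).
#' @return Object of class `peptide_numbering`: a list with `positions`,
#'   `indices`, `pivot`, `seg1` and `seg2` (position vectors).
#' @export
peptide_numbering <- function(positions = 3:-8, pivot = -3) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions))
    stop("peptide positions must be unique")
  if (any(diff(positions) != -1L))
    stop("peptide positions must descend by 1 from N- to C-terminus")
  if (!pivot %in% positions)
    stop("pivot position ", pivot, " not among peptide positions")
  out <- list(
    positions = positions,
    indices   = seq_along(positions),
    pivot     = as.integer(pivot),
    seg1      = positions[positions > pivot],
    seg2      = positions[positions < pivot]
  )
  class(out) <- "peptide_numbering"
  out
}

#' Map a peptide position to its sequential residue index
#'
#' @param numbering A [peptide_numbering()] object.
#' @param position Integer peptide position(s) (e.g. 3, 0, -8).
#' @return Integer sequential index(es), 1-based from the N-terminus.
#' @examples
#' nb <- peptide_numbering()
#' map_position(nb, 3)   # 1
#' map_position(nb, -3)  # 7
#' map_position(nb, -8)  # 12
#' @export
map_position <- function(numbering, position) {
  stopifnot(inherits(numbering, "peptide_numbering"))
  idx <- match(as.integer(position), numbering$positions)
  if (anyNA(idx))
    stop("position(s) ", paste(position[is.na(idx)], collapse = ", "),
         " outside the peptide numbering range")
  numbering$indices[idx]
}

#' @export
print.peptide_numbering <- function(x, ...) {
  cat("Peptide numbering:", length(x$positions), "positions",
      sprintf("(%+d ... %+d), pivot %+d\n",
              x$positions[1], x$positions[length(x$positions)], x$pivot))
  invisible(x)
}

# Default Calpha binding-surface pairs (peptide position, domain residue).
# The pair set is user-configurable; these defaults pair segment-1 and pivot
# positions with surface-I / specificity-pocket residues and segment-2
# positions with surface-II residues. Seg1-only constructs retain the first
# four pairs.
.default_surface_pairs <- function() {
  data.frame(
    position       = c(3L, 1L, -1L, -3L, -5L, -7L, -8L),
    domain_residue = c(9L, 10L, 32L, 33L, 15L, 17L, 49L)
  )
}

#' Analysis configuration
#'
#' Single source of truth for every residue selection, distance cutoff and
#' threshold used by the pipeline. Distances are in Angstrom, dwell times
#' in ns, angles in degrees.
#'
#' State definitions (on the binding surface distance d): fully engaged
#' iff d < `fully_engaged_max`; unbound iff d > `encounter_max`; encounter
#' otherwise (boundary values fall in the encounter class). Transition
#' detection uses the stricter hysteresis thresholds `engage_max`,
#' `encounter_entry_max` and `unbind_min` together with the minimum dwell
#' `dwell_ns`.
#'
#' @param binding_surface_pairs Data frame with columns `position`
#'   (peptide position) and `domain_residue` (domain residue index) naming
#'   the Calpha pairs averaged into the binding surface distance.
#' @param fully_engaged_max,encounter_max State thresholds (11.5, 23 A).
#' @param engage_max,encounter_entry_max,unbind_min Hysteresis transition
#'   thresholds (10.5, 21, 25 A).
#' @param dwell_ns Minimum dwell below/above a transition threshold for an
#'   event to count (1 ns).
#' @param contact_cutoff Residue center-of-mass contact cutoff (8 A).
#' @param electrostatic_cutoff Long-range electrostatic cutoff between
#'   charged-group carbons/nitrogens (10 A).
#' @param electrostatic_occupancy_min Occupancy below which an
#'   electrostatic pair is dropped from reports (0.10).
#' @param hydrophobic_cutoff Hydrocarbon-group contact cutoff (6 A).
#' @param hbond_dist_max,hbond_angle_min Hydrogen-bond / salt-bridge
#'   heavy-atom distance (3 A) and acceptor-hydrogen-donor angle (135 deg).
#' @param native_cutoff_deg Dihedral-RMSD cutoff separating native from
#'   nonnative conformations of the full peptide (33.7 deg).
#' @param native_cutoff_seg1_deg Same for the segment-1 dihedrals (38.1 deg).
#' @param ppii_phi,ppii_psi Length-2 numeric ranges of the polyproline-II
#'   (phi, psi) window in degrees.
#' @param sasa_probe Solvent probe radius (1.4 A).
#' @param sasa_points Sphere sample points per atom (960).
#' @param vdw_radii Named element radius table, see [default_vdw_radii()].
#' @param si_residues,pocket_residues,sii_k8_residues,sii_l7_residues
#'   Domain residue groups entering the encounter subcategory rules:
#'   peptide K(+3)/K(-3) against `si_residues` (8, 9, 10) and
#'   `pocket_residues` (33, 35, 36); K(-8) against `sii_k8_residues`
#'   (14, 15, 16, 17, 49); L(-7) against `sii_l7_residues` (32, 33, 36, 49).
#' @param numbering A [peptide_numbering()] object.
#' @return Object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(binding_surface_pairs = .default_surface_pairs(),
                            fully_engaged_max = 11.5,
                            encounter_max = 23,
                            engage_max = 10.5,
                            encounter_entry_max = 21,
                            unbind_min = 25,
                            dwell_ns = 1,
                            contact_cutoff = 8,
                            electrostatic_cutoff = 10,
                            electrostatic_occupancy_min = 0.10,
                            hydrophobic_cutoff = 6,
                            hbond_dist_max = 3,
                            hbond_angle_min = 135,
                            native_cutoff_deg = 33.7,
                            native_cutoff_seg1_deg = 38.1,
                            ppii_phi = c(-110, -40),
                            ppii_psi = c(110, 180),
                            sasa_probe = 1.4,
                            sasa_points = 960,
                            vdw_radii = default_vdw_radii(),
                            si_residues = c(8L, 9L, 10L),
                            pocket_residues = c(33L, 35L, 36L),
                            sii_k8_residues = c(14L, 15L, 16L, 17L, 49L),
                            sii_l7_residues = c(32L, 33L, 36L, 49L),
                            numbering = peptide_numbering()) {
  cfg <- list(
    binding_surface_pairs = as.data.frame(binding_surface_pairs),
    fully_engaged_max = fully_engaged_max,
    encounter_max = encounter_max,
    engage_max = engage_max,
    encounter_entry_max = encounter_entry_max,
    unbind_min = unbind_min,
    dwell_ns = dwell_ns,
    contact_cutoff = contact_cutoff,
    electrostatic_cutoff = electrostatic_cutoff,
    electrostatic_occupancy_min = electrostatic_occupancy_min,
    hydrophobic_cutoff = hydrophobic_cutoff,
    hbond_dist_max = hbond_dist_max,
    hbond_angle_min = hbond_angle_min,
    native_cutoff_deg = native_cutoff_deg,
    native_cutoff_seg1_deg = native_cutoff_seg1_deg,
    ppii_phi = ppii_phi,
    ppii_psi = ppii_psi,
    sasa_probe = sasa_probe,
    sasa_points = sasa_points,
    vdw_radii = vdw_radii,
    si_residues = as.integer(si_residues),
    pocket_residues = as.integer(pocket_residues),
    sii_k8_residues = as.integer(sii_k8_residues),
    sii_l7_residues = as.integer(sii_l7_residues),
    numbering = numbering
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' Enforces the threshold ordering
#' `0 < engage_max < fully_engaged_max < encounter_entry_max <
#' encounter_max < unbind_min`, positivity of every cutoff and dwell, and
#' structural requirements on the pair table.
#'
#' @param cfg An `analysis_config` object.
#' @return `cfg`, invisibly; stops with the offending key(s) on failure.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  ord <- c(engage_max = cfg$engage_max,
           fully_engaged_max = cfg$fully_engaged_max,
           encounter_entry_max = cfg$encounter_entry_max,
           encounter_max = cfg$encounter_max,
           unbind_min = cfg$unbind_min)
  if (any(ord <= 0) || any(diff(ord) <= 0))
    stop("config error: thresholds must satisfy 0 < engage_max < ",
         "fully_engaged_max < encounter_entry_max < encounter_max < ",
         "unbind_min; got ", paste(names(ord), ord, sep = "=", collapse = ", "))
  pos_keys <- c("dwell_ns", "contact_cutoff", "electrostatic_cutoff",
                "hydrophobic_cutoff", "hbond_dist_max", "sasa_probe",
                "sasa_points", "native_cutoff_deg", "native_cutoff_seg1_deg")
  for (k in pos_keys)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config error: key '", k, "' must be a positive number")
  if (cfg$electrostatic_occupancy_min < 0 || cfg$electrostatic_occupancy_min > 1)
    stop("config error: key 'electrostatic_occupancy_min' must lie in [0,1]")
  bp <- cfg$binding_surface_pairs
  if (!all(c("position", "domain_residue") %in% names(bp)) || nrow(bp) < 1)
    stop("config error: key 'binding_surface_pairs' needs columns ",
         "'position' and 'domain_residue' and at least one row")
  map_position(cfg$numbering, bp$position)  # every position must exist
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  states: engaged < %.1f A, encounter < %.1f A, unbound > %.1f A\n",
              x$fully_engaged_max, x$encounter_max, x$encounter_max))
  cat(sprintf("  transitions: engage < %.1f, enter < %.1f, unbind > %.1f A (dwell %.2g ns)\n",
              x$engage_max, x$encounter_entry_max, x$unbind_min, x$dwell_ns))
  cat(sprintf("  cutoffs: contact %.1f, electrostatic %.1f, hydrophobic %.1f, hbond %.1f A / %.0f deg\n",
              x$contact_cutoff, x$electrostatic_cutoff, x$hydrophobic_cutoff,
              x$hbond_dist_max, x$hbond_angle_min))
  cat(sprintf("  native dihedral-RMSD cutoffs: %.1f deg (full), %.1f deg (seg1)\n",
              x$native_cutoff_deg, x$native_cutoff_seg1_deg))
  cat(sprintf("  binding-surface pairs: %d\n", nrow(x$binding_surface_pairs)))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML schema mirrors the fields of [analysis_config()]; unknown keys
#' raise an error naming the key, and the resulting configuration is
#' validated (threshold-ordering violations name the offending keys).
#'
#' @param path File path.
#' @return `read_config()` returns an `analysis_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$binding_surface_pairs))
    raw$binding_surface_pairs <- as.data.frame(raw$binding_surface_pairs)
  if (!is.null(raw$vdw_radii)) raw$vdw_radii <- unlist(raw$vdw_radii)
  if (!is.null(raw$numbering))
    raw$numbering <- peptide_numbering(raw$numbering$positions,
                                       raw$numbering$pivot)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg An `analysis_config` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  out <- unclass(cfg)
  out$binding_surface_pairs <- as.list(out$binding_surface_pairs)
  out$vdw_radii <- as.list(out$vdw_radii)
  out$numbering <- list(positions = out$numbering$positions,
                        pivot = out$numbering$pivot)
  yaml::write_yaml(out, path)
  invisible(path)
}
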