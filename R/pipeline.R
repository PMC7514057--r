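# End-to-end orchestration and report writers.

.pkg_version <- function() {
  as.character(tryCatch(utils::packageVersion("idpbind"),
                        error = function(e) "0.0.0"))
}

#' Run the full binding-pathway analysis pipeline
#'
#' Orchestrates, for one or more trajectories sharing a topology: binding
#' surface distance (and dihedral RMSD when a reference is available),
#' state classification with encounter subcategories, residue contact
#' maps per ensemble, long-range electrostatic contacts per state,
#' first-passage kinetics with exponential fits and a bootstrap error on
#' the encounter-formation rate, and an ensemble summary. Results are
#' written as CSV/TSV/JSON plus a run manifest.
#'
#' @param topology A `topology` object or PDB path.
#' @param trajectories A [trajectory()], a list of them, or file paths
#'   (DCD / multi-model PDB).
#' @param config An [analysis_config()] or YAML config path.
#' @param output_dir Directory for the report bundle (created).
#' @param concentration Domain concentration in M for rate constants
#'   (default 4 mM, the effective single-pair box concentration).
#' @param frame_interval_ps Frame spacing used when trajectories are read
#'   from files.
#' @param dihedral_reference Optional [dihedral_set()] for the
#'   native-fold flag; when `NULL` and the topology lacks backbone
#'   atoms, fold flags are left undefined.
#' @param seed Seed for the bootstrap.
#' @param bootstrap_B Bootstrap resamples (default 200).
#' @return Invisibly, a list with `summary` (an [ensemble_summary()]),
#'   `rates` (a [two_step_rates()]), `labels`, `files`.
#' @export
run_pipeline <- function(topology, trajectories, config = analysis_config(),
                         output_dir, concentration = 0.004,
                         frame_interval_ps = 10, dihedral_reference = NULL,
                         seed = 1, bootstrap_B = 200) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (is.character(topology)) topology <- read_topology(topology)
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  input_files <- character()
  if (is.character(trajectories)) {
    input_files <- trajectories
    trajectories <- lapply(trajectories, function(p)
      read_trajectory(p, topology, frame_interval_ps))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(output_dir, x)

  series <- lapply(trajectories, binding_surface_distance, config = config)
  all_d <- unlist(lapply(series, `[[`, "values"))
  traj_id <- rep(seq_along(series), vapply(series, function(s)
    length(s$values), integer(1)))
  frame_t <- unlist(lapply(series, `[[`, "time_ns"))
  primary <- classify_frames(all_d, config)

  drmsd <- rep(NA_real_, length(all_d))
  native <- rep(NA, length(all_d))
  if (!is.null(dihedral_reference)) {
    drmsd <- unlist(lapply(trajectories, function(tr)
      dihedral_rmsd(tr, dihedral_reference)$values))
    native <- drmsd < config$native_cutoff_deg
  }

  cms <- lapply(trajectories, contact_map, config = config,
                keep_frames = TRUE)
  contacts <- do.call(abind_frames, cms)
  subcat <- categorize_encounter(contacts, primary, config)
  labels <- state_labels(primary, subcat, native)

  elec <- tryCatch(
    lapply(trajectories, electrostatic_contacts, config = config),
    error = function(e) NULL)
  elec_counts <- if (is.null(elec)) NULL else
    unlist(lapply(elec, `[[`, "per_frame_counts"))

  extra <- list()
  if (!is.null(elec_counts)) extra$electrostatic_contacts <- elec_counts
  summ <- ensemble_summary(labels, extra)

  fpt_enc <- first_passage_times(series, "encounter", config)
  tau_enc <- tryCatch(fit_tau(fpt_enc, "ecdf_fit"), error = function(e) NA)
  k1 <- if (is.finite(tau_enc)) rate_from_tau(tau_enc, concentration) else NA
  k1_sd <- if (is.finite(tau_enc) && nrow(fpt_enc) >= 2)
    bootstrap_rate_sd(fpt_enc, concentration, B = bootstrap_B,
                      seed = seed)$sd else NA
  fpt_eng <- first_passage_times(series, "fully_engaged", config)
  tau_on <- tryCatch(fit_tau(fpt_eng, "ecdf_fit"), error = function(e) NA)
  k_on <- if (is.finite(tau_on)) rate_from_tau(tau_on, concentration) else NA
  rates <- two_step_rates(k1 = if (is.finite(k1)) k1 else NA,
                          k_on = if (is.finite(k_on)) k_on else NA,
                          tau_ns = if (is.finite(tau_enc)) tau_enc else NA,
                          concentration = concentration,
                          sd = c(k1 = k1_sd))

  # ---- outputs ----
  utils::write.csv(data.frame(trajectory = traj_id, time_ns = frame_t,
                              binding_surface_distance = all_d,
                              dihedral_rmsd = drmsd),
                   fp("metrics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(trajectory = traj_id, time_ns = frame_t,
                              state = primary, subcategory = subcat,
                              native = native),
                   fp("state_labels.csv"), row.names = FALSE)
  pooled_cm <- contact_fraction_from_array(contacts)
  utils::write.table(pooled_cm, fp("contact_map.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(elec)) {
    occ <- elec[[1]]$occupancy
    if (length(elec) > 1) {
      om <- sapply(elec, function(e) e$occupancy$occupancy)
      occ$occupancy <- rowMeans(om)
      occ$reported <- occ$occupancy >= config$electrostatic_occupancy_min
    }
    utils::write.csv(occ, fp("electrostatic_contacts.csv"),
                     row.names = FALSE)
  }
  events <- do.call(rbind, lapply(seq_along(series), function(i)
    detect_transitions(series[[i]], config, trajectory_id = i)))
  utils::write.csv(events, fp("transition_events.csv"), row.names = FALSE)
  jsonlite::write_json(summary_as_list(summ), fp("ensemble_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(rates_as_list(rates), fp("kinetics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  manifest <- list(
    package_version = .pkg_version(),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    concentration_M = concentration,
    n_trajectories = length(trajectories),
    n_frames = length(all_d),
    inputs = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    config = rapply(unclass(config)[!vapply(config, is.object, TRUE)],
                    unclass, how = "replace"))
  manifest$config$numbering <- list(positions = config$numbering$positions,
                                    pivot = config$numbering$pivot)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  write_report(summ, rates, output_dir)

  invisible(list(summary = summ, rates = rates, labels = labels,
                 files = list.files(output_dir, full.names = TRUE)))
}

# concatenate the per-frame contact arrays of several contact maps
#' @keywords internal
abind_frames <- function(...) {
  maps <- list(...)
  arrs <- lapply(maps, `[[`, "contacts")
  d <- dim(arrs[[1]])
  out <- array(FALSE, c(sum(vapply(arrs, function(a) dim(a)[1], integer(1))),
                        d[2], d[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[2:3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @keywords internal
contact_fraction_from_array <- function(contacts) {
  m <- apply(contacts, c(2, 3), mean)
  dimnames(m) <- dimnames(contacts)[2:3]
  m
}

#' @keywords internal
summary_as_list <- function(s) {
  list(state_fractions = as.list(s$state_fractions),
       unbound_fraction = s$unbound_fraction,
       quadrants = as.list(s$quadrants),
       subcategory_percent = as.list(s$subcategory_percent),
       state_means = if (is.null(s$state_means)) NULL else
         lapply(split(s$state_means, s$state_means$series), function(r)
           as.list(r[1, c("unbound", "encounter", "fully_engaged")])))
}

#' @keywords internal
rates_as_list <- function(r) {
  out <- unclass(r)
  out$sd <- as.list(out$sd)
  out
}

#' Write summary tables mirroring the standard report layout
#'
#' Produces `encounter_categories.csv` (percentage of the encounter
#' ensemble in each subcategory), `state_electrostatics.csv` (mean
#' simultaneous long-range electrostatic contacts per state, when
#' computed) and `rates.csv` (rate constants with units in the header;
#' missing standard deviations are left empty, not zero).
#'
#' @param summary An [ensemble_summary()].
#' @param rates A [two_step_rates()].
#' @param output_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(summary, rates, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(output_dir, x)
  files <- character()
  sub <- summary$subcategory_percent
  utils::write.csv(data.frame(ensemble = "encounter",
                              category = names(sub),
                              percent = as.numeric(sub)),
                   fp("encounter_categories.csv"), row.names = FALSE)
  files <- c(files, fp("encounter_categories.csv"))
  if (!is.null(summary$state_means)) {
    utils::write.csv(summary$state_means, fp("state_electrostatics.csv"),
                     row.names = FALSE)
    files <- c(files, fp("state_electrostatics.csv"))
  }
  sdv <- function(nm) {
    v <- rates$sd[nm]
    if (length(v) && is.finite(v)) as.character(v) else ""
  }
  rt <- data.frame(
    constant = c("k1 (M^-1 s^-1)", "k_minus1 (s^-1)", "k2 (s^-1)",
                 "k_on (M^-1 s^-1)", "k_off (s^-1)", "tau (ns)"),
    value = c(rates$k1, rates$k_minus1, rates$k2, rates$k_on, rates$k_off,
              rates$tau_ns),
    sd = c(sdv("k1"), sdv("k_minus1"), sdv("k2"), sdv("k_on"), sdv("k_off"),
           sdv("tau_ns")))
  utils::write.csv(rt, fp("rates.csv"), row.names = FALSE, na = "")
  invisible(c(files, fp("rates.csv")))
}
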