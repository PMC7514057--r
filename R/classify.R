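# Frame-state assignment and ensemble summaries.

#' State label series container
#'
#' @param primary Character vector per frame: "unbound", "encounter" or
#'   "fully_engaged".
#' @param subcategory Encounter subcategory per frame: "forward",
#'   "reverse", "seg2_only", "other", or "not_applicable" for frames not
#'   in the encounter state.
#' @param native Logical per frame: native fold flag (dihedral RMSD below
#'   the configured cutoff). May be `NA` when not computed.
#' @return Object of class `state_labels`.
#' @export
state_labels <- function(primary,
                         subcategory = rep("not_applicable", length(primary)),
                         native = rep(NA, length(primary))) {
  primary <- as.character(primary)
  subcategory <- as.character(subcategory)
  stopifnot(length(subcategory) == length(primary),
            length(native) == length(primary))
  if (!all(primary %in% c("unbound", "encounter", "fully_engaged")))
    stop("unknown primary state label")
  if (!all(subcategory %in% c("forward", "reverse", "seg2_only", "other",
                              "not_applicable")))
    stop("unknown encounter subcategory label")
  bad <- xor(primary == "encounter", subcategory != "not_applicable")
  if (any(bad))
    stop("subcategory must be 'not_applicable' exactly for non-encounter frames (",
         sum(bad), " violations)")
  structure(list(primary = primary, subcategory = subcategory,
                 native = as.logical(native)), class = "state_labels")
}

#' @export
print.state_labels <- function(x, ...) {
  tb <- table(factor(x$primary,
                     c("unbound", "encounter", "fully_engaged")))
  cat("State labels:", length(x$primary), "frames |",
      paste(names(tb), sprintf("%.1f%%", 100 * tb / sum(tb)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify frames by binding surface distance
#'
#' Assigns every frame to one of three states: fully engaged when the
#' binding surface distance d is below `fully_engaged_max` (11.5 A),
#' unbound when d is above `encounter_max` (23 A), encounter otherwise.
#' Boundary values fall in the encounter class (the state definitions use
#' strict inequalities on both sides).
#'
#' @param series A [metric_series()] of binding surface distances, or a
#'   plain numeric vector.
#' @param config An [analysis_config()].
#' @return Character vector of per-frame primary states.
#' @export
classify_frames <- function(series, config = analysis_config()) {
  d <- if (inherits(series, "metric_series")) series$values else
    as.numeric(series)
  out <- rep("encounter", length(d))
  out[d < config$fully_engaged_max] <- "fully_engaged"
  out[d > config$encounter_max] <- "unbound"
  out
}

# contact test helper: any contact between one peptide position and a
# domain residue group, given the per-frame boolean contact array
.pos_contact <- function(contacts, position, group) {
  p <- as.character(position)
  g <- intersect(as.character(group), dimnames(contacts)[[3]])
  if (!p %in% dimnames(contacts)[[2]])
    stop("peptide position ", position, " absent from contact array")
  if (!length(g)) return(rep(FALSE, dim(contacts)[1]))
  sl <- contacts[, p, g, drop = FALSE]
  apply(sl, 1, any)
}

#' Subcategorize encounter-complex frames
#'
#' Applies the contact rules for the encounter subcategories to each
#' frame: forward requires a K(+3) contact with surface-I residues
#' (8, 9, 10) and a K(-3) contact with the specificity-pocket residues
#' (33, 35, 36); reverse swaps the two lysines; seg2-only requires the
#' K(-3) pocket contact together with a K(-8) contact on surface II
#' (14-17, 49) or an L(-7) contact (32, 33, 36, 49), and not forward or
#' reverse. Frames matching both forward and reverse, or none, are
#' labelled "other". Contacts use the 8 A residue center-of-mass rule.
#'
#' @param contacts Per-frame boolean contact array (frames x peptide
#'   positions x domain residues) as returned by
#'   `contact_map(..., keep_frames = TRUE)$contacts`.
#' @param primary Per-frame primary states from [classify_frames()];
#'   non-encounter frames get "not_applicable".
#' @param config An [analysis_config()] (domain residue groups).
#' @return Character vector of per-frame subcategories.
#' @export
categorize_encounter <- function(contacts, primary,
                                 config = analysis_config()) {
  nf <- dim(contacts)[1]
  stopifnot(length(primary) == nf)
  k3_si  <- .pos_contact(contacts, 3, config$si_residues)
  k3_pk  <- .pos_contact(contacts, 3, config$pocket_residues)
  km3_si <- .pos_contact(contacts, -3, config$si_residues)
  km3_pk <- .pos_contact(contacts, -3, config$pocket_residues)
  km8_s2 <- .pos_contact(contacts, -8, config$sii_k8_residues)
  lm7_s2 <- .pos_contact(contacts, -7, config$sii_l7_residues)
  fwd <- k3_si & km3_pk
  rev <- km3_si & k3_pk
  ambiguous <- fwd & rev          # mutually exclusive by definition
  fwd[ambiguous] <- rev[ambiguous] <- FALSE
  seg2 <- km3_pk & (km8_s2 | lm7_s2) & !fwd & !rev
  out <- rep("other", nf)
  out[seg2] <- "seg2_only"
  out[rev] <- "reverse"
  out[fwd] <- "forward"
  out[primary != "encounter"] <- "not_applicable"
  out
}

#' Native/nonnative cutoff from a dihedral-RMSD histogram
#'
#' Bins the samples (default 1-degree bins, 3-bin moving-average
#' smoothing), locates the first mode, and returns the position of the
#' first local minimum after it, provided a second mode follows. Frames
#' with dihedral RMSD below the cutoff are native.
#'
#' @param samples Numeric dihedral-RMSD samples in degrees (>= 1000).
#' @param bin_width Histogram bin width in degrees (default 1).
#' @param smooth Apply 3-bin moving-average smoothing before minimum
#'   detection (default `TRUE`).
#' @return Cutoff in degrees, or `NA` with a warning when the histogram
#'   is unimodal (no defensible cutoff).
#' @export
native_cutoff_from_histogram <- function(samples, bin_width = 1,
                                         smooth = TRUE) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 1000)
    stop("need at least 1000 samples for a stable histogram cutoff")
  breaks <- seq(0, 180 + bin_width, by = bin_width)
  h <- hist(pmin(pmax(samples, 0), 180), breaks = breaks, plot = FALSE)
  cnt <- h$counts
  if (smooth && length(cnt) >= 3)
    cnt <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  cnt[is.na(cnt)] <- 0
  n <- length(cnt)
  # local maxima (strict rise before, non-rise after)
  is_max <- c(FALSE, diff(cnt) > 0) & c(diff(cnt) <= 0, TRUE) & cnt > 0
  is_max[1] <- cnt[1] > cnt[2]
  modes <- which(is_max)
  # drop negligible modes (< 1% of the main mode) caused by binning noise
  if (length(modes)) modes <- modes[cnt[modes] >= 0.01 * max(cnt[modes])]
  if (length(modes) < 2) {
    warning("histogram is unimodal: no native/nonnative cutoff")
    return(NA_real_)
  }
  seg <- cnt[modes[1]:modes[2]]
  cut_bin <- modes[1] + which.min(seg) - 1
  h$mids[cut_bin]
}

#' Ensemble summary
#'
#' Occupancy of the four state-by-fold quadrants (folded / nonnative
#' crossed with fully engaged / encounter) plus the unbound fraction,
#' percentages of the encounter ensemble in each subcategory, and
#' per-state conditional means of any supplied per-frame series (e.g.
#' simultaneous electrostatic-contact counts, SASA). Empty states yield
#' `NA` (undefined), never zero.
#'
#' @param labels A [state_labels()] object (fold flags required for the
#'   quadrants; `NA` fold flags leave the quadrants `NA`).
#' @param series Named list of per-frame numeric vectors to average by
#'   state.
#' @return Object of class `ensemble_summary`: list with `quadrants`
#'   (named fractions summing with `unbound_fraction` to 1),
#'   `subcategory_percent` (percentages of encounter frames, summing to
#'   100), `state_fractions` and `state_means` (one row per series).
#' @export
ensemble_summary <- function(labels, series = list()) {
  stopifnot(inherits(labels, "state_labels"))
  nf <- length(labels$primary)
  for (nm in names(series))
    if (length(series[[nm]]) != nf)
      stop("series '", nm, "' length ", length(series[[nm]]),
           " does not match ", nf, " frames")
  st <- labels$primary
  frac <- function(mask) sum(mask) / nf
  quad <- if (all(is.na(labels$native))) {
    c(folded_fully_engaged = NA_real_, nonnative_fully_engaged = NA_real_,
      folded_encounter = NA_real_, nonnative_encounter = NA_real_)
  } else {
    nat <- labels$native
    c(folded_fully_engaged = frac(st == "fully_engaged" & nat),
      nonnative_fully_engaged = frac(st == "fully_engaged" & !nat),
      folded_encounter = frac(st == "encounter" & nat),
      nonnative_encounter = frac(st == "encounter" & !nat))
  }
  enc <- labels$subcategory[st == "encounter"]
  subp <- if (length(enc))
    100 * table(factor(enc, c("forward", "reverse", "seg2_only", "other"))) /
      length(enc)
  else
    stats::setNames(rep(NA_real_, 4), c("forward", "reverse", "seg2_only",
                                        "other"))
  states <- c("unbound", "encounter", "fully_engaged")
  smeans <- NULL
  if (length(series)) {
    smeans <- do.call(rbind, lapply(names(series), function(nm) {
      v <- series[[nm]]
      means <- vapply(states, function(s)
        if (any(st == s)) mean(v[st == s]) else NA_real_, numeric(1))
      data.frame(series = nm, t(means))
    }))
    names(smeans)[-1] <- states
  }
  out <- list(quadrants = quad,
              unbound_fraction = frac(st == "unbound"),
              subcategory_percent = c(subp),
              state_fractions = vapply(states, function(s) frac(st == s),
                                       numeric(1)),
              state_means = smeans)
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary\n  state fractions:",
      paste(names(x$state_fractions),
            sprintf("%.1f%%", 100 * x$state_fractions), collapse = ", "), "\n")
  if (!all(is.na(x$quadrants)))
    cat("  quadrants:",
        paste(names(x$quadrants), sprintf("%.1f%%", 100 * x$quadrants),
              collapse = ", "), "\n")
  if (!all(is.na(x$subcategory_percent)))
    cat("  encounter subcategories:",
        paste(names(x$subcategory_percent),
              sprintf("%.1f%%", x$subcategory_percent), collapse = ", "), "\n")
  invisible(x)
}
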