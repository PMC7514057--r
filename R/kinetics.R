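# Transition detection, first-passage times, exponential fitting and
# two-step rate algebra. Times in ns at the interface, rates in s^-1 or
# M^-1 s^-1.

.AVOGADRO <- 6.02214076e23

#' Detect binding transitions with hysteresis
#'
#' Walks the state machine unbound <-> encounter -> fully engaged on a
#' binding-surface-distance trace using the stricter transition
#' thresholds and a minimum dwell: encounter formation fires (only from
#' the unbound state) at the first frame of a window of at least
#' `dwell_ns` with d below `encounter_entry_max` (21 A); full engagement
#' fires (only from the encounter state) for d below `engage_max`
#' (10.5 A); unbinding fires (only from the encounter state) for d above
#' `unbind_min` (25 A). A fully engaged complex silently returns to the
#' encounter state after a dwell with d above `fully_engaged_max`
#' (11.5 A) and below `encounter_entry_max`; sub-dwell excursions never
#' fire events, and a partial window at the end of the trace does not
#' fire.
#'
#' @param series A [metric_series()] of binding surface distances (time
#'   axis supplies the frame interval).
#' @param config An [analysis_config()].
#' @param trajectory_id Identifier stored with the events.
#' @return Data frame of events: `trajectory`, `kind`
#'   ("encounter_formation", "full_engagement", "unbinding"), `time_ns`.
#' @export
detect_transitions <- function(series, config = analysis_config(),
                               trajectory_id = 1L) {
  stopifnot(inherits(series, "metric_series"))
  d <- series$values
  t_ns <- series$time_ns
  nf <- length(d)
  dt <- if (nf > 1) t_ns[2] - t_ns[1] else stop("series too short")
  w <- max(1L, as.integer(round(config$dwell_ns / dt)))
  if (nf < w) stop("series shorter than one dwell window (", w, " frames)")
  win_start <- function(cond) {
    cs <- cumsum(c(0, cond))
    full <- (cs[(w + 1):(nf + 1)] - cs[1:(nf - w + 1)]) == w
    c(full, rep(FALSE, w - 1))
  }
  enter <- win_start(d < config$encounter_entry_max)
  engage <- win_start(d < config$engage_max)
  unbind <- win_start(d > config$unbind_min)
  disengage <- win_start(d > config$fully_engaged_max &
                           d < config$encounter_entry_max)
  state <- classify_frames(d[1], config)
  events <- list()
  push <- function(kind, i)
    events[[length(events) + 1]] <<- data.frame(trajectory = trajectory_id,
                                                kind = kind, time_ns = t_ns[i])
  for (i in seq_len(nf)) {
    if (state == "unbound" && enter[i]) {
      push("encounter_formation", i); state <- "encounter"
    } else if (state == "encounter" && engage[i]) {
      push("full_engagement", i); state <- "fully_engaged"
    } else if (state == "encounter" && unbind[i]) {
      push("unbinding", i); state <- "unbound"
    } else if (state == "fully_engaged" && disengage[i]) {
      state <- "encounter"  # silent return; not a counted event
    }
  }
  if (!length(events))
    return(data.frame(trajectory = integer(), kind = character(),
                      time_ns = numeric()))
  do.call(rbind, events)
}

#' First-passage times to a target state
#'
#' Extracts, per trajectory, the time of the first qualifying transition
#' into the target state; trajectories that never arrive contribute their
#' full length as a censored observation. Trajectories that do not start
#' in the unbound state are excluded with a warning.
#'
#' @param series_list List of [metric_series()] distance traces (one per
#'   trajectory).
#' @param target `"encounter"` or `"fully_engaged"`.
#' @param config An [analysis_config()].
#' @return Object of class `binding_times`: data frame with `trajectory`,
#'   `time_ns`, `censored`, `length_ns`.
#' @export
first_passage_times <- function(series_list,
                                target = c("encounter", "fully_engaged"),
                                config = analysis_config()) {
  target <- match.arg(target)
  kind <- c(encounter = "encounter_formation",
            fully_engaged = "full_engagement")[[target]]
  if (inherits(series_list, "metric_series")) series_list <- list(series_list)
  rows <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    if (classify_frames(s$values[1], config) != "unbound") {
      warning("trajectory ", i, " does not start unbound; excluded")
      next
    }
    ev <- detect_transitions(s, config, trajectory_id = i)
    hit <- ev$time_ns[ev$kind == kind]
    len <- s$time_ns[length(s$time_ns)]
    rows[[length(rows) + 1]] <- data.frame(
      trajectory = i,
      time_ns = if (length(hit)) hit[1] else len,
      censored = !length(hit),
      length_ns = len)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("binding_times", "data.frame")
  out
}

#' Construct binding times directly
#'
#' @param time_ns First-passage times in ns.
#' @param censored Logical censoring flags (censored entries carry the
#'   trajectory length as their time).
#' @param length_ns Trajectory lengths in ns (defaults to `time_ns` for
#'   censored entries and `max(time_ns)` otherwise).
#' @return A `binding_times` data frame.
#' @export
binding_times <- function(time_ns, censored = rep(FALSE, length(time_ns)),
                          length_ns = NULL) {
  if (is.null(length_ns))
    length_ns <- ifelse(censored, time_ns, max(time_ns))
  if (any(time_ns <= 0) || any(time_ns > length_ns + 1e-9))
    stop("binding times must satisfy 0 < t <= trajectory length")
  out <- data.frame(trajectory = seq_along(time_ns), time_ns = time_ns,
                    censored = censored, length_ns = length_ns)
  class(out) <- c("binding_times", "data.frame")
  out
}

#' Fit the exponential binding-time constant
#'
#' The first-passage time to a state entered at constant hazard is
#' exponentially distributed, with cumulative distribution
#' 1 - exp(-t / tau). `ecdf_fit` performs unweighted nonlinear least
#' squares of the empirical CDF of the uncensored times (step heights
#' i/n at the ordered event times) against the theoretical CDF; `mle` is
#' the censoring-aware maximum-likelihood estimator, in closed form the
#' total observed time divided by the number of events.
#'
#' @param times A `binding_times` object.
#' @param method `"ecdf_fit"` (default) or `"mle"`.
#' @return Fitted tau in ns.
#' @export
fit_tau <- function(times, method = c("ecdf_fit", "mle")) {
  method <- match.arg(method)
  stopifnot(inherits(times, "binding_times"))
  ev <- times$time_ns[!times$censored]
  if (!length(ev))
    stop("no uncensored binding events: tau is not identifiable")
  if (method == "mle")
    return(sum(times$time_ns) / length(ev))
  t_sorted <- sort(ev)
  f_emp <- seq_along(t_sorted) / length(t_sorted)
  fit <- minpack.lm::nlsLM(f_emp ~ 1 - exp(-t_sorted / tau),
                           start = list(tau = mean(t_sorted)),
                           lower = 1e-12)
  stats::coef(fit)[["tau"]]
}

#' Binding rate constant from the time constant
#'
#' k = 1 / ([domain] tau), with tau converted from ns to s.
#'
#' @param tau_ns Binding time constant in ns (> 0).
#' @param concentration Domain concentration in M (> 0).
#' @return Rate constant in M^-1 s^-1.
#' @export
rate_from_tau <- function(tau_ns, concentration) {
  if (any(tau_ns <= 0) || any(concentration <= 0))
    stop("tau and concentration must be positive")
  1 / (concentration * tau_ns * 1e-9)
}

#' Effective concentration of n molecules in a simulation box
#'
#' @param volume_A3 Box volume in Angstrom^3 (> 0).
#' @param n Number of molecules (default 1).
#' @return Concentration in M: n / (N_A x volume in liters).
#' @export
concentration_from_volume <- function(volume_A3, n = 1) {
  if (any(volume_A3 <= 0)) stop("volume must be positive")
  n / (.AVOGADRO * volume_A3 * 1e-27)
}

#' Bootstrap standard deviation of a binding rate constant
#'
#' Resamples trajectories with replacement, refits tau on each resample,
#' converts to a rate via [rate_from_tau()], and reports the standard
#' deviation. Resamples with zero uncensored events are skipped (their
#' count is reported).
#'
#' @param times A `binding_times` object (>= 2 trajectories).
#' @param concentration Domain concentration in M.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @param method Fit method passed to [fit_tau()].
#' @return List with `sd` (M^-1 s^-1), `k` (point estimate), `skipped`.
#' @export
bootstrap_rate_sd <- function(times, concentration, B = 1000, seed = 1,
                              method = "ecdf_fit") {
  stopifnot(inherits(times, "binding_times"))
  n <- nrow(times)
  if (n < 2) stop("need at least 2 trajectories to bootstrap")
  set.seed(seed)
  ks <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- times[idx, ]
    class(res) <- class(times)
    if (all(res$censored)) { skipped <- skipped + 1L; next }
    tau <- tryCatch(fit_tau(res, method), error = function(e) NA_real_)
    if (is.finite(tau)) ks[b] <- rate_from_tau(tau, concentration)
  }
  list(sd = stats::sd(ks, na.rm = TRUE),
       k = rate_from_tau(fit_tau(times, method), concentration),
       skipped = skipped)
}

#' Steady-state two-step rate algebra
#'
#' For the scheme unbound <-> encounter -> fully engaged with negligible
#' reverse engagement (k_minus2 = 0), the steady-state overall
#' association constant is k_on = k2 k1 / (k_minus1 + k2). Supplying `k2`
#' computes `k_on` (forward direction); supplying `k_on` inverts the
#' relation, k2 = k_minus1 k_on / (k1 - k_on), which requires
#' 0 < k_on < k1 (encounter formation cannot be slower than overall
#' binding).
#'
#' @param k1 Encounter formation rate constant (M^-1 s^-1).
#' @param k_minus1 Encounter dissociation rate (s^-1).
#' @param k2 Engagement rate (s^-1); give exactly one of `k2`, `k_on`.
#' @param k_on Overall association constant (M^-1 s^-1).
#' @return Named value: `k_on` (forward) or `k2` (inverse).
#' @export
steady_state_rates <- function(k1, k_minus1, k2 = NULL, k_on = NULL) {
  if (is.null(k2) == is.null(k_on))
    stop("supply exactly one of k2 (forward) or k_on (inverse)")
  if (k1 <= 0 || k_minus1 <= 0) stop("rates must be positive")
  if (!is.null(k2)) {
    if (k2 < 0) stop("rates must be non-negative")
    return(c(k_on = k2 * k1 / (k_minus1 + k2)))
  }
  if (k_on <= 0 || k_on >= k1)
    stop("inverse direction requires 0 < k_on < k1 ",
         "(encounter formation cannot be slower than overall binding)")
  c(k2 = k_minus1 * k_on / (k1 - k_on))
}

#' Rates from CPMG relaxation-dispersion fit parameters
#'
#' Downstream algebra for a two-state exchange fit: the dissociation rate
#' is k_off = (1 - p_bound) k_ex, and the association constant follows
#' from the dissociation constant as k_on = k_off / K_d.
#'
#' @param k_ex Exchange rate from the dispersion fit (s^-1, > 0).
#' @param p_bound Bound population fraction (0 <= p_bound < 1).
#' @param K_d Dissociation constant in M (> 0); optional, `k_on` is `NA`
#'   without it.
#' @return Named vector with `k_off` (s^-1) and `k_on` (M^-1 s^-1).
#' @export
cpmg_rates <- function(k_ex, p_bound, K_d = NULL) {
  if (k_ex <= 0) stop("k_ex must be positive")
  if (p_bound < 0 || p_bound >= 1) stop("p_bound must lie in [0, 1)")
  k_off <- (1 - p_bound) * k_ex
  c(k_off = k_off,
    k_on = if (is.null(K_d)) NA_real_ else {
      if (K_d <= 0) stop("K_d must be positive")
      k_off / K_d
    })
}

#' Pseudo-first-order binding timescale of a single molecule
#'
#' @param k_on Association constant (M^-1 s^-1).
#' @param concentration Partner concentration in M.
#' @return Timescale 1 / (k_on x concentration) in seconds.
#' @export
single_molecule_timescale <- function(k_on, concentration) {
  if (k_on <= 0 || concentration <= 0) stop("inputs must be positive")
  1 / (k_on * concentration)
}

#' Two-step rate container
#'
#' Collects the kinetic constants of the two-step scheme with light
#' consistency checking: when `k1`, `k_minus1`, `k2` and `k_on` are all
#' present (and `k_minus2` is 0), they must satisfy the steady-state
#' relation within 1 percent.
#'
#' @param k1,k_on M^-1 s^-1. @param k_minus1,k2,k_minus2,k_off,k_ex s^-1.
#' @param p_bound Bound fraction. @param K_d M. @param tau_ns ns.
#' @param concentration M. @param sd Named numeric vector of standard
#'   deviations for any of the rates.
#' @return Object of class `two_step_rates`.
#' @export
two_step_rates <- function(k1 = NA, k_minus1 = NA, k2 = NA, k_minus2 = 0,
                           k_on = NA, k_off = NA, k_ex = NA, p_bound = NA,
                           K_d = NA, tau_ns = NA, concentration = NA,
                           sd = c()) {
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
            k_on = k_on, k_off = k_off, k_ex = k_ex)
  if (any(vals < 0, na.rm = TRUE)) stop("rates must be non-negative")
  if (!is.na(p_bound) && (p_bound < 0 || p_bound > 1))
    stop("p_bound must lie in [0, 1]")
  if (all(!is.na(c(k1, k_minus1, k2, k_on))) && identical(k_minus2, 0)) {
    pred <- k2 * k1 / (k_minus1 + k2)
    if (abs(pred - k_on) > 0.01 * k_on)
      stop("inconsistent rates: k_on deviates from k2 k1 / (k_minus1 + k2)")
  }
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
                 k_on = k_on, k_off = k_off, k_ex = k_ex, p_bound = p_bound,
                 K_d = K_d, tau_ns = tau_ns, concentration = concentration,
                 sd = sd), class = "two_step_rates")
}

#' @export
print.two_step_rates <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 3)
  cat("Two-step binding rates\n")
  cat("  k1 =", fmt(x$k1), "M^-1 s^-1; k_minus1 =", fmt(x$k_minus1), "s^-1\n")
  cat("  k2 =", fmt(x$k2), "s^-1; k_minus2 =", fmt(x$k_minus2), "s^-1\n")
  cat("  k_on =", fmt(x$k_on), "M^-1 s^-1; k_off =", fmt(x$k_off), "s^-1\n")
  if (!is.na(x$tau_ns)) cat("  tau =", fmt(x$tau_ns), "ns at",
                            fmt(x$concentration), "M\n")
  invisible(x)
}
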