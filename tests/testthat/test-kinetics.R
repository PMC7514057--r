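# build a metric series from (level, duration_ns) segments at 10 ps frames
segment_series <- function(levels, durations_ns, dt_ns = 0.01) {
  v <- unlist(mapply(function(l, d) rep(l, round(d / dt_ns)),
                     levels, durations_ns, SIMPLIFY = FALSE))
  metric_series(v, seq_along(v) * dt_ns, "binding_surface_distance")
}

test_that("transition detection walks the hysteresis state machine", {
  cfg <- analysis_config()
  # 30 (2 ns) -> 20 (2) -> 9 (2) -> 30 (2): engaged state persists at the
  # end, so no unbinding fires
  s1 <- segment_series(c(30, 20, 9, 30), c(2, 2, 2, 2))
  ev1 <- detect_transitions(s1, cfg)
  expect_equal(ev1$kind, c("encounter_formation", "full_engagement"))
  # with a return to 20 before 30, unbinding fires
  s2 <- segment_series(c(30, 20, 9, 20, 30), c(2, 2, 2, 2, 2))
  ev2 <- detect_transitions(s2, cfg)
  expect_equal(ev2$kind,
               c("encounter_formation", "full_engagement", "unbinding"))
  # event times: first frame of the qualifying dwell window
  expect_equal(ev2$time_ns[1], 2.01, tolerance = 1e-9)
  expect_equal(ev2$time_ns[2], 4.01, tolerance = 1e-9)
  expect_equal(ev2$time_ns[3], 8.01, tolerance = 1e-9)
})

test_that("sub-dwell excursions never fire events", {
  cfg <- analysis_config()
  # dip below 10.5 lasting only 0.5 ns
  s <- segment_series(c(30, 20, 9, 20), c(2, 2, 0.5, 2))
  ev <- detect_transitions(s, cfg)
  expect_false("full_engagement" %in% ev$kind)
  # flat unbound trace: no events at all
  flat <- segment_series(30, 8)
  expect_equal(nrow(detect_transitions(flat, cfg)), 0L)
})

test_that("transition sequences form a legal walk on the state machine", {
  cfg <- analysis_config()
  set.seed(14)
  for (rep in 1:10) {
    lv <- sample(c(30, 20, 9, 26), 12, replace = TRUE)
    s <- segment_series(lv, rep(1.5, 12))
    ev <- detect_transitions(s, cfg)
    if (nrow(ev) < 2) next
    for (i in 2:nrow(ev)) {
      prev <- ev$kind[i - 1]; cur <- ev$kind[i]
      # encounter_formation only after unbinding (or at the start);
      # unbinding and full_engagement only after encounter_formation or
      # full engagement followed by silent return
      if (cur == "encounter_formation") expect_equal(prev, "unbinding")
      if (prev == "unbinding") expect_equal(cur, "encounter_formation")
      expect_true(ev$time_ns[i] > ev$time_ns[i - 1])
    }
  }
})

test_that("first-passage extraction censors non-binding trajectories", {
  cfg <- analysis_config()
  bind_at_100 <- segment_series(c(30, 20, 9), c(100, 4, 4))
  never <- segment_series(30, 108)
  fpt <- first_passage_times(list(bind_at_100, never), "fully_engaged", cfg)
  expect_equal(fpt$censored, c(FALSE, TRUE))
  expect_equal(fpt$time_ns[1], 104.01, tolerance = 1e-6)
  expect_equal(fpt$time_ns[2], 108)
  # trajectory starting bound is excluded with a warning
  pre_bound <- segment_series(c(9, 9), c(2, 2))
  expect_warning(
    fpt2 <- first_passage_times(list(bind_at_100, pre_bound),
                                "fully_engaged", cfg),
    "does not start unbound")
  expect_equal(nrow(fpt2), 1L)
})

test_that("a 9-of-50 ensemble yields 9 uncensored and 41 censored times", {
  cfg <- analysis_config()
  set.seed(8)
  traces <- lapply(1:50, function(i) {
    if (i <= 9) segment_series(c(30, 20, 9), c(5 + i, 2, 3))
    else segment_series(c(30, 20), c(6, 4))
  })
  fpt <- first_passage_times(traces, "fully_engaged", cfg)
  expect_equal(sum(!fpt$censored), 9L)
  expect_equal(sum(fpt$censored), 41L)
})

test_that("exponential fitting recovers tau by MLE and ECDF", {
  # MLE on uncensored times equals the mean
  bt <- binding_times(c(50, 150))
  expect_equal(fit_tau(bt, "mle"), 100)
  # censored closed form: (sum of all observed time) / events
  t_obs <- c(30, 80, 120, 200, 45, 90, 150, 60, 110)
  bt2 <- binding_times(c(t_obs, rep(1000, 41)),
                       c(rep(FALSE, 9), rep(TRUE, 41)),
                       rep(1000, 50))
  expect_equal(fit_tau(bt2, "mle"), (sum(t_obs) + 41 * 1000) / 9,
               tolerance = 1e-12)
  # ECDF fit on a large exponential sample
  bt3 <- sample_binding_times(100, 1000, Inf, seed = 42)
  expect_equal(fit_tau(bt3, "ecdf_fit"), 100, tolerance = 0.1)
  expect_error(fit_tau(binding_times(c(10, 10), c(TRUE, TRUE))),
               "no uncensored")
})

test_that("rates follow from tau and concentration with unit discipline", {
  expect_equal(rate_from_tau(1000, 1e-3), 1e9)  # 1 us at 1 mM
  expect_equal(rate_from_tau(52, 4e-3), 4.8e9, tolerance = 0.01)
  # monotone decreasing in both arguments
  expect_gt(rate_from_tau(50, 1e-3), rate_from_tau(60, 1e-3))
  expect_gt(rate_from_tau(50, 1e-3), rate_from_tau(50, 2e-3))
  expect_error(rate_from_tau(-1, 1e-3), "positive")
})

test_that("box volume converts to molar concentration", {
  expect_equal(concentration_from_volume(4.153e5), 4.0e-3, tolerance = 0.01)
  v <- 3e5
  expect_equal(concentration_from_volume(2 * v),
               concentration_from_volume(v) / 2, tolerance = 1e-12)
  # A^3 and nm^3 input paths agree after unit conversion
  k1 <- rate_from_tau(52, concentration_from_volume(4.153e5))
  k2 <- rate_from_tau(52, concentration_from_volume(415.3 * 1e3))
  expect_equal(k1, k2, tolerance = 1e-12)
  expect_error(concentration_from_volume(-5), "positive")
})

test_that("bootstrap SD is reproducible and behaves asymptotically", {
  bt <- sample_binding_times(100, 50, Inf, seed = 7)
  b1 <- bootstrap_rate_sd(bt, 4e-3, B = 300, seed = 5)
  b2 <- bootstrap_rate_sd(bt, 4e-3, B = 300, seed = 5)
  expect_identical(b1$sd, b2$sd)
  # CV of the exponential rate estimator is ~ 1/sqrt(n)
  expect_equal(b1$sd / b1$k, 1 / sqrt(50), tolerance = 0.4)
  # identical times: MLE tau identical in every resample, SD exactly 0
  same <- binding_times(rep(80, 10))
  expect_equal(bootstrap_rate_sd(same, 4e-3, B = 50, seed = 1,
                                 method = "mle")$sd, 0)
})

test_that("steady-state algebra inverts exactly and guards its domain", {
  k1 <- 4.8e9; km1 <- 2.6e7; kon <- 1.21e8
  k2 <- steady_state_rates(k1, km1, k_on = kon)[["k2"]]
  expect_equal(k2, 6.7e5, tolerance = 0.01)
  # round trip to machine precision
  kon2 <- steady_state_rates(k1, km1, k2 = k2)[["k_on"]]
  expect_equal(kon2, kon, tolerance = 1e-12)
  # k_on -> 0 implies k2 -> 0
  expect_lt(steady_state_rates(k1, km1, k_on = 1)[["k2"]], 1e-2)
  expect_error(steady_state_rates(k1, km1, k_on = k1 * 1.1), "k_on < k1")
  expect_error(steady_state_rates(k1, km1), "exactly one")
})

test_that("CPMG algebra yields k_off and k_on", {
  r <- cpmg_rates(224, 0.08, 1.7e-6)
  expect_equal(r[["k_off"]], (1 - 0.08) * 224)
  expect_equal(r[["k_off"]], 206.1, tolerance = 0.005)
  expect_equal(r[["k_on"]], 1.21e8, tolerance = 0.01)
  # p_bound -> 1 limit: k_off -> 0
  expect_equal(cpmg_rates(224, 1 - 1e-12, 1.7e-6)[["k_off"]], 0,
               tolerance = 1e-9)
  expect_error(cpmg_rates(224, 1, 1.7e-6), "p_bound")
})

test_that("two-step rate container checks internal consistency", {
  expect_error(two_step_rates(k1 = -1), "non-negative")
  kon <- steady_state_rates(4.8e9, 2.6e7, k2 = 6.8e5)[["k_on"]]
  r <- two_step_rates(k1 = 4.8e9, k_minus1 = 2.6e7, k2 = 6.8e5, k_on = kon)
  expect_s3_class(r, "two_step_rates")
  expect_error(two_step_rates(k1 = 4.8e9, k_minus1 = 2.6e7, k2 = 6.8e5,
                              k_on = kon * 2), "inconsistent")
})
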