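# Minima detection, period/amplitude estimation, alignment, turnoff.

test_that("minima of an exact sampled cosine are recovered within a frame", {
  tt <- seq(0, 42, by = 0.5)
  y <- 5 + cos(2 * pi * tt / 21)    # minima at 10.5 and 31.5
  m <- detect_minima(y, tt, 21)
  expect_equal(nrow(m), 2L)
  expect_true(all(abs(m$time - c(10.5, 31.5)) <= 0.5))
  # strictly increasing ramp -> empty
  expect_equal(nrow(detect_minima(seq_along(tt) * 1.0, tt, 21)), 0L)
})

test_that("minima detection is shift-equivariant and offset-invariant", {
  set.seed(2)
  tt <- seq(0, 63, by = 0.5)
  y <- 1500 - 1000 * cos(2 * pi * (tt - 3) / 21) + rnorm(length(tt), 0, 20)
  m0 <- detect_minima(y, tt, 21)$time
  k <- 8                                       # shift by 8 frames = 4 h
  m_shift <- detect_minima(y, tt + k * 0.5, 21)$time
  expect_equal(m_shift, m0 + k * 0.5, tolerance = 1e-6)
  m_off <- detect_minima(y + 300, tt, 21)$time
  expect_equal(m_off, m0, tolerance = 1e-6)
})

test_that("noisy minima stay within the 1 h precision bound", {
  set.seed(33)
  s <- sqrt(log(1.0025))               # measurement CV 0.05
  hits <- 0; total <- 0
  for (r in 1:120) {
    theta <- runif(1, 0, 2 * pi)
    tt <- seq(0, 63, by = 0.5)
    y <- (1500 + 1000 * -cos(2 * pi * (tt / 21 + theta / (2 * pi)))) *
      exp(rnorm(length(tt), -s^2 / 2, s))
    truem <- filaclock:::true_minima(21, theta, 63)
    m <- detect_minima(y, tt, 21)$time
    for (mm in m) {
      total <- total + 1
      if (min(abs(mm - truem)) <= 1) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("period estimation pools minima spacings as specified", {
  p1 <- estimate_period(c(0, 21, 42))
  expect_equal(p1$mean, 21); expect_equal(p1$se, 0)
  expect_equal(estimate_period(c(0, 20, 22))$mean, 11)  # spacings 20 and 2
  expect_equal(estimate_period(list(c(0, 20, 22)))$mean, 11)
  coh <- estimate_period(list(c(0, 21), c(1, 23), c(2, 22)))
  expect_equal(coh$mean, mean(c(21, 22, 20)))
  expect_equal(coh$n, 3L)
  expect_error(estimate_period(list(c(5), c(7))),
               class = "filaclock_domain_error")
  # invariance to intensity rescaling (through minima detection)
  tt <- seq(0, 63, by = 0.5)
  y <- 5 + cos(2 * pi * tt / 21)
  m1 <- detect_minima(y, tt, 21)$time
  m2 <- detect_minima(1000 * y, tt, 21)$time
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("cycle windows tile the span between consecutive minima", {
  cw <- cycle_windows(c(0, 21, 42))
  expect_equal(cw$t_start, c(0, 21))
  expect_equal(cw$t_end, c(21, 42))
  expect_equal(cw$cycle_index, 1:2)
  expect_equal(nrow(cycle_windows(10)), 0L)
})

test_that("amplitude is half the peak-to-trough range", {
  tt <- seq(0, 21, by = 0.5)
  y <- 7 + 3 * cos(2 * pi * tt / 21)
  expect_equal(amplitude(y, c(0, 21), tt), 3, tolerance = 0.01)
  expect_equal(amplitude(rep(4, length(tt)), c(0, 21), tt), 0)
})

test_that("noise-free generator recovers the 5x heterocyst amplitude ratio", {
  cfg <- regime_preset("nitrogen_deprived", seed = 41, n_filaments = 2,
                       oscillator = oscillator_params(
                         period_sd = 0, within_interval_phase_sd = 0,
                         across_interval_phase_mode = "independent_uniform"),
                       differentiation = differentiation_params(
                         events_per_interval_per_cycle = 0),
                       noise = noise_params(measurement_cv = 0,
                                            extrinsic_cell_cv = 0))
  sim <- simulate_cohort(cfg)
  trs <- resolve_lineages(sim$series)
  kind <- sim$truth$cells$kind[match(names(trs), sim$truth$cells$cell_id)]
  ar <- amplitude_ratio(trs[kind == "veg"], trs[kind == "het"], 21)
  expect_equal(ar$ratio, 5, tolerance = 0.05)
})

test_that("event alignment preserves shape and handles edge cases", {
  trs <- sin_traces(c(0, 0), dt = 0.5, n_periods = 2)
  # identical traces shifted events: mean equals the single shifted trace
  al <- align_by_event(trs, c(10, 12))
  common <- !apply(al$mat, 1, function(r) any(is.na(r)))
  expect_gt(sum(common), 10)
  # at rel time 0 both traces are at their event value
  i0 <- which(al$rel_times == 0)
  expect_equal(al$mat[i0, 1], trs[[1]]$gfp[trs[[1]]$times == 10])
  expect_equal(al$mat[i0, 2], trs[[2]]$gfp[trs[[2]]$times == 12])
  # matched events on dephased cosines: no phase-smearing amplitude loss
  P <- 21
  phs <- c(0, 1.1, 2.5)
  trs2 <- sin_traces(phs, period = P, dt = 0.5, n_periods = 3)
  events <- (pi - phs) %% (2 * pi) / (2 * pi) * P + P  # a common feature
  al2 <- align_by_event(trs2, events)
  common2 <- !apply(al2$mat, 1, function(r) any(is.na(r)))
  mean_amp <- (max(al2$mean[common2]) - min(al2$mean[common2])) / 2
  expect_equal(mean_amp, 1, tolerance = 0.05)
  # single trace: mean equals the trace
  al3 <- align_by_event(trs[1], 10)
  expect_equal(al3$mean, trs[[1]]$gfp)
  expect_error(align_by_event(trs, c(10, 999)),
               class = "filaclock_window_error")
})

test_that("turnoff gradient recovers the configured per-cell delay", {
  mk_cfg <- function(delay, seed) regime_preset(
    "nitrogen_deprived", n_filaments = 2, seed = seed,
    oscillator = oscillator_params(
      across_interval_phase_mode = "independent_uniform",
      waveform = "rise_hold_decay", within_interval_phase_sd = 0,
      period_sd = 0, turnoff_delay_per_cell = delay),
    differentiation = differentiation_params(events_per_interval_per_cycle = 0),
    noise = noise_params(measurement_cv = 0.02))
  sim <- simulate_cohort(mk_cfg(0.5, 3))
  trs <- resolve_lineages(sim$series)
  ivs <- Filter(function(v) v$bounded, intervals_at(sim$series, 0))
  recs <- do.call(rbind, lapply(ivs, function(v)
    interval_turnoffs(trs, v, 21)))
  g <- turnoff_gradient(recs)
  expect_lt(abs(g$slope - 0.5), 0.1)
  # zero configured delay -> slope ~ 0
  sim0 <- simulate_cohort(mk_cfg(0, 4))
  trs0 <- resolve_lineages(sim0$series)
  ivs0 <- Filter(function(v) v$bounded, intervals_at(sim0$series, 0))
  recs0 <- do.call(rbind, lapply(ivs0, function(v)
    interval_turnoffs(trs0, v, 21)))
  expect_lt(abs(turnoff_gradient(recs0)$slope), 0.1)
  # single measurable distance -> degenerate gradient
  expect_error(turnoff_gradient(recs[recs$distance_to_heterocyst == 2, ]),
               class = "filaclock_degenerate_error")
})
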