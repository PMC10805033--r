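# Synthetic cohort generator: determinism, phase structure, gating truth.

test_that("identical seeds give identical cohorts, byte for byte", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 2,
                       duration_h = 48, seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$truth$events, s2$truth$events)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traces(s1$series, p1); write_traces(s2$series, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noise-free shared-phase cosine cohort is an exact sampled cosine", {
  cfg <- sim_config(
    n_filaments = 1, n_intervals_per_filament = 2, duration_h = 44,
    oscillator = oscillator_params(period_sd = 0,
                                   within_interval_phase_sd = 0,
                                   across_interval_phase_mode = "shared"),
    differentiation = differentiation_params(events_per_interval_per_cycle = 0),
    noise = noise_params(measurement_cv = 0, extrinsic_cell_cv = 0),
    seed = 3)
  sim <- simulate_cohort(cfg)
  tru <- sim$truth$cells
  veg <- tru[tru$kind == "veg", ]
  one <- sim$series[sim$series$cell_id == veg$cell_id[1], ]
  one <- one[order(one$time_h), ]
  expected <- (1500 + 1000 * -cos(2 * pi * (one$time_h / veg$period[1] +
                                              veg$theta[1] / (2 * pi)))) *
    one$area
  expect_equal(one$gfp, expected, tolerance = 1e-10)
  # all vegetative traces identical up to cell scale -> R = 1 over a period
  trs <- resolve_lineages(sim$series)
  vtr <- trs[veg$cell_id]
  win <- c(0, veg$period[1] - 0.5)
  expect_equal(sync_index(vtr, window = win)$R, 1, tolerance = 1e-9)
})

test_that("within an interval, zero-noise traces differ only by scale and delay", {
  cfg <- sim_config(
    n_filaments = 1, n_intervals_per_filament = 2, duration_h = 44,
    oscillator = oscillator_params(period_sd = 0,
                                   within_interval_phase_sd = 0),
    differentiation = differentiation_params(events_per_interval_per_cycle = 0),
    noise = noise_params(measurement_cv = 0, extrinsic_cell_cv = 0.2),
    seed = 12)
  sim <- simulate_cohort(cfg)
  tru <- sim$truth$cells
  iv1 <- tru[tru$kind == "veg" & tru$interval_id == tru$interval_id[2], ]
  trs <- resolve_lineages(sim$series)
  ref <- trs[[iv1$cell_id[1]]]$gfp / iv1$extrinsic[1]
  for (k in seq_len(nrow(iv1))) {
    got <- trs[[iv1$cell_id[k]]]$gfp / iv1$extrinsic[k]
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("independent interval phases are uniform on the circle", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 20,
                       n_intervals_per_filament = 10, duration_h = 44,
                       seed = 31)
  sim <- simulate_cohort(cfg)
  phi <- sim$truth$intervals$phi
  expect_gte(length(phi), 200L)
  ct <- table(cut(phi %% (2 * pi), breaks = seq(0, 2 * pi, length.out = 9)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("regime presets encode the two nitrogen regimes", {
  rep_cfg <- regime_preset("nitrogen_replete", seed = 2)
  expect_equal(rep_cfg$oscillator$across_interval_phase_mode, "shared")
  expect_equal(rep_cfg$differentiation$events_per_interval_per_cycle, 0)
  simr <- simulate_cohort(rep_cfg)
  expect_equal(nrow(simr$truth$events), 0L)
  expect_false(any(simr$series$cell_type == "heterocyst"))

  dep_cfg <- regime_preset("nitrogen_deprived", n_filaments = 5,
                           n_intervals_per_filament = 4, seed = 2)
  simd <- simulate_cohort(dep_cfg)
  # 20 intervals x ~4 cycles at 0.15/interval/cycle: >= 1 event essentially
  # surely (1 - 0.85^80 ~ 1)
  expect_gte(nrow(simd$truth$events), 1L)
  expect_error(regime_preset("nitrogen_rich"), class = "filaclock_error")
})

test_that("presets round-trip through YAML and JSON config files", {
  for (ext in c(".yaml", ".json")) {
    cfg <- regime_preset("nitrogen_deprived", seed = 9)
    p <- withr::local_tempfile(fileext = ext)
    write_config(cfg, p)
    back <- read_config(p)
    expect_equal(back, cfg, tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_filaments = 2, nonsense_key = 1), bad,
                       auto_unbox = TRUE)
  expect_error(read_config(bad), class = "filaclock_schema_error",
               regexp = "nonsense_key")
})

test_that("heterocysts are never adjacent with suppression_radius >= 1", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 4, seed = 77,
                       differentiation = differentiation_params(
                         events_per_interval_per_cycle = 0.6,
                         suppression_radius = 1))
  sim <- simulate_cohort(cfg)
  expect_gt(nrow(sim$truth$events), 0L)
  df <- sim$series
  for (tt in unique(df$time_h[df$time_h %% 12 == 0])) {
    fr <- df[df$time_h == tt, ]
    for (f in unique(fr$filament_id)) {
      d <- fr[fr$filament_id == f, ]
      het <- d$cell_type[order(d$pos_index)] == "heterocyst"
      expect_false(any(het[-1] & het[-length(het)]))
    }
  }
})

test_that("true gate phases concentrate at the configured gate center", {
  ev <- simulate_gating_events(1000, seed = 5)
  g <- ev$truth$gate_phase
  z <- mean(exp(2i * pi * g))
  mu <- (Arg(z) / (2 * pi)) %% 1
  # circular SE of a wrapped normal, sd 0.05 cycles, n = 1000
  se <- 0.05 / sqrt(1000)
  expect_lt(min(abs(mu - 0.6), 1 - abs(mu - 0.6)), 3 * se)
})

test_that("ground-truth cycle indices match minima counts before onset", {
  for (src in list(simulate_gating_events(200, seed = 6)$truth,
                   simulate_cohort(regime_preset("nitrogen_deprived",
                                                 n_filaments = 6,
                                                 seed = 13))$truth$events)) {
    expect_gt(nrow(src), 0L)
    for (i in seq_len(nrow(src))) {
      mins <- filaclock:::true_minima(src$period[i], src$theta[i],
                                      src$t_on[i] + src$period[i])
      expect_equal(sum(mins <= src$t_on[i] + 1e-9), src$cycle_index[i])
    }
  }
})

test_that("a zero-width gate snaps events to the frame grid with a warning", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 4, seed = 19,
                       differentiation = differentiation_params(
                         gate_sd = 0,
                         events_per_interval_per_cycle = 0.5))
  w <- capture_warnings(sim <- simulate_cohort(cfg))
  expect_true(any(grepl("snapped", w)))
  # snapped onsets sit on the frame grid
  expect_true(all(abs(sim$truth$events$t_on / 0.5 -
                        round(sim$truth$events$t_on / 0.5)) < 1e-9))
})
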