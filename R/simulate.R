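# Synthetic filament-cohort generator.  Emulates circadian reporter traces
# along heterocyst-patterned filaments: per-cell oscillators with a common
# phase per vegetative interval (independent across intervals under nitrogen
# deprivation, one shared phase under replete conditions), 5-fold smaller
# oscillation amplitude in heterocysts, position-graded expression turnoff,
# and clock-phase-gated autofluorescence decay onsets.  A ground-truth log
# (phases, periods, events, divisions) supports parameter-recovery tests.

#' Oscillator parameters for the trace generator
#'
#' @param period_mean,period_sd circadian period distribution across cells,
#'   hours.
#' @param amplitude_veg oscillation amplitude in vegetative cells, a.u.
#' @param amplitude_het_ratio factor by which heterocyst amplitude is
#'   smaller (>= 1).
#' @param baseline mean expression level, a.u. (must exceed
#'   `amplitude_veg` so intensities stay positive).
#' @param within_interval_phase_sd per-cell phase jitter around the
#'   interval phase, radians.
#' @param across_interval_phase_mode `"independent_uniform"` (each interval
#'   draws its phase uniformly on \eqn{[0, 2\pi)}) or `"shared"` (one
#'   cohort-wide draw).
#' @param turnoff_delay_per_cell delay of the expression decay segment,
#'   hours per cell of distance to the nearest bounding heterocyst
#'   (`rise_hold_decay` waveform only).
#' @param waveform `"cosine"` (analytic default) or `"rise_hold_decay"`
#'   (linear rise over 40% of the cycle, hold 10%, parabolic decay 50%,
#'   with the per-cell decay delay above).
#' @return List of class `oscillator_params`.
#' @export
oscillator_params <- function(period_mean = 21, period_sd = 1,
                              amplitude_veg = 1000, amplitude_het_ratio = 5,
                              baseline = 1500,
                              within_interval_phase_sd = 0.5,
                              across_interval_phase_mode =
                                c("independent_uniform", "shared"),
                              turnoff_delay_per_cell = 0.5,
                              waveform = c("cosine", "rise_hold_decay")) {
  fila_assert(period_mean > 0 && period_sd >= 0, "domain",
              "period_mean must be > 0 and period_sd >= 0")
  fila_assert(amplitude_het_ratio >= 1, "domain", "amplitude_het_ratio >= 1")
  fila_assert(within_interval_phase_sd >= 0, "domain", "phase sd >= 0")
  structure(list(period_mean = period_mean, period_sd = period_sd,
                 amplitude_veg = amplitude_veg,
                 amplitude_het_ratio = amplitude_het_ratio,
                 baseline = baseline,
                 within_interval_phase_sd = within_interval_phase_sd,
                 across_interval_phase_mode =
                   match.arg(across_interval_phase_mode),
                 turnoff_delay_per_cell = turnoff_delay_per_cell,
                 waveform = match.arg(waveform)),
            class = "oscillator_params")
}

#' Differentiation (gating) parameters for the trace generator
#'
#' @param gate_center,gate_sd wrapped-normal distribution of the clock
#'   phase (cycle fraction in \eqn{[0,1)}, 0 = expression minimum) at which
#'   autofluorescence decay begins in cells that differentiate.
#' @param events_per_interval_per_cycle probability that an interval
#'   initiates one differentiation event in a given circadian cycle.
#' @param af_decay_curvature curvature of the post-onset autofluorescence
#'   parabola, a.u. per hour^2 (concentration scale); the default 20 lets
#'   AF fall to half its baseline in about 7 h, matching the loss of
#'   photosynthetic pigments over roughly half a day of differentiation.
#' @param af_baseline_veg vegetative autofluorescence level, a.u.
#' @param suppression_radius no event within this many cells of an existing
#'   heterocyst or differentiating cell.
#' @param maturation_h hours from decay onset to mature heterocyst.
#' @return List of class `differentiation_params`.
#' @export
differentiation_params <- function(gate_center = 0.6, gate_sd = 0.05,
                                   events_per_interval_per_cycle = 0.15,
                                   af_decay_curvature = 20,
                                   af_baseline_veg = 2000,
                                   suppression_radius = 2,
                                   maturation_h = 8) {
  fila_assert(gate_center >= 0 && gate_center < 1, "domain",
              "gate_center in [0, 1)")
  fila_assert(events_per_interval_per_cycle >= 0 &&
                events_per_interval_per_cycle <= 1, "domain",
              "events_per_interval_per_cycle is a probability")
  structure(list(gate_center = gate_center, gate_sd = gate_sd,
                 events_per_interval_per_cycle = events_per_interval_per_cycle,
                 af_decay_curvature = af_decay_curvature,
                 af_baseline_veg = af_baseline_veg,
                 suppression_radius = suppression_radius,
                 maturation_h = maturation_h),
            class = "differentiation_params")
}

#' Noise parameters for the trace generator
#'
#' @param measurement_cv per-frame multiplicative (lognormal, mean 1)
#'   measurement noise, as a coefficient of variation.
#' @param extrinsic_cell_cv static per-cell multiplicative scale factor CV.
#' @return List of class `noise_params`.
#' @export
noise_params <- function(measurement_cv = 0.05, extrinsic_cell_cv = 0.1) {
  fila_assert(measurement_cv >= 0 && extrinsic_cell_cv >= 0, "domain",
              "noise CVs must be >= 0")
  structure(list(measurement_cv = measurement_cv,
                 extrinsic_cell_cv = extrinsic_cell_cv),
            class = "noise_params")
}

#' Full simulation configuration
#'
#' @param n_filaments number of filaments in the cohort.
#' @param interval_length_range integer pair: vegetative cells per interval
#'   (heterocyst spacing), default 10--15.
#' @param n_intervals_per_filament bounded vegetative intervals per
#'   filament (0 gives an undifferentiated, heterocyst-free filament).
#' @param duration_h experiment length, hours (>= 2 periods).
#' @param dt_h sampling step, hours (default 0.5, one image every 30 min).
#' @param oscillator,differentiation,noise parameter blocks; see
#'   [oscillator_params()], [differentiation_params()], [noise_params()].
#' @param division_enabled simulate cell growth and division (area doubles
#'   over `doubling_time_h`; at division the area halves and total
#'   intensities partition binomially).
#' @param doubling_time_h cell doubling time, hours.
#' @param seed root RNG seed; per-filament child seeds are derived by fixed
#'   arithmetic, so cohorts are reproducible under subsetting.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_filaments = 3,
                       interval_length_range = c(10L, 15L),
                       n_intervals_per_filament = 3,
                       duration_h = 96, dt_h = 0.5,
                       oscillator = oscillator_params(),
                       differentiation = differentiation_params(),
                       noise = noise_params(),
                       division_enabled = FALSE,
                       doubling_time_h = 24,
                       seed = 1L) {
  fila_assert(dt_h > 0, "domain", "dt_h must be > 0")
  fila_assert(duration_h >= 2 * oscillator$period_mean, "domain",
              "duration_h must cover at least two periods")
  fila_assert(length(interval_length_range) == 2L &&
                interval_length_range[1] <= interval_length_range[2] &&
                interval_length_range[1] >= 1, "domain",
              "interval_length_range must be an increasing integer pair")
  structure(list(n_filaments = as.integer(n_filaments),
                 interval_length_range = as.integer(interval_length_range),
                 n_intervals_per_filament = as.integer(n_intervals_per_filament),
                 duration_h = duration_h, dt_h = dt_h,
                 oscillator = oscillator, differentiation = differentiation,
                 noise = noise, division_enabled = isTRUE(division_enabled),
                 doubling_time_h = doubling_time_h, seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset configurations for the two nitrogen regimes
#'
#' `nitrogen_deprived` gives heterocyst-bounded 10--15-cell intervals with
#' independent interval phases and clock-gated differentiation events;
#' `nitrogen_replete` gives undifferentiated filaments with one cohort-wide
#' shared phase and no differentiation.
#'
#' @param name `"nitrogen_deprived"` or `"nitrogen_replete"`.
#' @param ... overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
regime_preset <- function(name = c("nitrogen_deprived", "nitrogen_replete"),
                          ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) fila_stop("domain",
                     paste("unknown regime preset:", name[1])))
  base <- if (name == "nitrogen_deprived") {
    list(oscillator = oscillator_params(across_interval_phase_mode =
                                          "independent_uniform"),
         differentiation = differentiation_params())
  } else {
    list(n_intervals_per_filament = 0L,
         interval_length_range = c(25L, 30L),
         oscillator = oscillator_params(across_interval_phase_mode =
                                          "shared"),
         differentiation =
           differentiation_params(events_per_interval_per_cycle = 0))
  }
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

# Waveform on the cycle fraction u in [0,1), minimum at u = 0.
# decay_start (scalar, >= 0.5) delays the decay segment of rise_hold_decay;
# the parabolic decay is compressed so the next minimum stays at u = 1.
waveform_eval <- function(u, waveform, decay_start = 0.5) {
  if (waveform == "cosine") return(-cos(2 * pi * u))
  d <- min(max(decay_start, 0.5), 0.85)
  w <- numeric(length(u))
  rise <- u < 0.4
  hold <- u >= 0.4 & u < d
  dec <- u >= d
  w[rise] <- -1 + u[rise] / 0.4 * 2
  w[hold] <- 1
  w[dec] <- 1 - 2 * ((u[dec] - d) / (1 - d))^2
  w
}

# cycle fraction of a cell at time t: u = (t/T + theta/2pi) mod 1, with
# u = 0 at an expression minimum.
cycle_fraction <- function(t, period, theta) {
  (t / period + theta / (2 * pi)) %% 1
}

# true expression minima of a cell in [0, duration]
true_minima <- function(period, theta, duration) {
  m0 <- ((1 - (theta / (2 * pi)) %% 1) %% 1) * period
  mm <- seq(m0, duration, by = period)
  mm[mm >= 0 & mm <= duration]
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate a filament cohort with ground truth
#'
#' Generates a long-format [filament_series()] plus a ground-truth log.
#' Vegetative GFP concentration of cell \eqn{i} in interval \eqn{j} is
#' \deqn{g_i(t) = (B + A_i\, w(2\pi t/T_i + \phi_j + \epsilon_i))\,
#'       E_i\, \eta_i(t),}
#' with interval phase \eqn{\phi_j} (independent uniform or shared),
#' per-cell jitter \eqn{\epsilon_i}, static extrinsic factor \eqn{E_i} and
#' per-frame measurement noise \eqn{\eta_i(t)}.  Heterocysts oscillate with
#' the amplitude divided by `amplitude_het_ratio` and the phase inherited
#' from their progenitor.  Autofluorescence is flat at `af_baseline_veg`
#' until a differentiation event at \eqn{t_{on}}, then decays as
#' \eqn{B_{af} - c (t - t_{on})^2} (clipped at a 5% floor); events are
#' placed so the cell's clock phase at \eqn{t_{on}} is wrapped-normal
#' around `gate_center`.  Recorded `gfp`/`af` are totals
#' (concentration x area).
#'
#' @param config a [sim_config()].
#' @return List with `series` (a [filament_series()]) and `truth`, a list
#'   of data frames: `cells` (true phase, period, extrinsic factor,
#'   distance), `intervals` (interval phase), `events` (onset time, gate
#'   phase, cycle index), `divisions`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  osc <- config$oscillator; dif <- config$differentiation
  noi <- config$noise
  dt <- config$dt_h
  times <- seq(0, config$duration_h, by = dt)
  af_floor <- 0.05 * dif$af_baseline_veg

  phi_shared <- with_seed(config$seed, stats::runif(1, 0, 2 * pi))

  rec_list <- list()
  truth_cells <- list(); truth_intervals <- list()
  truth_events <- list(); truth_div <- list()

  for (f in seq_len(config$n_filaments)) {
    res <- with_seed(child_seed(config$seed, f),
                     simulate_filament(f, times, config, phi_shared, af_floor))
    rec_list[[f]] <- res$records
    truth_cells[[f]] <- res$cells
    truth_intervals[[f]] <- res$intervals
    truth_events[[f]] <- res$events
    truth_div[[f]] <- res$divisions
  }
  df <- do.call(rbind, rec_list)
  series <- filament_series(df, validate = FALSE)
  attr(series, "dt") <- dt
  list(series = series,
       truth = list(cells = do.call(rbind, truth_cells),
                    intervals = do.call(rbind, truth_intervals),
                    events = do.call(rbind, truth_events),
                    divisions = do.call(rbind, truth_div)))
}

# one filament; called under its child seed
simulate_filament <- function(f, times, config, phi_shared, af_floor) {
  osc <- config$oscillator; dif <- config$differentiation
  noi <- config$noise
  dur <- config$duration_h; dt <- config$dt_h
  fid <- sprintf("F%02d", f)
  n_iv <- config$n_intervals_per_filament
  lr <- config$interval_length_range

  if (n_iv >= 1L) {
    lens <- sample(seq(lr[1], lr[2]), n_iv, replace = TRUE)
    # pattern: H | interval 1 | H | interval 2 | ... | H
    layout <- list()
    for (j in seq_len(n_iv)) {
      layout[[length(layout) + 1L]] <- list(kind = "het", interval = j - 1L)
      for (i in seq_len(lens[j]))
        layout[[length(layout) + 1L]] <- list(kind = "veg", interval = j,
                                              pos_in_iv = i, iv_len = lens[j])
    }
    layout[[length(layout) + 1L]] <- list(kind = "het", interval = n_iv)
  } else {
    len <- sample(seq(lr[1], lr[2]), 1L)
    layout <- lapply(seq_len(len), function(i)
      list(kind = "veg", interval = 1L, pos_in_iv = i, iv_len = len))
    lens <- len
  }
  n_cells <- length(layout)
  n_true_iv <- if (n_iv >= 1L) n_iv else 1L

  phi <- if (osc$across_interval_phase_mode == "shared")
    rep(phi_shared, n_true_iv) else stats::runif(n_true_iv, 0, 2 * pi)

  cells <- data.frame(
    cell_id = sprintf("%s_c%03d", fid, seq_len(n_cells)),
    kind = vapply(layout, `[[`, "", "kind"),
    interval = vapply(layout, function(l) as.integer(l$interval), 0L),
    pos_in_iv = vapply(layout, function(l)
      if (is.null(l$pos_in_iv)) NA_integer_ else as.integer(l$pos_in_iv), 0L),
    iv_len = vapply(layout, function(l)
      if (is.null(l$iv_len)) NA_integer_ else as.integer(l$iv_len), 0L),
    stringsAsFactors = FALSE)
  # distance to nearest bounding heterocyst (bounded intervals only)
  cells$distance <- ifelse(cells$kind == "veg" & n_iv >= 1L,
                           pmin(cells$pos_in_iv, cells$iv_len + 1L -
                                  cells$pos_in_iv), NA_integer_)
  cells$distance[cells$kind == "het"] <- 0L

  # per-cell oscillator draws; heterocysts inherit the phase of the
  # adjacent (left, or right for the leftmost) interval, as from a sister.
  eps <- stats::rnorm(n_cells, 0, osc$within_interval_phase_sd)
  own_iv <- ifelse(cells$kind == "het", pmax(cells$interval, 1L),
                   cells$interval)
  theta <- phi[own_iv] + eps
  period <- pmax(4, stats::rnorm(n_cells, osc$period_mean, osc$period_sd))
  extr <- lognorm_factor(n_cells, noi$extrinsic_cell_cv)
  area0 <- pmax(1, stats::rnorm(n_cells, 5, 0.25))
  delay_u0 <- 0.5 + ifelse(is.na(cells$distance), 0,
                           cells$distance * osc$turnoff_delay_per_cell) / period

  # ---- differentiation events (clock-phase gated) ----------------------
  events <- list()
  warned_snap <- FALSE
  if (dif$events_per_interval_per_cycle > 0 && n_iv >= 1L) {
    taken <- rep(FALSE, n_cells)
    for (j in seq_len(n_iv)) {
      iv_rows <- which(cells$kind == "veg" & cells$interval == j)
      L <- lens[j]
      max_cycles <- max(1L, floor(dur / osc$period_mean))
      for (k in seq_len(max_cycles)) {
        if (stats::runif(1) > dif$events_per_interval_per_cycle) next
        ev_pos <- cells$pos_in_iv[iv_rows][taken[iv_rows]]
        elig <- iv_rows[!taken[iv_rows] &
                          cells$distance[iv_rows] > dif$suppression_radius]
        if (length(ev_pos) > 0L && length(elig) > 0L)
          elig <- elig[vapply(cells$pos_in_iv[elig], function(p)
            all(abs(p - ev_pos) > dif$suppression_radius), TRUE)]
        if (length(elig) == 0L) next
        i <- if (length(elig) == 1L) elig else sample(elig, 1L)
        g <- stats::rnorm(1, dif$gate_center, dif$gate_sd) %% 1
        mins <- true_minima(period[i], theta[i], dur + 2 * period[i])
        if (length(mins) < k + 1L) next
        t_on <- mins[k] + g * period[i]
        if (dif$gate_sd == 0) {
          # no frame hits the exact phase: schedule at the nearest frame
          t_on <- snap_to_grid(t_on, dt)
          g <- (t_on - mins[k]) / period[i]
          if (!warned_snap) {
            warning("gate_sd = 0: events snapped to the nearest frame",
                    call. = FALSE)
            warned_snap <- TRUE
          }
        }
        if (t_on < 6 || t_on > dur - 6) next
        taken[i] <- TRUE
        events[[length(events) + 1L]] <- data.frame(
          filament_id = fid, cell_id = cells$cell_id[i],
          interval_id = sprintf("%s_iv%02d", fid, j),
          t_on = t_on, gate_phase = g, cycle_index = k,
          period = period[i], theta = theta[i],
          distance = cells$distance[i], stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(filament_id = character(), cell_id = character(),
               interval_id = character(), t_on = numeric(),
               gate_phase = numeric(), cycle_index = integer(),
               period = numeric(), theta = numeric(), distance = integer(),
               stringsAsFactors = FALSE)
  t_on_of <- stats::setNames(events$t_on, events$cell_id)

  # ---- division schedule ------------------------------------------------
  # live-cell state; divisions replace a row by two daughters
  live <- data.frame(cell_id = cells$cell_id, parent = NA_character_,
                     birth = 0, area0 = area0, theta = theta,
                     period = period, extr = extr, delay_u0 = delay_u0,
                     kind = cells$kind, distance = cells$distance,
                     stringsAsFactors = FALSE)
  live$t_on <- unname(t_on_of[live$cell_id])
  live$next_div <- if (config$division_enabled)
    stats::runif(nrow(live), 0.1, 1) * config$doubling_time_h else Inf
  live$next_div[live$kind == "het" | !is.na(live$t_on)] <- Inf
  divisions <- list()

  frames <- vector("list", length(times))
  growth_rate <- if (config$division_enabled)
    log(2) / config$doubling_time_h else 0

  for (ti in seq_along(times)) {
    t <- times[ti]
    # divisions due at this frame (one at a time: indices shift on insert)
    repeat {
      d <- which(t >= live$next_div & live$kind == "veg" &
                   is.na(live$t_on))[1]
      if (is.na(d)) break
      m <- live[d, ]
      a_m <- m$area0 * exp(growth_rate * (t - m$birth))
      g_tot <- (osc$baseline + osc$amplitude_veg) * m$extr * a_m
      nq <- max(100, round(g_tot))
      q <- stats::rbinom(1, nq, 0.5) / nq
      d1 <- d2 <- m
      d1$cell_id <- paste0(m$cell_id, ".1")
      d2$cell_id <- paste0(m$cell_id, ".2")
      d1$parent <- d2$parent <- m$cell_id
      d1$birth <- d2$birth <- t
      d1$area0 <- a_m / 2; d2$area0 <- a_m / 2
      d1$extr <- m$extr * 2 * q; d2$extr <- m$extr * 2 * (1 - q)
      jit <- stats::rlnorm(2, 0, 0.05)
      d1$next_div <- t + config$doubling_time_h * jit[1]
      d2$next_div <- t + config$doubling_time_h * jit[2]
      divisions[[length(divisions) + 1L]] <- data.frame(
        filament_id = fid, mother = m$cell_id, daughter1 = d1$cell_id,
        daughter2 = d2$cell_id, time = t, stringsAsFactors = FALSE)
      keep_after <- seq_len(nrow(live)) > d
      live <- rbind(live[seq_len(d - 1L), ], d1, d2, live[keep_after, ])
      rownames(live) <- NULL
    }
    n <- nrow(live)
    u <- (t / live$period + live$theta / (2 * pi)) %% 1
    post_onset <- !is.na(live$t_on) & t >= live$t_on
    is_het <- live$kind == "het" |
      (post_onset & t >= live$t_on + dif$maturation_h)
    ctype <- ifelse(live$kind == "het", "heterocyst",
                    ifelse(!post_onset, "vegetative",
                           ifelse(is_het, "heterocyst", "differentiating")))
    # expression amplitude ramps down to the heterocyst level over ~3 h
    # (prompt transcriptional repression on differentiation; short enough
    # that the transition clears the next minimum's fit window)
    amp_lo <- osc$amplitude_veg / osc$amplitude_het_ratio
    ramp_h <- min(3, dif$maturation_h)
    frac <- ifelse(post_onset, pmin(1, (t - live$t_on) / ramp_h), 0)
    frac[is.na(frac)] <- 0
    amp <- ifelse(live$kind == "het", amp_lo,
                  osc$amplitude_veg - (osc$amplitude_veg - amp_lo) * frac)
    if (osc$waveform == "cosine") {
      w <- -cos(2 * pi * u)
    } else {
      w <- vapply(seq_len(n), function(i)
        waveform_eval(u[i], "rise_hold_decay", live$delay_u0[i]), 0)
    }
    gfp_c <- (osc$baseline + amp * w) * live$extr
    af_c <- rep(dif$af_baseline_veg, n)
    af_c[live$kind == "het"] <- af_floor
    dec <- post_onset
    af_c[dec] <- pmax(af_floor, dif$af_baseline_veg -
                        dif$af_decay_curvature * (t - live$t_on[dec])^2)
    af_c <- af_c * live$extr
    area <- live$area0 * exp(growth_rate * (t - live$birth))
    gfp <- gfp_c * area * lognorm_factor(n, noi$measurement_cv)
    af <- af_c * area * lognorm_factor(n, noi$measurement_cv)
    # parent link recorded only on the first frame a daughter appears
    newborn <- live$birth == t & live$birth > 0
    frames[[ti]] <- data.frame(
      time_h = t, filament_id = fid, cell_id = live$cell_id,
      parent_id = ifelse(newborn, live$parent, NA_character_),
      pos_index = seq_len(n) - 1L, cell_type = ctype,
      gfp = gfp, af = af, area = area, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, frames)

  cells_out <- data.frame(
    filament_id = fid, cell_id = cells$cell_id, kind = cells$kind,
    interval_id = ifelse(cells$kind == "veg",
                         sprintf("%s_iv%02d", fid, cells$interval), NA),
    theta = theta, period = period, extrinsic = extr,
    distance = cells$distance, stringsAsFactors = FALSE)
  intervals_out <- data.frame(
    filament_id = fid,
    interval_id = sprintf("%s_iv%02d", fid, seq_len(n_true_iv)),
    length = lens, phi = phi, stringsAsFactors = FALSE)
  list(records = records, cells = cells_out, intervals = intervals_out,
       events = events,
       divisions = if (length(divisions)) do.call(rbind, divisions) else
         data.frame(filament_id = character(), mother = character(),
                    daughter1 = character(), daughter2 = character(),
                    time = numeric(), stringsAsFactors = FALSE))
}

#' Simulate isolated differentiation events for gating-recovery tests
#'
#' Generates `n_events` independent differentiating cells (GFP oscillator
#' plus flat-then-parabolic autofluorescence) whose true decay onsets are
#' clock-phase gated, without the surrounding filament.
#'
#' @param n_events number of events.
#' @param osc,dif,noi parameter blocks (defaults as in the deprived preset).
#' @param duration_h,dt_h sampling window.
#' @param cycles integer vector of allowed cycle indices for the onset.
#' @param seed RNG seed.
#' @return List with `traces` (list of `times`/`gfp`/`af`) and `truth`
#'   (data frame: `t_on`, `gate_phase`, `cycle_index`, `period`, `theta`).
#' @export
simulate_gating_events <- function(n_events,
                                   osc = oscillator_params(),
                                   dif = differentiation_params(),
                                   noi = noise_params(),
                                   duration_h = 96, dt_h = 0.5,
                                   cycles = 2:4, seed = 1L) {
  with_seed(seed, {
    times <- seq(0, duration_h, by = dt_h)
    af_floor <- 0.05 * dif$af_baseline_veg
    traces <- vector("list", n_events)
    truth <- vector("list", n_events)
    i <- 0L
    while (i < n_events) {
      theta <- stats::runif(1, 0, 2 * pi)
      period <- max(4, stats::rnorm(1, osc$period_mean, osc$period_sd))
      mins <- true_minima(period, theta, duration_h + period)
      k <- if (length(cycles) == 1L) cycles else sample(cycles, 1L)
      if (length(mins) < k + 1L) next
      g <- stats::rnorm(1, dif$gate_center, dif$gate_sd) %% 1
      t_on <- mins[k] + g * period
      if (t_on < 6 || t_on > duration_h - 6) next
      i <- i + 1L
      extr <- lognorm_factor(1, noi$extrinsic_cell_cv)
      u <- cycle_fraction(times, period, theta)
      amp_lo <- osc$amplitude_veg / osc$amplitude_het_ratio
      ramp_h <- min(3, dif$maturation_h)
      frac <- pmin(1, pmax(0, (times - t_on) / ramp_h))
      amp <- osc$amplitude_veg - (osc$amplitude_veg - amp_lo) * frac
      gfp <- (osc$baseline + amp * -cos(2 * pi * u)) * extr *
        lognorm_factor(length(times), noi$measurement_cv)
      af <- pmax(af_floor, ifelse(times < t_on, dif$af_baseline_veg,
                                  dif$af_baseline_veg -
                                    dif$af_decay_curvature *
                                    (times - t_on)^2)) * extr *
        lognorm_factor(length(times), noi$measurement_cv)
      traces[[i]] <- list(cell_id = sprintf("ev%03d", i), times = times,
                          gfp = gfp, af = af)
      truth[[i]] <- data.frame(cell_id = sprintf("ev%03d", i), t_on = t_on,
                               gate_phase = g, cycle_index = k,
                               period = period, theta = theta)
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Read / write a simulation configuration
#'
#' Serializes a [sim_config()] to YAML or JSON (by file extension),
#' mirroring the configuration field names exactly.
#'
#' @param config a [sim_config()].
#' @param path file ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_config` returns a [sim_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- lapply(unclass(config), function(el)
    if (is.list(el)) unclass(el) else el)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), names(formals(sim_config)))
  if (length(bad) > 0L)
    fila_stop("schema", paste("unknown config key(s):",
                              paste(bad, collapse = ", ")))
  x$oscillator <- do.call(oscillator_params, as.list(x$oscillator))
  x$differentiation <- do.call(differentiation_params,
                               as.list(x$differentiation))
  x$noise <- do.call(noise_params, as.list(x$noise))
  do.call(sim_config, x)
}
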