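# Circadian minima detection, period/amplitude estimation, onset-aligned
# averaging and sequential-turnoff quantification.
#
# Minima are located on a lightly smoothed signal and refined by fitting,
# to the raw data in a +/-20%-of-period window, both a single parabola and
# a value-continuous piecewise parabola-then-line; the lower-SSE admissible
# fit supplies the refined time (parabola vertex, or the stitch point of
# the piecewise fit, where the fitted curve attains its minimum).

as_series_input <- function(trace, times, channel) {
  if (inherits(trace, "cell_trace")) list(y = trace[[channel]],
                                          t = trace$times)
  else {
    fila_assert(!is.null(times), "domain", "times required for numeric input")
    list(y = as.numeric(trace), t = as.numeric(times))
  }
}

# parabola fit; returns vertex, sse, curvature (NULL if degenerate)
fit_parabola <- function(t, y) {
  X <- cbind(1, t, t * t)
  f <- stats::lm.fit(X, y)
  b <- f$coefficients
  if (anyNA(b) || b[3] == 0) return(NULL)
  list(vertex = -b[2] / (2 * b[3]), curvature = b[3],
       sse = sum(f$residuals^2))
}

# piecewise parabola (t <= t0) + continuous line (t > t0); admissible only
# when the fitted curve attains its minimum at the stitch (parabola
# decreasing up to t0, line non-decreasing after it)
fit_parabola_line <- function(t, y) {
  n <- length(t)
  best <- NULL
  for (i0 in 3:(n - 2L)) {
    t0 <- t[i0]
    left <- t <= t0 + 1e-9
    s <- ifelse(left, 0, t - t0)
    tc <- ifelse(left, t, t0)
    X <- cbind(1, tc, tc * tc, s)
    f <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(f)) next
    b <- f$coefficients
    if (anyNA(b)) next
    a2 <- b[3]; slope <- b[4]
    if (a2 <= 0 || slope < 0) next
    vertex <- -b[2] / (2 * a2)
    if (vertex < t0 - 1e-9) next         # parabola must fall into the stitch
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(stitch = t0, sse = sse, curvature = a2)
  }
  best
}

#' Detect circadian minima of a fluorescence trace
#'
#' Candidate minima are local minima of a 5-frame moving mean, kept at
#' least half a period apart; each is refined on the raw data within
#' \eqn{\pm 20\%} of the expected period by the lower-SSE of a parabolic
#' fit (refined time = vertex) and a piecewise parabola-plus-line fit
#' (refined time = stitch point).  A refined time falling outside its fit
#' window rejects the candidate.
#'
#' @param trace a `cell_trace`, or a numeric series (then supply `times`).
#' @param times frame times in hours (numeric input only).
#' @param expected_period prior on the period, hours; the trace must span
#'   at least 1.5 periods.
#' @param channel `"gfp"` (default) or `"af"` for `cell_trace` input.
#' @return Data frame of class `minima_estimates` with columns `time`,
#'   `method` (`"parabola"` or `"parabola_linear"`), `sse`, `win_lo`,
#'   `win_hi`; zero rows for a monotone trace.
#' @export
detect_minima <- function(trace, times = NULL, expected_period = 21,
                          channel = "gfp") {
  inp <- as_series_input(trace, times, channel)
  y <- inp$y; t <- inp$t
  n <- length(y)
  fila_assert(n >= 8L, "window", "trace too short")
  span <- t[n] - t[1]
  fila_assert(span >= 1.5 * expected_period, "window",
              "trace must span >= 1.5 expected periods")
  dt <- stats::median(diff(t))
  s <- moving_mean(y, 5L)
  cand <- which(diff(sign(diff(s))) > 0) + 1L   # local minima of smoothed
  empty <- structure(data.frame(time = numeric(), method = character(),
                                sse = numeric(), win_lo = numeric(),
                                win_hi = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("minima_estimates", "data.frame"))
  if (length(cand) == 0L) return(empty)
  # enforce >= half-period separation, keeping the deeper minima
  cand <- cand[order(s[cand])]
  keep <- integer()
  for (i in cand) {
    if (all(abs(t[i] - t[keep]) >= 0.5 * expected_period)) keep <- c(keep, i)
  }
  keep <- sort(keep)

  half <- 0.2 * expected_period
  rows <- list()
  for (i in keep) {
    sel <- which(t >= t[i] - half - 1e-9 & t <= t[i] + half + 1e-9)
    if (length(sel) < 5L) next
    tt <- t[sel]; yy <- y[sel]
    pa <- fit_parabola(tt, yy)
    pa_ok <- !is.null(pa) && pa$curvature > 0 &&
      pa$vertex >= tt[1] - 1e-9 && pa$vertex <= tt[length(tt)] + 1e-9
    pl <- if (length(sel) >= 6L) fit_parabola_line(tt, yy) else NULL
    use_pl <- !is.null(pl) && (!pa_ok || pl$sse < pa$sse)
    if (use_pl) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = pl$stitch, method = "parabola_linear", sse = pl$sse,
        win_lo = tt[1], win_hi = tt[length(tt)], stringsAsFactors = FALSE)
    } else if (pa_ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = pa$vertex, method = "parabola", sse = pa$sse,
        win_lo = tt[1], win_hi = tt[length(tt)], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$time), , drop = FALSE]
  # refinement can merge neighbours: re-enforce the separation rule
  if (nrow(out) > 1L) {
    sep_ok <- c(TRUE, diff(out$time) >= 0.5 * expected_period)
    out <- out[sep_ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("minima_estimates", "data.frame"))
}

#' Estimate the circadian period from minima times
#'
#' Per trace, the period is the mean spacing of consecutive minima; across
#' a cohort the mean and its standard error are taken over traces.
#'
#' @param minima numeric vector of minima times (one trace), or a list of
#'   such vectors (a cohort; traces with fewer than 2 minima are dropped).
#' @return List with `mean`, `se` (hours) and `n` (traces, or spacings for
#'   a single trace).
#' @export
estimate_period <- function(minima) {
  if (is.list(minima) && !is.data.frame(minima)) {
    per <- vapply(minima, function(m) {
      m <- sort(as.numeric(m))
      if (length(m) < 2L) NA_real_ else mean(diff(m))
    }, 0)
    per <- per[!is.na(per)]
    fila_assert(length(per) >= 1L, "domain",
                "no trace contains >= 2 minima")
    se <- if (length(per) > 1L) stats::sd(per) / sqrt(length(per)) else 0
    list(mean = mean(per), se = se, n = length(per))
  } else {
    m <- sort(as.numeric(minima))
    fila_assert(length(m) >= 2L, "domain", "need >= 2 minima")
    d <- diff(m)
    se <- if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0
    list(mean = mean(d), se = se, n = length(d))
  }
}

#' Consecutive-minima cycle windows
#'
#' @param minima >= 2 minima times, hours.
#' @return Data frame with `t_start`, `t_end`, `cycle_index` (1-based);
#'   zero rows if fewer than 2 minima.
#' @export
cycle_windows <- function(minima) {
  m <- sort(as.numeric(minima))
  if (length(m) < 2L)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      cycle_index = integer()))
  data.frame(t_start = m[-length(m)], t_end = m[-1L],
             cycle_index = seq_len(length(m) - 1L))
}

#' Oscillation amplitude within one cycle window
#'
#' Amplitude is half the peak-to-trough range of the trace inside the
#' window.
#'
#' @param trace a `cell_trace` or numeric series.
#' @param window `c(t_start, t_end)` hours.
#' @param times,channel as in [detect_minima()].
#' @param smooth_frames odd moving-mean window applied before taking the
#'   range (1 = raw trace); smoothing tames the upward bias of the range
#'   statistic on noisy traces.
#' @return Amplitude in intensity units.
#' @export
amplitude <- function(trace, window, times = NULL, channel = "gfp",
                      smooth_frames = 1L) {
  inp <- as_series_input(trace, times, channel)
  y <- if (smooth_frames > 1L) moving_mean(inp$y, smooth_frames) else inp$y
  sel <- inp$t >= window[1] - 1e-9 & inp$t <= window[2] + 1e-9
  fila_assert(any(sel), "window", "window outside trace span")
  yy <- y[sel]
  (max(yy) - min(yy)) / 2
}

#' Vegetative-to-heterocyst amplitude ratio
#'
#' For each trace the amplitude of its first full fitted cycle is taken;
#' the ratio of the vegetative median to the heterocyst median is
#' returned (about 5 under nitrogen deprivation).
#'
#' @param veg_traces,het_traces lists of `cell_trace` objects.
#' @param expected_period hours.
#' @param channel intensity channel.
#' @param smooth_frames passed to [amplitude()].
#' @return List with `ratio`, `amp_veg` and `amp_het` (medians), `n_veg`,
#'   `n_het`.
#' @export
amplitude_ratio <- function(veg_traces, het_traces, expected_period = 21,
                            channel = "gfp", smooth_frames = 1L) {
  fila_assert(length(veg_traces) >= 1L && length(het_traces) >= 1L,
              "domain", "both groups must be non-empty")
  amp_one <- function(tr) {
    mins <- tryCatch(detect_minima(tr, expected_period = expected_period,
                                   channel = channel),
                     error = function(e) NULL)
    if (is.null(mins) || nrow(mins) < 2L) return(NA_real_)
    amplitude(tr, c(mins$time[1], mins$time[2]), channel = channel,
              smooth_frames = smooth_frames)
  }
  av <- vapply(veg_traces, amp_one, 0)
  ah <- vapply(het_traces, amp_one, 0)
  av <- av[!is.na(av)]; ah <- ah[!is.na(ah)]
  fila_assert(length(av) >= 1L && length(ah) >= 1L, "domain",
              "no full cycle found in one of the groups")
  list(ratio = stats::median(av) / stats::median(ah),
       amp_veg = stats::median(av), amp_het = stats::median(ah),
       n_veg = length(av), n_het = length(ah))
}

#' Align traces on per-trace event times and average
#'
#' Shifts each trace so its event (e.g. the autofluorescence-decay onset of
#' the cell it descends from) sits at relative time 0, then averages over
#' the traces present at each relative frame.  Shifts are snapped to the
#' frame grid.
#'
#' @param traces list of `cell_trace` objects (or lists with `times` and
#'   the channel series).
#' @param event_times one event time per trace, hours.
#' @param channel intensity channel.
#' @return List with `rel_times`, `mat` (traces in columns, `NA` where a
#'   trace is absent), and `mean`.
#' @export
align_by_event <- function(traces, event_times, channel = "gfp") {
  fila_assert(length(traces) == length(event_times), "domain",
              "one event time per trace required")
  dt <- stats::median(diff(traces[[1]]$times))
  shifts <- snap_to_grid(event_times, dt)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (event_times[i] < min(tr$times) - 1e-9 ||
        event_times[i] > max(tr$times) + 1e-9)
      fila_stop("window", "event time outside trace span")
  }
  rel <- lapply(seq_along(traces), function(i)
    round((traces[[i]]$times - shifts[i]) / dt))
  lo <- min(vapply(rel, min, 0)); hi <- max(vapply(rel, max, 0))
  grid <- seq(lo, hi)
  mat <- vapply(seq_along(traces), function(i) {
    v <- rep(NA_real_, length(grid))
    v[match(rel[[i]], grid)] <- traces[[i]][[channel]]
    v
  }, numeric(length(grid)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(traces))
  list(rel_times = grid * dt, mat = mat,
       mean = rowMeans(mat, na.rm = TRUE))
}

#' Detect the expression-turnoff time of one cell in one cycle
#'
#' Within the cycle window the trace rises, holds, then decays; the
#' turnoff time is the stitching point of a constant-then-parabola fit
#' applied from the peak plateau onward (the same changepoint machinery as
#' the autofluorescence-onset fit).
#'
#' @param trace a `cell_trace` (GFP channel) or numeric series.
#' @param window a cycle window `c(t_start, t_end)`, hours.
#' @param times numeric-input frame times.
#' @param cycle_index optional cycle label carried into the record.
#' @return List of class `turnoff_record`: `cell_id`, `cycle_index`,
#'   `turnoff_time`, `distance_to_heterocyst`, `sse`.
#' @export
detect_turnoff <- function(trace, window, times = NULL, cycle_index = NA) {
  inp <- as_series_input(trace, times, "gfp")
  sel <- which(inp$t >= window[1] - 1e-9 & inp$t <= window[2] + 1e-9)
  fila_assert(length(sel) >= 8L, "window", "cycle window too short")
  tt <- inp$t[sel]; yy <- inp$y[sel]
  s <- moving_mean(yy, 5L)
  # start at the smoothed argmax: inside the peak plateau, past the rise
  # (a threshold crossing would land on the smoothed rise-to-hold corner
  # and contaminate the pre-stitch constant segment)
  peak <- which.max(s)
  seg <- peak:length(tt)
  if (length(seg) < 6L)
    fila_stop("no_turnoff", "no decay segment within the window")
  fit <- tryCatch(
    fit_const_parabola(tt[seg], yy[seg], min_pre = 2L, min_post = 3L),
    filaclock_error = function(e)
      fila_stop("no_turnoff", "no decay detected within the window"))
  structure(list(cell_id = if (inherits(trace, "cell_trace"))
                   trace$cell_id else NA_character_,
                 cycle_index = cycle_index,
                 turnoff_time = fit$t_on,
                 distance_to_heterocyst = if (inherits(trace, "cell_trace"))
                   trace$distance[1] else NA_integer_,
                 sse = fit$sse),
            class = "turnoff_record")
}

#' Turnoff-delay gradient along an interval
#'
#' Least-squares slope of turnoff time against distance to the nearest
#' bounding heterocyst (hours per cell); positive when cells farther from
#' the heterocysts turn off later.  Records from a single interval and
#' cycle are regressed directly; when records carry `interval_id` /
#' `cycle_index` labels spanning several groups, both variables are
#' centered within group first (a pooled within-group regression), since
#' absolute turnoff times of dephased intervals are not comparable.
#'
#' @param records list of `turnoff_record`s, or a data frame with columns
#'   `turnoff_time` and `distance_to_heterocyst` (optionally
#'   `interval_id`, `cycle_index`).
#' @return List with `slope` (h/cell), `intercept` (mean turnoff time at
#'   distance 0 for a single group, `NA` for the pooled fit), `n`.
#' @export
turnoff_gradient <- function(records) {
  if (!is.data.frame(records))
    records <- do.call(rbind, lapply(records, function(r)
      data.frame(turnoff_time = r$turnoff_time,
                 distance_to_heterocyst = r$distance_to_heterocyst,
                 cycle_index = r$cycle_index)))
  records <- records[!is.na(records$distance_to_heterocyst), , drop = FALSE]
  fila_assert(nrow(records) >= 2L &&
                length(unique(records$distance_to_heterocyst)) >= 2L,
              "degenerate",
              "need >= 2 records at >= 2 distinct distances")
  grp <- interaction(
    if (!is.null(records$interval_id)) records$interval_id else "iv",
    if (!is.null(records$cycle_index)) records$cycle_index else 1L,
    drop = TRUE)
  if (nlevels(grp) > 1L) {
    y <- records$turnoff_time -
      stats::ave(records$turnoff_time, grp, FUN = mean)
    x <- records$distance_to_heterocyst -
      stats::ave(as.numeric(records$distance_to_heterocyst), grp,
                 FUN = mean)
    fila_assert(stats::sd(x) > 0, "degenerate",
                "no within-group distance variation")
    list(slope = sum(x * y) / sum(x * x), intercept = NA_real_,
         n = nrow(records))
  } else {
    f <- stats::lm(turnoff_time ~ distance_to_heterocyst, data = records)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]), n = nrow(records))
  }
}

#' Turnoff records for the member cells of one interval
#'
#' Convenience wrapper: cycle windows are taken from fitted minima of the
#' interval's mean trace; each member trace contributes one turnoff record
#' per cycle where a decay is detected.
#'
#' @param traces lineage-resolved traces (named by root cell id).
#' @param interval a `veg_interval`.
#' @param expected_period hours.
#' @return Data frame: `cell_id`, `cycle_index`, `turnoff_time`,
#'   `distance_to_heterocyst`.
#' @export
interval_turnoffs <- function(traces, interval, expected_period = 21) {
  grp <- traces[interval$cell_ids]
  grp <- grp[!vapply(grp, is.null, TRUE)]
  fila_assert(length(grp) >= 2L, "domain", "interval has < 2 traces")
  tm <- trace_matrix(grp, "gfp")
  mins <- detect_minima(rowMeans(tm$Y), tm$times, expected_period)
  cw <- cycle_windows(mins$time)
  rows <- list()
  for (k in seq_len(nrow(cw))) {
    for (tr in grp) {
      rec <- tryCatch(detect_turnoff(tr, c(cw$t_start[k], cw$t_end[k]),
                                     cycle_index = cw$cycle_index[k]),
                      filaclock_error = function(e) NULL)
      if (!is.null(rec))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = rec$cell_id, interval_id = interval$interval_id,
          cycle_index = rec$cycle_index,
          turnoff_time = rec$turnoff_time,
          distance_to_heterocyst = rec$distance_to_heterocyst,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cell_id = character(), interval_id = character(),
                      cycle_index = integer(), turnoff_time = numeric(),
                      distance_to_heterocyst = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
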