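# Synchronization index R, expression noise (CV^2), and the neighbour /
# cross-interval Pearson correlation structure.
#
# R is the ratio of the variance over time of the group-mean trace mu(t) to
# the per-cell temporal variances averaged over cells, evaluated over one
# full period of oscillation.  R = 1 for identical traces; for n cells with
# independent phases E[R] ~ 1/n.

#' Synchronization index R of a group of traces
#'
#' \deqn{R = \frac{\langle\mu^2\rangle - \langle\mu\rangle^2}
#'            {\overline{\langle f_i^2\rangle - \langle f_i\rangle^2}}}
#' where \eqn{\langle\cdot\rangle} is a time average over the window,
#' \eqn{\mu(t)} the across-cell mean trace, and the overline an average
#' over cells.  The same sample-variance estimator (denominator
#' \eqn{n - 1}) is used in numerator and denominator, so \eqn{0 \le R \le 1}.
#'
#' @param traces list of `cell_trace` objects (see [resolve_lineages()]),
#'   or a numeric matrix with one column per cell and one row per frame.
#' @param window `c(t_start, t_end)` in hours delimiting one full
#'   oscillation period; `NULL` uses the full shared span.
#' @param channel `"gfp"` or `"af"` (list input only).
#' @return Object of class `sync_result`: `R`, `var_of_mean`,
#'   `mean_of_var`, `n_cells`, `window`.
#' @export
sync_index <- function(traces, window = NULL, channel = "gfp") {
  if (is.matrix(traces)) {
    Y <- traces
    win <- if (is.null(window)) c(NA_real_, NA_real_) else window
  } else {
    tm <- trace_matrix(traces, channel = channel, window = window)
    Y <- tm$Y
    win <- range(tm$times)
  }
  fila_assert(ncol(Y) >= 2L, "alignment", "need at least 2 traces")
  fila_assert(nrow(Y) >= 4L, "alignment", "window must contain >= 4 frames")
  v <- apply(Y, 2L, stats::var)
  if (any(v <= 0))
    fila_stop("zero_variance", "constant trace in window")
  mu <- rowMeans(Y)
  vm <- stats::var(mu)
  R <- vm / mean(v)
  structure(list(R = R, var_of_mean = vm, mean_of_var = mean(v),
                 n_cells = ncol(Y), window = win),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> R = %.4f  (var of mean %.4g / mean cell var %.4g)\n",
    x$R, x$var_of_mean, x$mean_of_var))
  cat(sprintf("  n_cells = %d, window = [%g, %g] h\n", x$n_cells,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Expression noise: squared coefficient of variation
#'
#' Cell-to-cell variability of intensities at one frame, defined as the
#' squared coefficient of variation (variance over squared mean).
#'
#' @param values intensities of >= 2 cells at one time point.
#' @return CV^2, dimensionless.
#' @export
expression_noise <- function(values) {
  fila_assert(length(values) >= 2L, "domain", "need >= 2 values")
  m <- mean(values)
  if (m <= 0) fila_stop("domain", "mean intensity must be > 0")
  stats::var(values) / m^2
}

frame_values <- function(series, cell_ids, time, channel = "gfp",
                         concentration = TRUE) {
  fr <- series[near(series$time_h, time), , drop = FALSE]
  idx <- match(cell_ids, fr$cell_id)
  fila_assert(!anyNA(idx), "alignment",
              "some cells absent at the requested frame")
  v <- fr[[channel]][idx]
  if (concentration) v <- v / fr$area[idx]
  v
}

#' Intensity pairs of nearest-neighbour cells within a vegetative interval
#'
#' @param interval a `veg_interval` from [intervals_at()].
#' @param series the [filament_series()].
#' @param time frame time in hours.
#' @param channel,concentration intensity channel and whether to divide by
#'   cell area.
#' @return Object of class `pair_set` with numeric `x`, `y`,
#'   `pairing_kind`, and `sample_time`; an interval of one cell yields an
#'   empty pair set.
#' @export
neighbor_pairs <- function(interval, series, time, channel = "gfp",
                           concentration = TRUE) {
  v <- frame_values(series, interval$cell_ids, time, channel, concentration)
  n <- length(v)
  structure(list(x = if (n > 1L) v[-n] else numeric(),
                 y = if (n > 1L) v[-1L] else numeric(),
                 pairing_kind = "nearest_neighbor", sample_time = time),
            class = "pair_set")
}

#' Intensity pairs of corresponding cells in adjacent vegetative intervals
#'
#' Cells are paired by index counted from the shared bounding heterocyst,
#' truncated to the shorter interval.
#'
#' @param interval_a,interval_b `veg_interval`s sharing a bounding
#'   heterocyst.
#' @inheritParams neighbor_pairs
#' @return A `pair_set` with `pairing_kind = "adjacent_interval"`.
#' @export
interval_pairs <- function(interval_a, interval_b, series, time,
                           channel = "gfp", concentration = TRUE) {
  va <- frame_values(series, interval_a$cell_ids, time, channel,
                     concentration)
  vb <- frame_values(series, interval_b$cell_ids, time, channel,
                     concentration)
  shared_ab <- !is.na(interval_a$bounding["right"]) &&
    identical(unname(interval_a$bounding["right"]),
              unname(interval_b$bounding["left"]))
  shared_ba <- !is.na(interval_b$bounding["right"]) &&
    identical(unname(interval_b$bounding["right"]),
              unname(interval_a$bounding["left"]))
  if (shared_ab) {            # A left of B: count A from its right end
    va <- rev(va)
  } else if (shared_ba) {     # B left of A
    vb <- rev(vb)
  } else {
    fila_stop("alignment", "intervals do not share a bounding heterocyst")
  }
  k <- min(length(va), length(vb))
  structure(list(x = va[seq_len(k)], y = vb[seq_len(k)],
                 pairing_kind = "adjacent_interval", sample_time = time),
            class = "pair_set")
}

#' Pearson correlation of a pair set
#'
#' @param pairs a `pair_set` (or any list with numeric `x` and `y`).
#' @return Product-moment correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson <- function(pairs) {
  x <- pairs$x; y <- pairs$y
  fila_assert(length(x) >= 3L, "degenerate", "need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fila_stop("degenerate", "zero variance in x or y")
  stats::cor(x, y)
}

#' Sampling times at one- and three-quarters of each circadian cycle
#'
#' Expression fluctuations across cells are maximal near the quarter
#' phases of the cycle; this picks, for each pair of consecutive minima,
#' the times at cycle fractions 1/4 and 3/4, snapped to the frame grid.
#'
#' @param minima >= 2 minima times, hours.
#' @param dt frame step for snapping, hours.
#' @return Sorted numeric vector of sample times.
#' @export
pick_quarter_times <- function(minima, dt = 0.5) {
  fila_assert(length(minima) >= 2L, "domain", "need >= 2 minima")
  minima <- sort(minima)
  out <- unlist(lapply(seq_len(length(minima) - 1L), function(k) {
    t0 <- minima[k]; t1 <- minima[k + 1L]
    t0 + c(0.25, 0.75) * (t1 - t0)
  }))
  sort(snap_to_grid(out, dt))
}

# ---- group construction (contiguous vs separated cells) -----------------

# central contiguous run of size_max (or the whole interval if shorter)
central_members <- function(cell_ids, size_max = 11L) {
  n <- length(cell_ids)
  if (n <= size_max) return(cell_ids)
  start <- (n - size_max) %/% 2L + 1L
  cell_ids[start:(start + size_max - 1L)]
}

# centre cell of an interval; ties broken toward the left heterocyst
center_member <- function(cell_ids) cell_ids[(length(cell_ids) + 1L) %/% 2L]

#' Synchronization contrast between contiguous and separated cell groups
#'
#' Reproduces the group protocol of the synchrony analysis: the index R is
#' evaluated over (a) groups of 8--11 contiguous vegetative cells within
#' single intervals and (b) one group of single cells taken from the
#' centres of different vegetative intervals.  Each contiguous group's
#' full-period window is delimited by two consecutive fitted minima of the
#' group-mean trace; the separated group uses one common window (the
#' median of the contiguous-group windows).
#'
#' @param series a [filament_series()].
#' @param expected_period prior on the oscillation period, hours.
#' @param division_policy passed to [resolve_lineages()].
#' @param min_size,max_size contiguous group size limits (default 8--11).
#' @return List with `within` (mean R over contiguous groups), `across`
#'   (R of the separated group), `gap`, and the per-group `sync_result`s.
#' @export
synchrony_contrast <- function(series, expected_period = 21,
                               division_policy = "concentration",
                               min_size = 8L, max_size = 11L) {
  traces <- resolve_lineages(series, division_policy)
  ivs <- intervals_at(series, min(series$time_h))
  bounded <- Filter(function(v) v$bounded, ivs)
  if (length(bounded) == 0L) bounded <- ivs
  usable <- Filter(function(v) length(v$cell_ids) >= min_size, bounded)
  fila_assert(length(usable) >= 2L, "domain",
              "need >= 2 intervals of at least min_size cells")

  within_res <- list()
  windows <- list()
  for (v in usable) {
    ids <- central_members(v$cell_ids, max_size)
    grp <- traces[ids]
    grp <- grp[!vapply(grp, is.null, TRUE)]
    if (length(grp) < min_size) next
    tm <- trace_matrix(grp, "gfp")
    mu <- rowMeans(tm$Y)
    mins <- tryCatch(detect_minima(mu, tm$times, expected_period),
                     error = function(e) NULL)
    if (is.null(mins) || length(mins$time) < 2L) next
    win <- c(mins$time[1], mins$time[2])
    res <- tryCatch(sync_index(grp, window = win),
                    error = function(e) NULL)
    if (is.null(res)) next
    within_res[[length(within_res) + 1L]] <- res
    windows[[length(windows) + 1L]] <- win
  }
  fila_assert(length(within_res) >= 1L, "domain",
              "no contiguous group produced a valid cycle window")

  centers <- vapply(usable, function(v) center_member(v$cell_ids), "")
  centers <- centers[seq_len(min(length(centers), max_size))]
  wmat <- do.call(rbind, windows)
  common <- c(stats::median(wmat[, 1]), stats::median(wmat[, 2]))
  dth <- attr(series, "dt")
  common <- snap_to_grid(common, dth)
  across_res <- sync_index(traces[centers], window = common)

  within <- mean(vapply(within_res, function(r) r$R, 0))
  list(within = within, across = across_res$R,
       gap = within - across_res$R,
       within_groups = within_res, across_group = across_res)
}
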