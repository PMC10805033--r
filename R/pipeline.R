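# Pipeline orchestration: simulate-to-files, full trace analysis into a
# machine-readable report, and ground-truth recovery tables.
# Progress is logged to stderr; results never are.

stage_msg <- function(...) message("[filaclock] ", ...)

#' Simulate a cohort and write traces plus ground truth to a directory
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written: the traces
#'   CSV, ground-truth CSVs (cells, intervals, events, divisions) and the
#'   resolved configuration JSON.
#' @export
simulate_to_files <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- c(traces = file.path(out_dir, "traces.csv"),
             cells = file.path(out_dir, "truth_cells.csv"),
             intervals = file.path(out_dir, "truth_intervals.csv"),
             events = file.path(out_dir, "truth_events.csv"),
             divisions = file.path(out_dir, "truth_divisions.csv"),
             config = file.path(out_dir, "config.json"))
  write_traces(sim$series, paths["traces"])
  utils::write.csv(sim$truth$cells, paths["cells"], row.names = FALSE)
  utils::write.csv(sim$truth$intervals, paths["intervals"],
                   row.names = FALSE)
  utils::write.csv(sim$truth$events, paths["events"], row.names = FALSE)
  utils::write.csv(sim$truth$divisions, paths["divisions"],
                   row.names = FALSE)
  write_config(config, paths["config"])
  stage_msg("simulated ", nrow(sim$series), " records (seed ",
            config$seed, ") -> ", out_dir)
  invisible(paths)
}

last_type <- function(tr) tr$cell_type[length(tr$cell_type)]

#' Analyze a traces file or filament series
#'
#' Runs the full pipeline in order: interval resolution, lineage splicing,
#' circadian minima and periods, synchronization contrast (contiguous vs
#' separated cell groups), expression noise and neighbour/cross-interval
#' Pearson correlations at quarter-cycle times, vegetative/heterocyst
#' amplitude ratio, autofluorescence-onset gating phases with bootstrap
#' histogram, and the turnoff-delay gradient.
#'
#' @param traces a [filament_series()] or the path of a traces CSV.
#' @param division_policy passed to [resolve_lineages()].
#' @param expected_period prior on the circadian period, hours.
#' @param n_bins,n_boot,seed histogram and bootstrap settings.
#' @param cycles admissible event cycle indices (`NULL` = all).
#' @return Object of class `analysis_report` (nested list; see
#'   [write_report()]).
#' @export
analyze_traces <- function(traces, division_policy = "concentration",
                           expected_period = 21, n_bins = 10L,
                           n_boot = 1000L, seed = 1L, cycles = 2:4) {
  series <- if (is.character(traces)) read_traces(traces) else traces
  stopifnot(inherits(series, "filament_series"))
  dt <- attr(series, "dt")
  t0 <- min(series$time_h)
  ivs <- intervals_at(series, t0)
  bounded <- Filter(function(v) v$bounded, ivs)
  stage_msg("intervals: ", length(ivs), " (", length(bounded), " bounded)")
  trs <- resolve_lineages(series, division_policy)
  stage_msg("lineages: ", length(trs), " traces")

  # --- oscillation section ------------------------------------------------
  veg <- trs[vapply(trs, function(tr) tr$cell_type[1] != "heterocyst" &&
                      last_type(tr) == "vegetative", TRUE)]
  het0 <- trs[vapply(trs, function(tr) tr$cell_type[1] == "heterocyst",
                     TRUE)]
  minima_of <- function(tr) tryCatch(
    detect_minima(tr, expected_period = expected_period)$time,
    filaclock_error = function(e) numeric())
  veg_minima <- lapply(veg, minima_of)
  het_minima <- lapply(het0, minima_of)
  per_veg <- tryCatch(estimate_period(veg_minima),
                      filaclock_error = function(e) NULL)
  per_het <- tryCatch(estimate_period(het_minima),
                      filaclock_error = function(e) NULL)
  amp <- tryCatch(amplitude_ratio(veg, het0, expected_period,
                                  smooth_frames = 5L),
                  filaclock_error = function(e) NULL)
  stage_msg("periods: veg n=", if (is.null(per_veg)) 0 else per_veg$n,
            ", het n=", if (is.null(per_het)) 0 else per_het$n)

  # --- synchrony section --------------------------------------------------
  contrast <- tryCatch(synchrony_contrast(series, expected_period,
                                          division_policy),
                       filaclock_error = function(e) NULL)
  noise_int <- numeric(); noise_fil <- numeric()
  np_all <- list(x = numeric(), y = numeric())
  ip_all <- list(x = numeric(), y = numeric())
  use_iv <- if (length(bounded) > 0L) bounded else ivs
  # quarter-cycle sampling times are common to the whole cohort (the
  # reference cycle is the median of the per-interval fitted cycles), so
  # dephased intervals are caught at different expression levels
  iv_minima <- lapply(use_iv, function(v) {
    grp <- trs[v$cell_ids]
    grp <- grp[!vapply(grp, is.null, TRUE)]
    if (length(grp) < 2L) return(NULL)
    tm <- tryCatch(trace_matrix(grp, "gfp"),
                   filaclock_error = function(e) NULL)
    if (is.null(tm)) return(NULL)
    mins <- tryCatch(detect_minima(rowMeans(tm$Y), tm$times,
                                   expected_period),
                     filaclock_error = function(e) NULL)
    if (is.null(mins) || nrow(mins) < 2L) NULL else mins$time
  })
  ok_iv <- !vapply(iv_minima, is.null, TRUE)
  qt <- if (any(ok_iv)) {
    m1 <- stats::median(vapply(iv_minima[ok_iv], `[`, 0, 1))
    per <- stats::median(vapply(iv_minima[ok_iv],
                                function(m) mean(diff(m)), 0))
    tmax <- max(series$time_h)
    cyc_starts <- seq(m1, tmax - per, by = per)
    snap_to_grid(as.vector(outer(c(0.25, 0.75) * per, cyc_starts, "+")),
                 dt)
  } else numeric()
  for (v in use_iv[ok_iv]) {
    for (tq in qt) {
      vals <- tryCatch(frame_values(series, v$cell_ids, tq),
                       filaclock_error = function(e) NULL)
      if (is.null(vals) || length(vals) < 2L) next
      noise_int <- c(noise_int, expression_noise(vals))
      np <- neighbor_pairs(v, series, tq)
      np_all$x <- c(np_all$x, np$x); np_all$y <- c(np_all$y, np$y)
      # all vegetative cells of the filament at the same frame
      fil_ivs <- Filter(function(w) w$filament_id == v$filament_id, use_iv)
      fil_cells <- unlist(lapply(fil_ivs, `[[`, "cell_ids"))
      fvals <- tryCatch(frame_values(series, fil_cells, tq),
                        filaclock_error = function(e) NULL)
      if (!is.null(fvals) && length(fvals) >= 2L)
        noise_fil <- c(noise_fil, expression_noise(fvals))
      # adjacent interval sharing the right bounding heterocyst
      nb <- Filter(function(w)
        identical(unname(w$bounding["left"]), unname(v$bounding["right"])) &&
          w$filament_id == v$filament_id, use_iv)
      if (length(nb) == 1L && !is.na(v$bounding["right"])) {
        ip <- tryCatch(interval_pairs(v, nb[[1]], series, tq),
                       filaclock_error = function(e) NULL)
        if (!is.null(ip)) {
          ip_all$x <- c(ip_all$x, ip$x); ip_all$y <- c(ip_all$y, ip$y)
        }
      }
    }
  }
  p_nn <- tryCatch(pearson(np_all), filaclock_error = function(e) NULL)
  p_iv <- tryCatch(pearson(ip_all), filaclock_error = function(e) NULL)
  stage_msg("synchrony: ", length(noise_int), " interval noise frames, ",
            length(np_all$x), " neighbour pairs, ",
            length(ip_all$x), " cross-interval pairs")

  # --- gating section -----------------------------------------------------
  ev_traces <- trs[vapply(trs, function(tr)
    tr$cell_type[1] != "heterocyst" &&
      any(tr$cell_type == "differentiating"), TRUE)]
  ph <- event_phases(ev_traces, expected_period, cycles)
  hist_obj <- if (nrow(ph) >= 5L)
    phase_histogram(ph$phase, n_bins, n_boot, seed) else NULL
  circ <- if (nrow(ph) >= 5L) gating_summary(ph$phase) else NULL
  stage_msg("gating: ", length(ev_traces), " differentiating traces, ",
            nrow(ph), " phased events")

  # --- turnoff section ----------------------------------------------------
  to_recs <- list()
  for (v in bounded) {
    r <- tryCatch(interval_turnoffs(trs, v, expected_period),
                  filaclock_error = function(e) NULL)
    if (!is.null(r) && nrow(r) > 0L) to_recs[[length(to_recs) + 1L]] <- r
  }
  to_tab <- if (length(to_recs)) do.call(rbind, to_recs) else NULL
  to_grad <- if (!is.null(to_tab))
    tryCatch(turnoff_gradient(to_tab), filaclock_error = function(e) NULL)
  else NULL

  report <- structure(list(
    provenance = list(package = "filaclock",
                      version = as.character(utils::packageVersion("filaclock")),
                      seed = as.integer(seed),
                      division_policy = division_policy,
                      expected_period = expected_period,
                      n_records = nrow(series)),
    synchrony = list(
      within_interval_R = if (is.null(contrast)) NULL else contrast$within,
      across_interval_R = if (is.null(contrast)) NULL else contrast$across,
      R_gap = if (is.null(contrast)) NULL else contrast$gap,
      n_within_groups = if (is.null(contrast)) 0L else
        length(contrast$within_groups),
      noise_cv2_interval = if (length(noise_int)) mean(noise_int) else NULL,
      noise_cv2_filament = if (length(noise_fil)) mean(noise_fil) else NULL,
      pearson_neighbor = p_nn,
      pearson_cross_interval = p_iv,
      n_neighbor_pairs = length(np_all$x),
      n_cross_pairs = length(ip_all$x)),
    oscillation = list(
      period_veg_h = if (is.null(per_veg)) NULL else per_veg$mean,
      period_veg_se = if (is.null(per_veg)) NULL else per_veg$se,
      n_veg_traces = if (is.null(per_veg)) 0L else per_veg$n,
      period_het_h = if (is.null(per_het)) NULL else per_het$mean,
      period_het_se = if (is.null(per_het)) NULL else per_het$se,
      n_het_traces = if (is.null(per_het)) 0L else per_het$n,
      amplitude_ratio = if (is.null(amp)) NULL else amp$ratio,
      turnoff_slope_h_per_cell = if (is.null(to_grad)) NULL else
        to_grad$slope,
      n_turnoff_records = if (is.null(to_tab)) 0L else nrow(to_tab)),
    gating = list(
      n_events = nrow(ph),
      events = ph,
      histogram = if (is.null(hist_obj)) NULL else unclass(hist_obj),
      circular_mean = if (is.null(circ)) NULL else circ$mean,
      resultant_length = if (is.null(circ)) NULL else circ$resultant)),
    class = "analysis_report")
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  s <- x$synchrony; o <- x$oscillation; g <- x$gating
  if (!is.null(s$within_interval_R))
    cat(sprintf("  R within intervals %.3f | across %.3f (gap %.3f)\n",
                s$within_interval_R, s$across_interval_R, s$R_gap))
  if (!is.null(s$noise_cv2_interval))
    cat(sprintf("  noise CV^2: interval %.3f | filament %s\n",
                s$noise_cv2_interval,
                if (is.null(s$noise_cv2_filament)) "-" else
                  sprintf("%.3f", s$noise_cv2_filament)))
  if (!is.null(s$pearson_neighbor))
    cat(sprintf("  Pearson: neighbours %.3f | cross-interval %s\n",
                s$pearson_neighbor,
                if (is.null(s$pearson_cross_interval)) "-" else
                  sprintf("%.3f", s$pearson_cross_interval)))
  if (!is.null(o$period_veg_h))
    cat(sprintf("  period: veg %.2f +/- %.2f h (n=%d)", o$period_veg_h,
                o$period_veg_se, o$n_veg_traces))
  if (!is.null(o$period_het_h))
    cat(sprintf(" | het %.2f +/- %.2f h (n=%d)", o$period_het_h,
                o$period_het_se, o$n_het_traces))
  if (!is.null(o$period_veg_h)) cat("\n")
  if (!is.null(o$amplitude_ratio))
    cat(sprintf("  amplitude ratio veg/het: %.2f\n", o$amplitude_ratio))
  if (!is.null(o$turnoff_slope_h_per_cell))
    cat(sprintf("  turnoff gradient: %.3f h/cell (%d records)\n",
                o$turnoff_slope_h_per_cell, o$n_turnoff_records))
  cat(sprintf("  gating: %d events", g$n_events))
  if (!is.null(g$circular_mean))
    cat(sprintf(", circular mean %.3f, resultant %.3f",
                g$circular_mean, g$resultant_length))
  cat("\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Keys keep their construction order and floating-point values are
#' serialized at 12 significant digits, so identical analyses produce
#' byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(12), pretty = TRUE, null = "null")
  invisible(path)
}

#' Ground-truth recovery table for a simulated configuration
#'
#' Simulates a cohort, analyses it blind to the truth, and tabulates true
#' versus estimated quantities: cohort period, per-event onset times and
#' gate phases (with error quantiles), and the turnoff gradient where the
#' waveform defines one.
#'
#' @param config a [sim_config()].
#' @param ... passed to [analyze_traces()].
#' @return List with `table` (quantity, true, estimated, n), `onset_errors`
#'   and `phase_errors` (named quantile vectors, `NULL` without events).
#' @export
recover_cohort <- function(config, ...) {
  sim <- simulate_cohort(config)
  rep <- analyze_traces(sim$series,
                        expected_period = config$oscillator$period_mean, ...)
  ev <- sim$truth$events
  rows <- list(data.frame(
    quantity = "period_veg_h", true = config$oscillator$period_mean,
    estimated = null_na(rep$oscillation$period_veg_h),
    n = rep$oscillation$n_veg_traces))
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "amplitude_ratio",
    true = config$oscillator$amplitude_het_ratio,
    estimated = null_na(rep$oscillation$amplitude_ratio), n = NA)
  onset_err <- NULL; phase_err <- NULL
  if (!is.null(ev) && nrow(ev) > 0L && nrow(rep$gating$events) > 0L) {
    est <- rep$gating$events
    m <- merge(ev, est, by = "cell_id", suffixes = c("_true", "_est"))
    if (nrow(m) > 0L) {
      onset_err <- stats::quantile(abs(m$t_on_est - m$t_on_true),
                                   c(0.5, 0.95))
      dphase <- abs(m$phase - m$gate_phase)
      dphase <- pmin(dphase, 1 - dphase)   # wrapped
      phase_err <- stats::quantile(dphase, c(0.5, 0.95))
    }
    if (nrow(est) >= 5L)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = "gate_phase_circmean",
        true = config$differentiation$gate_center,
        estimated = gating_summary(est$phase)$mean, n = nrow(est))
  }
  if (config$oscillator$waveform == "rise_hold_decay")
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "turnoff_slope_h_per_cell",
      true = config$oscillator$turnoff_delay_per_cell,
      estimated = null_na(rep$oscillation$turnoff_slope_h_per_cell),
      n = rep$oscillation$n_turnoff_records)
  list(table = do.call(rbind, rows), onset_errors = onset_err,
       phase_errors = phase_err, report = rep)
}

null_na <- function(x) if (is.null(x)) NA_real_ else x
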