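# Data model for filament time-lapse traces: long-format per-cell records,
# CSV I/O, vegetative-interval resolution and lineage splicing.

TRACE_COLUMNS <- c("time_h", "filament_id", "cell_id", "parent_id",
                   "pos_index", "cell_type", "gfp", "af", "area")
CELL_TYPES <- c("vegetative", "differentiating", "heterocyst")

#' Construct a filament series from a long-format data frame
#'
#' A filament series is one data frame with one row per cell per frame and
#' columns `time_h`, `filament_id`, `cell_id`, `parent_id`, `pos_index`,
#' `cell_type`, `gfp`, `af`, `area`.  `pos_index` is 0-based, left-to-right,
#' and re-assigned per frame; lineage (`cell_id`/`parent_id`), not position,
#' is the stable key.  Times are hours on a constant sampling grid
#' (default acquisition step 0.5 h).
#'
#' @param df data frame with the columns above.
#' @param validate check invariants (contiguous `pos_index` runs, unique
#'   cell per frame, constant time step, monotone cell-type transitions).
#' @return A `filament_series` (a data frame), with attribute `dt` holding
#'   the inferred sampling step in hours.
#' @export
filament_series <- function(df, validate = TRUE) {
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    fila_stop("schema", paste("missing column(s):",
                              paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)[, TRACE_COLUMNS]
  df$filament_id <- as.character(df$filament_id)
  df$cell_id <- as.character(df$cell_id)
  df$parent_id <- as.character(df$parent_id)
  df$parent_id[!is.na(df$parent_id) & df$parent_id == ""] <- NA_character_
  df$pos_index <- as.integer(df$pos_index)
  df$cell_type <- as.character(df$cell_type)
  df <- df[order(df$filament_id, df$time_h, df$pos_index), , drop = FALSE]
  rownames(df) <- NULL
  dt <- infer_dt(df$time_h)
  if (validate) validate_series(df, dt)
  structure(df, dt = dt, class = c("filament_series", "data.frame"))
}

infer_dt <- function(times) {
  ut <- sort(unique(times))
  if (length(ut) < 2L) return(NA_real_)
  steps <- diff(ut)
  dt <- min(steps)
  if (any(abs(steps / dt - round(steps / dt)) > 1e-6) || dt <= 0)
    fila_stop("sampling", "time points do not lie on a constant sampling grid")
  dt
}

validate_series <- function(df, dt = infer_dt(df$time_h)) {
  if (any(df$time_h < 0))
    fila_stop("schema", "negative time_h")
  if (!all(df$cell_type %in% CELL_TYPES))
    fila_stop("schema", paste("cell_type outside",
                              paste(CELL_TYPES, collapse = "/")))
  if (any(!is.finite(df$gfp)) || any(df$gfp < 0) ||
      any(!is.finite(df$af)) || any(df$af < 0) || any(df$area <= 0))
    fila_stop("schema", "intensities must be >= 0 and area > 0")
  if (!is.na(dt)) {
    offgrid <- abs(df$time_h / dt - round(df$time_h / dt)) > 1e-6
    if (any(offgrid))
      fila_stop("sampling", "time_h values off the sampling grid")
  }
  key <- paste(df$filament_id, df$cell_id, df$time_h)
  if (anyDuplicated(key))
    fila_stop("integrity", "duplicate (filament_id, cell_id, time_h) records")
  # contiguous 0..n-1 pos_index run per (filament, frame)
  frame_key <- paste(df$filament_id, df$time_h)
  bad <- vapply(split(df$pos_index, frame_key), function(p) {
    !identical(sort(p), seq_along(p) - 1L)
  }, logical(1))
  if (any(bad))
    fila_stop("integrity",
              paste("pos_index not a contiguous 0..n-1 run at frame(s):",
                    paste(utils::head(names(bad)[bad], 3), collapse = "; ")))
  # monotone vegetative -> differentiating -> heterocyst per cell
  rank <- match(df$cell_type, CELL_TYPES)
  ord <- order(df$filament_id, df$cell_id, df$time_h)
  for (idx in split(ord, paste(df$filament_id, df$cell_id)[ord])) {
    if (is.unsorted(rank[idx]))
      fila_stop("integrity",
                paste0("backward cell_type transition in cell ",
                       df$cell_id[idx[1]]))
  }
  invisible(TRUE)
}

#' Read a traces CSV into a filament series
#'
#' The CSV is UTF-8 with a header row and columns exactly
#' `time_h, filament_id, cell_id, parent_id, pos_index, cell_type, gfp, af,
#' area`; an empty `parent_id` field denotes a root cell.
#'
#' @param path file path.
#' @return A [filament_series()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) fila_stop("schema", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(parent_id = "character",
                                       filament_id = "character",
                                       cell_id = "character"))
  filament_series(df)
}

#' Write a filament series to a traces CSV
#'
#' Inverse of [read_traces()]: `read_traces(write_traces(x, p))` reproduces
#' `x` record for record.  `NA` parent ids are serialized as empty fields.
#'
#' @param series a [filament_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(series, path) {
  df <- as.data.frame(series)[, TRACE_COLUMNS]
  df$parent_id[is.na(df$parent_id)] <- ""
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fila_stop("schema", paste("cannot write:", path))
  invisible(path)
}

#' Vegetative intervals of every filament at one frame
#'
#' Partitions the non-heterocyst cells of each filament at time `time` into
#' maximal contiguous runs.  A run flanked by heterocysts on both sides is a
#' bounded vegetative interval (the organismic unit under nitrogen
#' deprivation); runs touching a filament end are flagged end-bounded.
#' Differentiating cells count as interval members until they mature.
#'
#' @param series a [filament_series()].
#' @param time a sampled frame time in hours.
#' @return List of `veg_interval` objects, each with `interval_id`,
#'   `filament_id`, `time`, ordered `cell_ids`, `bounding` (left/right
#'   heterocyst id or `NA` at a filament end), `bounded` flag, and
#'   `distance` (cells to the nearest bounding heterocyst, 1 = adjacent;
#'   `NA` in end-bounded runs).
#' @export
intervals_at <- function(series, time) {
  df <- series[near(series$time_h, time), , drop = FALSE]
  if (nrow(df) == 0L)
    fila_stop("sampling", paste("no frame at time", time))
  out <- list()
  for (fid in unique(df$filament_id)) {
    d <- df[df$filament_id == fid, , drop = FALSE]
    d <- d[order(d$pos_index), , drop = FALSE]
    het <- d$cell_type == "heterocyst"
    if (all(het)) next
    r <- rle(het)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_i <- 0L
    for (k in seq_along(r$values)) {
      if (r$values[k]) next
      run_i <- run_i + 1L
      i0 <- starts[k]; i1 <- ends[k]
      left <- if (i0 > 1L) d$cell_id[i0 - 1L] else NA_character_
      right <- if (i1 < nrow(d)) d$cell_id[i1 + 1L] else NA_character_
      len <- i1 - i0 + 1L
      bounded <- !is.na(left) && !is.na(right)
      dist <- if (bounded) pmin(seq_len(len), len + 1L - seq_len(len))
              else rep(NA_integer_, len)
      out[[length(out) + 1L]] <- structure(list(
        interval_id = paste0(fid, ":", ifelse(is.na(left), "END", left),
                             "-", ifelse(is.na(right), "END", right)),
        filament_id = fid, time = time,
        cell_ids = d$cell_id[i0:i1],
        bounding = c(left = left, right = right),
        bounded = bounded, distance = dist), class = "veg_interval")
    }
  }
  out
}

# cell_id -> (interval_id, distance) lookup for one frame
interval_lookup_at <- function(series, time) {
  ivs <- intervals_at(series, time)
  ids <- unlist(lapply(ivs, `[[`, "cell_ids"), use.names = FALSE)
  data.frame(cell_id = ids,
             interval_id = rep(vapply(ivs, `[[`, "", "interval_id"),
                               vapply(ivs, function(v) length(v$cell_ids), 0L)),
             distance = unlist(lapply(ivs, `[[`, "distance"), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Resolve cell lineages into single-cell traces
#'
#' Converts the per-frame records of a filament series into lineage-resolved
#' time series, one per root cell.  Because total per-cell fluorescence
#' halves at division, the default policy `"concentration"` divides
#' intensities by cell area before splicing mother and daughter, so a
#' division causes no jump beyond partitioning/measurement noise.  Policy
#' `"first_daughter"` splices raw totals through the daughter with the
#' smaller position index; `"sum"` totals intensity and area over all living
#' descendants of the root at each frame.
#'
#' @param series a [filament_series()].
#' @param division_policy `"concentration"` (default), `"first_daughter"`,
#'   or `"sum"`.
#' @return Named list of `cell_trace` objects with fields `cell_id` (the
#'   root), `times`, `gfp`, `af`, `area`, `interval_id`, `distance`
#'   (cells to the nearest bounding heterocyst per frame), `cell_type`, and
#'   `member_id` (the cell occupying the trace at each frame).
#' @export
resolve_lineages <- function(series,
                             division_policy = c("concentration",
                                                 "first_daughter", "sum")) {
  division_policy <- match.arg(division_policy)
  df <- as.data.frame(series)
  dt <- attr(series, "dt")
  times <- sort(unique(df$time_h))

  # per-frame (cell -> interval, distance) map
  ilk <- do.call(rbind, lapply(times, function(tt) {
    m <- interval_lookup_at(series, tt)
    if (nrow(m) > 0L) m$time <- tt
    m
  }))
  ikey <- if (!is.null(ilk) && nrow(ilk) > 0L)
    paste(ilk$time, ilk$cell_id) else character()
  dkey <- paste(df$time_h, df$cell_id)
  df$interval_id <- ilk$interval_id[match(dkey, ikey)]
  df$distance <- ilk$distance[match(dkey, ikey)]

  first_frame <- tapply(df$time_h, df$cell_id, min)
  last_frame <- tapply(df$time_h, df$cell_id, max)
  parent_of <- vapply(split(df$parent_id, df$cell_id),
                      function(p) p[1], "")
  # lineage consistency: a cell born mid-series must have a parent present
  # at the prior frame
  for (cid in names(first_frame)) {
    tf <- first_frame[[cid]]
    if (near(tf, times[1])) next
    p <- parent_of[[cid]]
    if (is.na(p))
      fila_stop("lineage",
                paste("cell", cid, "appears mid-series without a parent"))
    if (!p %in% names(last_frame) ||
        last_frame[[p]] < tf - dt - 1e-9)
      fila_stop("lineage", paste("orphan cell", cid, ": parent", p,
                                 "absent at the prior frame"))
  }
  roots <- names(parent_of)[is.na(parent_of)]

  kids <- df[!is.na(df$parent_id),
             c("cell_id", "parent_id", "time_h", "pos_index")]
  kids <- kids[!duplicated(kids$cell_id), , drop = FALSE]

  build_trace <- function(root, tab) {
    ord <- order(tab$time_h)
    tab <- tab[ord, , drop = FALSE]
    scale <- if (division_policy == "concentration") tab$area else 1
    structure(list(cell_id = root, times = tab$time_h,
                   gfp = tab$gfp / scale, af = tab$af / scale,
                   area = tab$area, interval_id = tab$interval_id,
                   distance = tab$distance, cell_type = tab$cell_type,
                   member_id = tab$cell_id, policy = division_policy,
                   dt = dt), class = "cell_trace")
  }

  if (division_policy %in% c("concentration", "first_daughter")) {
    traces <- lapply(roots, function(root) {
      chain <- root
      cur <- root
      repeat {
        tnext <- last_frame[[cur]] + dt
        dgt <- kids[kids$parent_id == cur & near(kids$time_h, tnext), ,
                    drop = FALSE]
        if (nrow(dgt) == 0L) break
        cur <- dgt$cell_id[which.min(dgt$pos_index)]
        chain <- c(chain, cur)
      }
      build_trace(root, df[df$cell_id %in% chain, , drop = FALSE])
    })
  } else {
    # sum policy: total intensity/area over all living descendants
    root_of <- stats::setNames(rep(NA_character_, length(parent_of)),
                               names(parent_of))
    for (cid in names(parent_of)) {
      cur <- cid
      while (!is.na(parent_of[[cur]])) cur <- parent_of[[cur]]
      root_of[[cid]] <- cur
    }
    traces <- lapply(roots, function(root) {
      sub <- df[root_of[df$cell_id] == root, , drop = FALSE]
      lead <- sub[order(sub$time_h, sub$pos_index), , drop = FALSE]
      lead <- lead[!duplicated(lead$time_h), , drop = FALSE]
      agg <- rowsum(sub[, c("gfp", "af", "area")], group = sub$time_h)
      tab <- data.frame(time_h = as.numeric(rownames(agg)),
                        cell_id = root, gfp = agg$gfp, af = agg$af,
                        area = agg$area,
                        interval_id = lead$interval_id,
                        distance = lead$distance,
                        cell_type = lead$cell_type,
                        stringsAsFactors = FALSE)
      tr <- build_trace(root, tab)
      tr$member_id <- rep(root, length(tr$times))
      tr
    })
  }
  stats::setNames(traces, roots)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("<cell_trace> root", x$cell_id, "|", length(x$times), "frames",
      sprintf("[%g, %g] h", min(x$times), max(x$times)),
      "| policy:", x$policy, "\n")
  invisible(x)
}

#' @export
print.filament_series <- function(x, ...) {
  cat("<filament_series>", length(unique(x$filament_id)), "filament(s),",
      length(unique(x$time_h)), "frames, dt =", attr(x, "dt"), "h,",
      nrow(x), "records\n")
  invisible(x)
}

# Align a list of cell traces on a common window -> matrix (time x cells).
trace_matrix <- function(traces, channel = "gfp", window = NULL) {
  fila_assert(length(traces) >= 2L, "alignment", "need at least 2 traces")
  t0 <- traces[[1]]$times
  for (tr in traces) {
    shared <- intersect(round(t0, 6), round(tr$times, 6))
    t0 <- t0[round(t0, 6) %in% shared]
  }
  if (!is.null(window)) t0 <- t0[t0 >= window[1] - 1e-9 & t0 <= window[2] + 1e-9]
  if (length(t0) < 4L)
    fila_stop("alignment", "fewer than 4 shared frames in the window")
  Y <- vapply(traces, function(tr) {
    idx <- match(round(t0, 6), round(tr$times, 6))
    if (anyNA(idx)) fila_stop("alignment", "mismatched time grids")
    tr[[channel]][idx]
  }, numeric(length(t0)))
  list(times = t0, Y = Y)
}
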