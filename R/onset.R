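# Constant-then-parabola changepoint fit: the stitching-point estimator of
# the onset of autofluorescence decay in incipient heterocysts (also reused
# for GFP expression turnoff).  The signal is modelled as f(t) = c for
# t <= t0 and f(t) = c - a (t - t0)^2 for t > t0 (value- and, by the
# vertex-at-t0 default, slope-continuous), fit by least squares with a grid
# search over the stitch point t0.

# Core least-squares solve for a fixed stitch t0.
# pre: indices with t <= t0; post: first frames of the decay.
solve_const_parabola <- function(y_pre, y_post, q) {
  n1 <- length(y_pre); n2 <- length(y_post)
  S1 <- sum(y_pre); S2 <- sum(y_post)
  Sq <- sum(q); Sq2 <- sum(q * q); Syq <- sum(y_post * q)
  # minimize sum(y_pre - c)^2 + sum(y_post - c + a q)^2 over (c, a)
  A <- matrix(c(n1 + n2, -Sq, Sq, -Sq2), 2, 2, byrow = TRUE)
  rhs <- c(S1 + S2, Syq)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  c0 <- sol[1]; a <- sol[2]
  sse <- sum((y_pre - c0)^2) + sum((y_post - c0 + a * q)^2)
  list(c = c0, a = a, sse = sse)
}

# Unconstrained-parabola variant: f(t) = c + b (t - t0) - a (t - t0)^2
# after the stitch (continuity at t0 kept, zero-slope constraint dropped).
solve_const_parabola_free <- function(y_pre, y_post, s) {
  Xp <- cbind(1, rep(0, length(y_pre)), rep(0, length(y_pre)))
  Xq <- cbind(1, s, -s * s)
  Xall <- rbind(Xp, Xq)
  yall <- c(y_pre, y_post)
  f <- tryCatch(stats::lm.fit(Xall, yall), error = function(e) NULL)
  if (is.null(f) || anyNA(f$coefficients)) return(NULL)
  b <- f$coefficients
  list(c = b[1], slope = b[2], a = b[3], sse = sum(f$residuals^2))
}

#' Constant-then-parabola stitching-point fit
#'
#' The fit targets the initial stage of the decay only: the analysis
#' window runs from the first frame to `extra_frames` past the point where
#' a lightly smoothed signal first falls below `drop_frac` (default half) of its starting
#' plateau, so every stitch candidate is scored on the same frames.  The
#' changepoint is grid-searched over the interior of that window (refined
#' on a half-frame grid when `refine = TRUE`); each candidate is fit by
#' least squares and the candidate minimizing the total SSE is returned,
#' ties broken toward the earliest stitch.  A fit whose decay over the
#' window is numerically negligible counts as no decay.
#'
#' @param times,y frame times (hours) and signal.
#' @param min_pre,min_post minimum frames before / after a candidate
#'   stitch.
#' @param refine also try candidates halfway between frames.
#' @param vertex_at_stitch if `TRUE` (default) the decay parabola has its
#'   vertex at the stitch (zero slope there); if `FALSE` an unconstrained
#'   linear term is allowed.
#' @param drop_frac,extra_frames delimit the initial decay stage (see
#'   above).
#' @return Object of class `onset_fit`: `t_on`, `pre_level`, `curvature`
#'   (a.u./h^2, positive = decay), `sse`, `n_frames_pre`, `n_frames_post`.
#' @export
fit_const_parabola <- function(times, y, min_pre = 6L, min_post = 4L,
                               refine = TRUE, vertex_at_stitch = TRUE,
                               drop_frac = 0.5, extra_frames = 4L) {
  n <- length(y)
  fila_assert(length(times) == n, "domain", "times/y length mismatch")
  fila_assert(all(y >= 0), "domain", "signal must be non-negative")
  if (n < min_pre + min_post)
    fila_stop("window", "trace too short for the changepoint fit")
  dt <- stats::median(diff(times))
  s <- moving_mean(y, 5L)
  plateau <- stats::median(s[seq_len(max(min_pre, 3L))])
  idx_drop <- which(s < drop_frac * plateau)[1]
  w_end <- if (is.na(idx_drop)) n else min(n, idx_drop + extra_frames)
  # never reach past the signal's minimum: frames beyond it (a following
  # rise, or a clipped floor) are not part of the decay being modelled,
  # yet their residuals against a still-falling parabola would dominate
  # the SSE and drag the stitch early
  w_min <- which.min(y[seq_len(w_end)])
  if (w_min <= min_pre)        # minimum at the start: nothing decays
    fila_stop("no_onset", "no decaying changepoint fit found")
  w_end <- min(w_end, w_min)
  if (w_end < min_pre + min_post)
    fila_stop("window", "decay starts too early for the changepoint fit")
  tw <- times[seq_len(w_end)]; yw <- y[seq_len(w_end)]
  cand <- tw[seq(min_pre, w_end - min_post)]
  if (refine && length(cand) > 1L)
    cand <- sort(c(cand, cand[-length(cand)] + dt / 2))
  a_tol <- 1e-6 * max(abs(plateau), 1)
  sol_at <- function(t0) {
    pre <- which(tw <= t0 + 1e-9)
    post <- which(tw > t0 + 1e-9)
    if (length(pre) < min_pre || length(post) < min_post) return(NULL)
    q <- (tw[post] - t0)^2
    sol <- if (vertex_at_stitch)
      solve_const_parabola(yw[pre], yw[post], q)
    else solve_const_parabola_free(yw[pre], yw[post], tw[post] - t0)
    if (is.null(sol) || !is.finite(sol$a) || sol$a <= 0) return(NULL)
    if (sol$a * max(q) <= a_tol) return(NULL)   # negligible decay
    list(t_on = t0, pre_level = sol$c, curvature = sol$a, sse = sol$sse,
         n_pre = length(pre), n_post = length(post))
  }
  best <- NULL
  for (t0 in cand) {
    sol <- sol_at(t0)
    if (!is.null(sol) && (is.null(best) || sol$sse < best$sse - 1e-12))
      best <- sol
  }
  if (is.null(best))
    fila_stop("no_onset", "no decaying changepoint fit found")
  # continuous local refinement around the grid winner: the SSE is smooth
  # in t0 between samples, so an off-grid stitch is recoverable beyond
  # the half-frame resolution
  if (best$sse > 0) {
    step <- if (refine) dt / 2 else dt
    op <- tryCatch(stats::optimize(function(t0) {
      s <- sol_at(t0)
      if (is.null(s)) .Machine$double.xmax / 2 else s$sse
    }, interval = c(best$t_on - step, best$t_on + step)),
    error = function(e) NULL)
    if (!is.null(op) && is.finite(op$objective) &&
        op$objective < best$sse * (1 - 1e-9)) {
      ref <- sol_at(op$minimum)
      if (!is.null(ref)) best <- ref
    }
  }
  structure(list(t_on = best$t_on, pre_level = unname(best$pre_level),
                 curvature = unname(best$curvature), sse = best$sse,
                 n_frames_pre = best$n_pre, n_frames_post = best$n_post,
                 vertex_at_stitch = vertex_at_stitch),
            class = "onset_fit")
}

#' Detect the onset of autofluorescence decay
#'
#' Applies the constant-then-parabola stitching-point fit
#' ([fit_const_parabola()]) to an autofluorescence trace; the stitch is
#' the estimated time at which photosynthetic-pigment fluorescence starts
#' to fall in an incipient heterocyst.
#'
#' @param af_trace a `cell_trace` (AF channel used) or numeric AF series.
#' @param times frame times for numeric input.
#' @param ... passed to [fit_const_parabola()].
#' @return An `onset_fit`.
#' @export
detect_af_onset <- function(af_trace, times = NULL, ...) {
  inp <- as_series_input(af_trace, times, "af")
  fit_const_parabola(inp$t, inp$y, ...)
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf(
    "<onset_fit> t_on = %.2f h, pre-level = %.4g, curvature = %.4g /h^2\n",
    x$t_on, x$pre_level, x$curvature))
  cat(sprintf("  SSE = %.4g over %d pre + %d post frames (%s)\n",
              x$sse, x$n_frames_pre, x$n_frames_post,
              if (x$vertex_at_stitch) "vertex at stitch"
              else "unconstrained parabola"))
  invisible(x)
}

#' @export
coef.onset_fit <- function(object, ...) {
  c(t_on = object$t_on, pre_level = object$pre_level,
    curvature = object$curvature)
}
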