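# Shared fixture builders (all data generated in code).

# minimal well-formed series: one filament, cosine traces, no divisions
toy_series <- function(n_cells = 3, n_frames = 6, dt = 0.5,
                       types = rep("vegetative", n_cells)) {
  times <- seq(0, by = dt, length.out = n_frames)
  df <- expand.grid(cell = seq_len(n_cells), time_h = times)
  data.frame(time_h = df$time_h,
             filament_id = "F01",
             cell_id = sprintf("c%02d", df$cell),
             parent_id = NA_character_,
             pos_index = df$cell - 1L,
             cell_type = types[df$cell],
             gfp = 100 + 10 * df$cell + df$time_h,
             af = 200,
             area = 5,
             stringsAsFactors = FALSE)
}

# series with a prescribed cell-type pattern at a single shared frame set
pattern_series <- function(pattern, n_frames = 4, dt = 0.5) {
  n <- nchar(pattern)
  types <- c(H = "heterocyst", V = "vegetative", D = "differentiating")
  toy <- toy_series(n, n_frames, dt,
                    types = types[strsplit(pattern, "")[[1]]])
  toy
}

# sinusoidal trace list on a dense grid over exactly n full periods
sin_traces <- function(phases, amplitude = 1, period = 21, dt = 0.05,
                       n_periods = 1, baseline = 10) {
  times <- seq(0, n_periods * period - dt, by = dt)
  lapply(seq_along(phases), function(i)
    structure(list(cell_id = sprintf("s%02d", i), times = times,
                   gfp = baseline + amplitude *
                     cos(2 * pi * times / period + phases[i]),
                   af = rep(1, length(times)),
                   area = rep(5, length(times)),
                   interval_id = rep("iv", length(times)),
                   distance = rep(1L, length(times)),
                   cell_type = rep("vegetative", length(times)),
                   member_id = rep(sprintf("s%02d", i), length(times)),
                   policy = "concentration", dt = dt),
              class = "cell_trace"))
}

# literal, unoptimized transcription of the synchronization-index formula:
# time averages written as explicit loops, sample variances with n-1.
sync_index_bruteforce <- function(Y) {
  n_t <- nrow(Y); n_c <- ncol(Y)
  mu <- numeric(n_t)
  for (t in seq_len(n_t)) mu[t] <- mean(Y[t, ])
  var_time <- function(v) {
    m <- 0
    for (t in seq_len(n_t)) m <- m + v[t]
    m <- m / n_t
    s <- 0
    for (t in seq_len(n_t)) s <- s + (v[t] - m)^2
    s / (n_t - 1)
  }
  num <- var_time(mu)
  den <- 0
  for (i in seq_len(n_c)) den <- den + var_time(Y[, i])
  den <- den / n_c
  num / den
}
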