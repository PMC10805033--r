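# Long-format trace data model: CSV I/O, invariants, intervals, lineages.

test_that("a well-formed series parses and a CSV round-trip is lossless", {
  df <- toy_series(n_cells = 2, n_frames = 3)
  fs <- filament_series(df)
  expect_s3_class(fs, "filament_series")
  expect_equal(nrow(fs), 6L)
  expect_equal(attr(fs, "dt"), 0.5)

  p <- withr::local_tempfile(fileext = ".csv")
  write_traces(fs, p)
  back <- read_traces(p)
  expect_equal(as.data.frame(back), as.data.frame(fs))

  # empty series -> header-only file
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traces(filament_series(df[0, ], validate = FALSE), p2)
  expect_equal(length(readLines(p2)), 1L)
  # null parent serialized as empty field
  expect_false(grepl("NA", readLines(p)[2]))
})

test_that("round-trip serialization is lossless for generator output", {
  for (seed in c(3L, 104L)) {
    cfg <- regime_preset("nitrogen_deprived", n_filaments = 1,
                         duration_h = 48, seed = seed)
    sim <- simulate_cohort(cfg)
    p <- withr::local_tempfile(fileext = ".csv")
    write_traces(sim$series, p)
    back <- read_traces(p)
    expect_equal(as.data.frame(back), as.data.frame(sim$series),
                 tolerance = 1e-12)
  }
})

test_that("schema and integrity violations raise classed errors", {
  df <- toy_series(3, 4)
  expect_error(filament_series(df[, -3]), class = "filaclock_schema_error")
  # pos_index gap {0,2} at one frame
  bad <- df
  bad$pos_index[bad$time_h == 0 & bad$pos_index == 1L] <- 2L
  bad <- bad[!(bad$time_h == 0 & bad$cell_id == "c03"), ]
  expect_error(filament_series(bad), class = "filaclock_integrity_error")
  # duplicate cell per frame
  dup <- rbind(df, df[1, ])
  expect_error(filament_series(dup), class = "filaclock_integrity_error")
  # non-constant time step
  odd <- df
  odd$time_h[odd$time_h == 1.5] <- 1.7
  expect_error(filament_series(odd), class = "filaclock_sampling_error")
  # backward differentiation
  backw <- df
  backw$cell_type <- ifelse(backw$time_h == 0 & backw$cell_id == "c01",
                            "heterocyst", backw$cell_type)
  expect_error(filament_series(backw), class = "filaclock_integrity_error")
})

test_that("intervals_at partitions vegetative cells by heterocyst bounds", {
  hs <- pattern_series("HVVVH")
  iv <- intervals_at(filament_series(hs), 0)
  expect_length(iv, 1L)
  expect_length(iv[[1]]$cell_ids, 3L)
  expect_true(iv[[1]]$bounded)
  expect_equal(iv[[1]]$distance, c(1L, 2L, 1L))

  vs <- pattern_series("VVHVV")
  iv2 <- intervals_at(filament_series(vs), 0)
  expect_length(iv2, 2L)
  expect_equal(sapply(iv2, function(v) length(v$cell_ids)), c(2L, 2L))
  expect_false(any(sapply(iv2, `[[`, "bounded")))
  expect_true(all(is.na(unlist(lapply(iv2, `[[`, "distance")))))
})

test_that("intervals cover every vegetative cell exactly once each frame", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 2,
                       duration_h = 48, seed = 21)
  sim <- simulate_cohort(cfg)
  # ground-truth lengths at t = 0
  iv0 <- intervals_at(sim$series, 0)
  expect_equal(sort(sapply(iv0, function(v) length(v$cell_ids))),
               sort(sim$truth$intervals$length))
  for (tt in c(0, 24, 48)) {
    fr <- sim$series[sim$series$time_h == tt, ]
    veg_ids <- fr$cell_id[fr$cell_type != "heterocyst"]
    got <- unlist(lapply(intervals_at(sim$series, tt), `[[`, "cell_ids"))
    expect_setequal(got, veg_ids)
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("lineage resolution splices through divisions as specified", {
  # hand-built: one cell divides at frame 3 (t = 1.0)
  rows <- list()
  for (tt in c(0, 0.5)) rows[[length(rows) + 1L]] <- data.frame(
    time_h = tt, filament_id = "F", cell_id = "m", parent_id = NA,
    pos_index = 0L, cell_type = "vegetative", gfp = 100, af = 50, area = 4)
  for (tt in c(1, 1.5)) for (d in 1:2) rows[[length(rows) + 1L]] <-
    data.frame(time_h = tt, filament_id = "F",
               cell_id = paste0("d", d),
               parent_id = ifelse(tt == 1, "m", NA),
               pos_index = d - 1L, cell_type = "vegetative",
               gfp = 40 + 10 * d, af = 25, area = 2)
  fs <- filament_series(do.call(rbind, rows))

  tr <- resolve_lineages(fs, "first_daughter")
  expect_length(tr, 1L)
  expect_equal(tr$m$times, c(0, 0.5, 1, 1.5))
  expect_equal(tr$m$gfp, c(100, 100, 50, 50))   # daughter with lower pos
  expect_equal(tr$m$member_id, c("m", "m", "d1", "d1"))

  trc <- resolve_lineages(fs, "concentration")
  expect_equal(trc$m$gfp, c(25, 25, 25, 25))    # no jump at division

  trs <- resolve_lineages(fs, "sum")
  expect_equal(trs$m$gfp, c(100, 100, 110, 110))
  expect_equal(trs$m$area, c(4, 4, 4, 4))

  # orphan parent
  bad <- as.data.frame(fs)
  bad$parent_id[bad$cell_id == "d1" & bad$time_h == 1] <- "ghost"
  expect_error(resolve_lineages(filament_series(bad, validate = FALSE)),
               class = "filaclock_lineage_error")
})

test_that("without divisions every cell yields its own verbatim trace", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 1,
                       duration_h = 48, seed = 8)
  sim <- simulate_cohort(cfg)
  tr <- resolve_lineages(sim$series, "first_daughter")
  expect_length(tr, length(unique(sim$series$cell_id)))
  one <- sim$series[sim$series$cell_id == names(tr)[3], ]
  expect_equal(tr[[3]]$gfp, one$gfp[order(one$time_h)])
})

test_that("simulated division log matches trace count and jump bound", {
  cfg <- regime_preset("nitrogen_deprived", n_filaments = 1, seed = 15,
                       duration_h = 48, division_enabled = TRUE,
                       doubling_time_h = 30)
  sim <- simulate_cohort(cfg)
  expect_gt(nrow(sim$truth$divisions), 5L)
  trs <- resolve_lineages(sim$series, "concentration")
  roots <- unique(sim$series$cell_id[is.na(sim$series$parent_id) &
                                       sim$series$time_h == 0])
  expect_length(trs, length(roots))
  # concentration policy: relative jump at a division frame bounded by
  # 5 x measurement CV in 99% of divisions
  dv <- sim$truth$divisions
  jumps <- c()
  for (i in seq_len(nrow(dv))) {
    hit <- which(vapply(trs, function(x) dv$mother[i] %in% x$member_id,
                        TRUE))
    if (length(hit) == 0L) next      # mother not on a first-daughter chain
    tr <- trs[[hit[1]]]
    k <- which(abs(tr$times - dv$time[i]) < 1e-9)
    if (length(k) != 1L || k == 1L) next
    jumps <- c(jumps, abs(tr$gfp[k] - tr$gfp[k - 1]) / tr$gfp[k - 1])
  }
  expect_gt(length(jumps), 5L)
  expect_gte(mean(jumps <= 5 * 0.05), 0.99)
})
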