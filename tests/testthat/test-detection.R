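test_that("episode segmentation finds maximal contact runs separated by silent frames", {
  g <- tiny_geometry()
  # all-zero recording -> no episodes
  rec0 <- make_rec(lapply(1:12, function(i) zero_frame(g)), g)
  expect_identical(detect_episodes(rec0), list())
  # one blob spanning frames 3..10
  rec1 <- blob_recording(3:10, 14)
  eps <- detect_episodes(rec1)
  expect_length(eps, 1)
  expect_equal(eps[[1]]$start_frame, 3)
  expect_equal(eps[[1]]$end_frame, 10)
  # two blobs separated by one silent frame
  rec2 <- blob_recording(c(2:5, 7:9), 12)
  eps2 <- detect_episodes(rec2)
  expect_length(eps2, 2)
  expect_equal(sapply(eps2, `[[`, "start_frame"), c(2, 7))
  expect_equal(sapply(eps2, `[[`, "end_frame"), c(5, 9))
  # a single-frame blip is rejected by min_duration = 2
  rec3 <- blob_recording(6, 10)
  expect_length(detect_episodes(rec3), 0)
})

test_that("episode frames partition the gate-passing frames", {
  sim <- simulate_recording(simulation_config(trial_duration = 6, seed = 31,
                                              touch_rate = 2, p_between = 0.5,
                                              noise_sd = 0.2))
  rec <- sim$recording
  cfg <- detection_config()
  eps <- detect_episodes(rec, cfg)
  covered <- unlist(lapply(eps, function(e) e$start_frame:e$end_frame))
  expect_false(any(duplicated(covered)))
  gate <- vapply(rec$frames, function(f)
    sum(f[f >= cfg$force_threshold]) >= cfg$min_total_force, TRUE)
  runs <- rle(gate)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  expected <- unlist(mapply(
    function(s, e, v, l) if (v && l >= cfg$min_duration) s:e else NULL,
    starts, ends, runs$values, runs$lengths))
  expect_identical(sort(covered), sort(as.integer(expected)))
})

test_that("largest-component selection keeps the foot and drops stray cells", {
  g <- tiny_geometry()
  m <- put_block(zero_frame(g), 11:13, 9:11, 10)  # 9-cell foot
  m[40, 18] <- 50                                  # lone noisy cell
  reg <- lemocot:::frame_active_region(m, detection_config())
  expect_equal(nrow(reg$cells), 9)
  expect_equal(reg$n_secondary, 1)
  expect_false(any(reg$cells[, 1] == 39))
  # 4- vs 8-connectivity: diagonal neighbours split under 4
  md <- zero_frame(g); md[11, 11] <- 5; md[12, 12] <- 5; md[13, 13] <- 5
  reg8 <- lemocot:::frame_active_region(md, detection_config(connectivity = 8))
  reg4 <- lemocot:::frame_active_region(md, detection_config(connectivity = 4))
  expect_equal(nrow(reg8$cells), 3)
  expect_equal(nrow(reg4$cells), 1)
})

test_that("COP is the force-weighted cell-centre mean and stays inside the hull", {
  g <- tiny_geometry()
  # one active cell at the origin
  r1 <- make_region(cbind(10L, 10L), 5)
  expect_equal(unname(cop_location(r1, g)), c(0, 0))
  # two cells at x = 0 and x = 8, forces 1 and 3 -> x = 6
  r2 <- make_region(rbind(c(10L, 10L), c(10L, 11L)), c(1, 3))
  expect_equal(unname(cop_location(r2, g)), c(6, 0))
  # uniform forces on a symmetric region -> centroid
  cells <- as.matrix(expand.grid(row = 10:12, col = 9:11))
  r3 <- make_region(cells, rep(2, 9))
  expect_equal(unname(cop_location(r3, g)),
               unname(colMeans(cell_to_point(cells[, 1], cells[, 2], g))))
  expect_error(cop_location(make_region(cbind(1L, 1L), 0), g), "zero total")
  # random fixtures: inside the convex hull of the cell centres
  set.seed(41)
  for (i in 1:30) {
    base <- cbind(row = c(10L, 11L, 10L), col = c(10L, 10L, 11L))
    extra <- cbind(row = sample(8:14, 5, TRUE), col = sample(8:14, 5, TRUE))
    cells <- unique(rbind(base, extra))
    reg <- make_region(cells, runif(nrow(cells), 0.5, 10))
    cop <- cop_location(reg, g)
    pts <- cell_to_point(cells[, 1], cells[, 2], g)
    hull_with <- grDevices::chull(rbind(pts, cop))
    expect_false((nrow(pts) + 1L) %in% hull_with)
  }
})

test_that("endpoint isolates the toe from a connected toe+heel contact", {
  g <- tiny_geometry()
  # single cell -> its centre
  expect_equal(unname(endpoint_location(make_region(cbind(10L, 10L), 4), g,
                                        c(0, 0))), c(0, 0))
  # toe blob at the proximal target + heel block towards the body (-y),
  # connected by an arch band, uniform forces
  toe <- as.matrix(expand.grid(row = 9:11, col = 9:11))
  heel <- as.matrix(expand.grid(row = -6:-4 + 10L, col = 8:12))
  arch <- cbind(row = 5:8, col = 10L)
  cells <- rbind(toe, heel, arch)
  reg <- make_region(cells, rep(5, nrow(cells)))
  ep <- endpoint_location(reg, g, c(0, 0))
  cop <- cop_location(reg, g)
  toe_centroid <- colMeans(cell_to_point(toe[, 1], toe[, 2], g))
  expect_lt(sqrt(sum((ep - toe_centroid)^2)), 8)   # near the toe centroid
  expect_gt(ep[2], cop[2])                          # COP dragged heelwards
  expect_gt(sqrt(sum((ep - cop)^2)), 0)
  # circular blob centred on the target -> endpoint within one pitch
  cc <- as.matrix(expand.grid(row = 9:13, col = 9:13))
  keep <- sqrt((cc[, 1] - 11)^2 + (cc[, 2] - 11)^2) <= 2
  regc <- make_region(cc[keep, , drop = FALSE], rep(7, sum(keep)))
  epc <- endpoint_location(regc, g, c(0, 0))
  expect_lt(max(abs(epc - c(0, 0))), 8)
})

test_that("time of touch is the earliest distance-minimising frame", {
  g <- tiny_geometry()
  cfg <- detection_config()
  # stationary endpoint -> start frame (tie-break)
  rec <- blob_recording(2:6, 8)
  ep <- detect_episodes(rec)[[1]]
  expect_equal(time_of_touch(ep, rec, c(0, 0), cfg), 2)
  # approach then retreat: minimum at the closest frame
  rows <- c(16, 13, 12, 10, 12, 15)  # 1-based; blob centroid y = (r - 10.5) * 8
  frames <- lapply(seq_along(rows), function(i)
    put_block(zero_frame(g), rows[i] + 0:1, 10:11, 10))
  rec2 <- make_rec(frames, g)
  ep2 <- detect_episodes(rec2)[[1]]
  expect_equal(time_of_touch(ep2, rec2, c(0, 0), cfg), 4)
  # two equally-near frames -> the earlier one
  rows3 <- c(14, 11, 11, 14)
  frames3 <- lapply(seq_along(rows3), function(i)
    put_block(zero_frame(g), rows3[i] + 0:1, 10:11, 10))
  rec3 <- make_rec(frames3, g)
  ep3 <- detect_episodes(rec3)[[1]]
  expect_equal(time_of_touch(ep3, rec3, c(0, 0), cfg), 2)
})

test_that("contact surface is cell count times cell area, monotone in the threshold", {
  g <- tiny_geometry()
  expect_equal(contact_surface(make_region(cbind(10L, 10L), 5), g), 0.64)
  cells10 <- as.matrix(expand.grid(row = 10:14, col = 10:11))
  expect_equal(contact_surface(make_region(cells10, rep(3, 10)), g), 6.4)
  set.seed(51)
  m <- put_block(zero_frame(g), 9:13, 8:12, 0)
  m[9:13, 8:12] <- matrix(runif(25, 0, 20), 5, 5)
  surf <- sapply(c(0.5, 2, 5, 10, 15), function(thr) {
    reg <- lemocot:::frame_active_region(m, detection_config(force_threshold = thr))
    if (is.null(reg)) 0 else contact_surface(reg, g)
  })
  expect_true(all(diff(surf) <= 0))
})

test_that("intended-target inference uses zones first, then alternation", {
  g <- tiny_geometry()
  # episode ending in the distal zone (y = 288)
  rec_d <- blob_recording(2:4, 6, rows = 46:47, cols = 10:11)
  ep_d <- detect_episodes(rec_d)[[1]]
  expect_equal(infer_intended_target(ep_d, rec_d), "distal")
  # between-zone drag: alternation from previous target
  rec_b <- blob_recording(2:4, 6, rows = 28:29, cols = 10:11)  # y ~ 146
  ep_b <- detect_episodes(rec_b)[[1]]
  expect_equal(infer_intended_target(ep_b, rec_b, previous_target = "proximal"),
               "distal")
  expect_equal(infer_intended_target(ep_b, rec_b, previous_target = "distal"),
               "proximal")
  expect_equal(infer_intended_target(ep_b, rec_b), "proximal")  # trial start
})

test_that("detection is deterministic: identical input gives identical output", {
  sim <- simulate_recording(simulation_config(trial_duration = 4, seed = 61,
                                              noise_sd = 0.2))
  t1 <- detect_touches(sim$recording)
  t2 <- detect_touches(sim$recording)
  expect_identical(t1, t2)
})
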