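test_that("median background subtraction matches its definition", {
  f <- matrix(1:9, 3, 3, byrow = TRUE)          # median 5
  out <- subtract_background(f)
  expect_equal(as.vector(t(out)), c(0, 0, 0, 0, 0, 1, 2, 3, 4))
  expect_true(all(subtract_background(matrix(7, 4, 4)) == 0))
  # shift invariance: adding a constant offset changes nothing
  g <- matrix(stats::rnorm(100, 50, 5), 10, 10)
  expect_equal(subtract_background(g + 13.7), subtract_background(g))
  expect_error(subtract_background(matrix(numeric(0), 0, 0)), "empty")
})

test_that("background subtraction is idempotent once background dominates", {
  set.seed(3)
  f <- matrix(0, 20, 20)
  f[5:8, 5:8] <- 100                            # <= half foreground
  once <- subtract_background(f)
  expect_equal(subtract_background(once), once)
})

test_that("phase correlation recovers constructed integer shifts", {
  set.seed(8)
  ref <- matrix(0, 48, 48)
  ref[10:20, 15:25] <- matrix(stats::runif(11 * 11, 50, 100), 11)
  shifted <- nucmorph:::shift_matrix(ref, 3, -2)
  reg <- register_timepoints(list(ref, shifted))
  expect_equal(unname(reg$shifts[2, ]), c(3, -2))
  # alignment restores the original up to the zero-filled border
  inner <- reg$aligned[[2]][5:40, 5:40]
  expect_equal(inner, ref[5:40, 5:40])
  # identical frames give zero shifts
  reg0 <- register_timepoints(list(ref, ref, ref))
  expect_true(all(reg0$shifts == 0))
  # blank frame is flagged, not crashed
  regb <- register_timepoints(list(ref, matrix(0, 48, 48)))
  expect_equal(regb$flags[2], "blank")
  expect_true(all(regb$shifts[2, ] == 0))
})

test_that("registration recovers simulated stage drift exactly", {
  cfg <- sim_config(n_cells = 6L, seed = 14L)
  sim <- simulate_field(cfg, noise = FALSE)
  reg <- register_timepoints(lapply(sim$frames, `[[`, "morph"))
  expect_equal(unname(reg$shifts), unname(sim$shifts))
  # with the default noise model too
  simn <- simulate_field(cfg, noise = TRUE)
  regn <- register_timepoints(lapply(lapply(simn$frames, `[[`, "morph"),
                                     subtract_background))
  expect_equal(unname(regn$shifts), unname(simn$shifts))
})

test_that("segmentation matches the integer-disc oracle", {
  # oracle: pixels with dx^2 + dy^2 <= r^2 around each center
  f <- matrix(0, 64, 64)
  centers <- list(c(15, 15), c(15, 55))
  for (ct in centers) {
    for (r in 1:64) for (c in 1:64) {
      if ((r - ct[1])^2 + (c - ct[2])^2 <= 25) f[r, c] <- 100
    }
  }
  obs <- segment_cells(f, min_area = 10L, threshold = 50)
  expect_length(obs, 2)
  expect_equal(vapply(obs, `[[`, 0L, "area_px"), c(81L, 81L))
  cents <- t(vapply(obs, `[[`, c(0, 0), "centroid"))
  expect_equal(cents[order(cents[, 2]), ],
               rbind(c(14, 14), c(14, 54)), tolerance = 1e-9)  # 0-based
  # blank frame and min_area filtering
  expect_length(segment_cells(matrix(0, 8, 8), threshold = 1), 0)
  expect_length(segment_cells(f, min_area = 100L, threshold = 50), 0)
})

test_that("segmentation recovers the simulated cell count", {
  cfg <- sim_config(n_cells = 8L, seed = 23L)
  sim <- simulate_field(cfg, noise = FALSE)
  obs <- segment_cells(subtract_background(sim$frames[[1]]$morph))
  expect_length(obs, 8)
  # at default noise, recall at least 90%
  simn <- simulate_field(cfg, noise = TRUE)
  obsn <- segment_cells(subtract_background(simn$frames[[1]]$morph))
  expect_gte(length(obsn), ceiling(0.9 * 8))
})

test_that("tracking links cells and ends tracks when cells disappear", {
  ob <- function(label, r, c) list(cell_label = label, mask = NULL,
                                   centroid = c(r, c), area_px = 50L,
                                   mean_intensity = c(morph = 1))
  tps <- list(
    list(timepoint_h = 0, observations = list(ob(1, 10, 10), ob(2, 40, 40))),
    list(timepoint_h = 8, observations = list(ob(1, 12, 11), ob(2, 42, 41))),
    list(timepoint_h = 16, observations = list(ob(1, 13, 12))))
  trks <- track_cells(tps, max_displacement = 20)
  expect_length(trks, 2)
  lens <- sort(vapply(trks, function(t) length(t$observations), 0L))
  expect_equal(lens, c(2L, 3L))
  # conservation: every observation in exactly one track
  expect_equal(sum(lens), 5L)
  # duplicate labels rejected
  bad <- list(list(timepoint_h = 0,
                   observations = list(ob(1, 1, 1), ob(1, 9, 9))))
  expect_error(track_cells(bad), "duplicate")
})

test_that("greedy tracking equals the exhaustive optimal assignment", {
  # 10 well-separated cells over 4 timepoints, small within-track motion
  set.seed(31)
  base <- cbind(stats::runif(10, 20, 300), stats::runif(10, 20, 300))
  while (min(stats::dist(base)) < 60) {
    base <- cbind(stats::runif(10, 20, 300), stats::runif(10, 20, 300))
  }
  tps <- lapply(0:3, function(k) {
    pos <- base + matrix(stats::rnorm(20, 0, 3), 10)
    list(timepoint_h = k * 8,
         observations = lapply(1:10, function(i)
           list(cell_label = i, centroid = pos[i, ], area_px = 40L,
                mean_intensity = c(morph = 1))))
  })
  trks <- track_cells(tps, max_displacement = 25)
  expect_length(trks, 10)
  expect_true(all(vapply(trks, function(t) length(t$observations), 0L) == 4))
  # per-transition greedy cost equals the DP-optimal assignment cost
  for (k in 1:3) {
    A <- t(vapply(tps[[k]]$observations, `[[`, c(0, 0), "centroid"))
    B <- t(vapply(tps[[k + 1]]$observations, `[[`, c(0, 0), "centroid"))
    D <- as.matrix(stats::dist(rbind(A, B)))[1:10, 11:20]
    opt <- optimal_assignment_cost(D, 25)
    # greedy cost for this transition
    gcost <- sum(vapply(trks, function(t) {
      o <- t$observations
      sqrt(sum((o[[k + 1]]$centroid - o[[k]]$centroid)^2))
    }, 0))
    expect_equal(gcost, opt, tolerance = 1e-9)
  }
})

test_that("crop extraction follows the half-open centered-window contract", {
  f <- matrix(stats::runif(64 * 64), 64, 64)
  cr <- extract_crop(f, c(32, 32), 64L)
  expect_equal(cr$pixels, f)
  expect_equal(cr$pad_fraction, 0)
  # corner centroid: 3/4 of the window is out of frame
  cr2 <- extract_crop(f, c(0, 0), 64L)
  expect_equal(cr2$pad_fraction, 0.75)
  # the centroid pixel lands at index side/2 (0-based) in each axis
  f3 <- matrix(0, 80, 80)
  f3[41, 53] <- 9                      # 0-based (40, 52)
  cr3 <- extract_crop(f3, c(40, 52), 32L)
  expect_equal(cr3$pixels[17, 17], 9)  # 0-based (16, 16) = side/2
  expect_equal(sum(cr3$pixels), 9)
  expect_error(extract_crop(f, c(-3, 10), 32L), "outside")
  expect_error(extract_crop(f, c(10, 10), 33), "")
})

test_that("crop centering: brightest component centroid sits at the center", {
  cfg <- sim_config(n_cells = 5L, seed = 17L)
  sim <- simulate_field(cfg, noise = FALSE)
  f <- subtract_background(sim$frames[[1]]$morph)
  obs <- segment_cells(f)
  for (o in obs) {
    cr <- extract_crop(f, o$centroid, 64L)
    sub <- segment_cells(cr$pixels, min_area = 20L)
    if (length(sub) == 0) next
    main <- sub[[which.max(vapply(sub, `[[`, 0L, "area_px"))]]
    expect_lt(max(abs(main$centroid - 32)), 1 + 1e-9)
  }
})

test_that("process_field produces consistent per-observation features", {
  cfg <- sim_config(n_cells = 6L, seed = 19L)
  sim <- simulate_field(cfg)
  pf <- process_field(sim)
  expect_true(all(c("cell_label", "timepoint_h", "area_px", "fluor_area_px",
                    "mean_gedi", "mean_morph") %in% names(pf$features)))
  # tracking conservation: features rows = sum of track lengths
  expect_equal(nrow(pf$features),
               sum(vapply(pf$tracks, function(t) length(t$observations), 0L)))
  expect_true(all(pf$features$mean_morph > 0))
  # recovered registration equals simulated drift
  expect_equal(unname(pf$shifts), unname(sim$shifts))
})
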