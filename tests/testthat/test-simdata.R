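make_truth <- function(marker, alive, cfg, seed = 5L, ratio = 0.1) {
  params <- nucmorph:::with_seed(seed, nucmorph:::sample_cell_params(cfg))
  list(marker = marker, alive = alive, params = params, gedi_ratio = ratio)
}

test_that("live nuclear-marker render confines all signal to the nucleus", {
  cfg <- sim_config(marker = "nls")
  for (seed in 1:5) {
    tr <- make_truth("nls", TRUE, cfg, seed)
    r <- render_cell(tr, cfg)
    expect_true(all(r$morph[!r$masks$nucleus] == 0))
    expect_true(any(r$morph > 0))
  }
})

test_that("dead nuclear-marker render has the punctum brightness contract", {
  cfg <- sim_config(marker = "nls")
  for (seed in 1:5) {
    r <- render_cell(make_truth("nls", FALSE, cfg, seed), cfg)
    expect_true(any(r$masks$punctum))
    peak <- max(r$morph[r$masks$punctum])
    surround <- mean(r$morph[r$masks$nucleus & !r$masks$punctum])
    expect_gte(peak / surround, cfg$punctum_brightness - 1e-9)
  }
})

test_that("same cell rendered live vs dead moves area in the marker's direction", {
  for (marker in c("diffuse", "nls")) {
    cfg <- sim_config(marker = marker)
    for (seed in 1:5) {
      al <- sum(render_cell(make_truth(marker, TRUE, cfg, seed), cfg)$morph > 0)
      ad <- sum(render_cell(make_truth(marker, FALSE, cfg, seed), cfg)$morph > 0)
      if (marker == "diffuse") expect_lt(ad, al) else expect_gt(ad, al)
    }
  }
})

test_that("area directionality holds in the mean over 100 cells and recovers the scale", {
  for (marker in c("diffuse", "nls")) {
    cfg <- sim_config(marker = marker)
    ratio <- nucmorph:::with_seed(42, {
      vapply(1:100, function(i) {
        params <- nucmorph:::sample_cell_params(cfg)
        tl <- list(marker = marker, alive = TRUE, params = params, gedi_ratio = 0.1)
        td <- list(marker = marker, alive = FALSE, params = params, gedi_ratio = 0.1)
        sum(render_cell(td, cfg)$morph > 0) / sum(render_cell(tl, cfg)$morph > 0)
      }, 0)
    })
    target <- cfg$dead_area_scale[[marker]]
    expect_lt(abs(mean(ratio) - target) / target, 0.1)
  }
})

test_that("mask invariants: punctum inside nucleus inside soma", {
  cfg <- sim_config(marker = "nls")
  for (seed in 1:8) {
    for (alive in c(TRUE, FALSE)) {
      r <- render_cell(make_truth("nls", alive, cfg, seed), cfg)
      expect_true(all(r$masks$nucleus[!r$masks$soma] == FALSE))
      expect_true(all(r$masks$punctum[!r$masks$nucleus] == FALSE))
      if (alive) expect_false(any(r$masks$punctum))
    }
  }
})

test_that("death-indicator channel encodes the true ratio exactly (noise off)", {
  cfg <- sim_config(marker = "diffuse")
  tr <- make_truth("diffuse", FALSE, cfg, 3, ratio = 0.37)
  r <- render_cell(tr, cfg)
  m <- r$morph > 0
  expect_equal(mean(r$gedi[m]) / mean(r$morph[m]), 0.37, tolerance = 1e-12)
})

test_that("invalid marker is rejected", {
  cfg <- sim_config()
  tr <- make_truth("diffuse", TRUE, cfg, 1)
  tr$marker <- "cytoplasmic"
  expect_error(render_cell(tr, cfg), "marker")
})

test_that("sampled ratios clear the thresholds for at least 95% of draws", {
  cfg <- sim_config()
  draws <- function(alive, marker) nucmorph:::with_seed(9, {
    sample_gedi_ratio(alive, marker, cfg, n = 10000L)
  })
  expect_gte(mean(draws(TRUE, "diffuse") < 0.1), 0.95)
  expect_gte(mean(draws(FALSE, "diffuse") > 0.25), 0.95)
  expect_gte(mean(draws(TRUE, "nls") < 0.03), 0.95)
  expect_gte(mean(draws(FALSE, "nls") > 0.055), 0.95)
})

test_that("degenerate zero-variance ratio distribution is a point mass", {
  cfg <- sim_config()
  cfg$gedi_dist$diffuse$dead <- c(meanlog = log(0.5), sdlog = 0)
  r <- sample_gedi_ratio(FALSE, "diffuse", cfg, n = 50L)
  expect_true(all(r == 0.5))
  expect_true(all(bucket_label(r, labeling_config("diffuse")) == "dead"))
})

test_that("simulate_field assigns exact death fractions and timing", {
  cfg <- sim_config(n_cells = 10L, fraction_dead = 0.5, seed = 4L)
  sim <- simulate_field(cfg, noise = FALSE)
  dead <- Filter(function(tr) !tr$alive, sim$truths)
  expect_length(dead, 5)
  expect_true(all(vapply(dead, function(tr) tr$death_time_h %in% c(8, 16, 24),
                         TRUE)))
  # a cell dying at 8h renders live at t=0 and dead from t=8 on
  cfg2 <- sim_config(n_cells = 4L, fraction_dead = 1, death_time_h = 8,
                     marker = "nls", seed = 6L)
  sim2 <- simulate_field(cfg2, noise = FALSE)
  tr <- sim2$truths[[1]]
  P <- cfg2$patch_size
  rows <- (tr$patch_offset[1] + 1):(tr$patch_offset[1] + P)
  cols <- (tr$patch_offset[2] + 1):(tr$patch_offset[2] + P)
  area_t <- vapply(seq_along(sim2$frames), function(k) {
    f <- nucmorph:::shift_matrix(sim2$frames[[k]]$morph,
                                 -sim2$shifts[k, 1], -sim2$shifts[k, 2])
    sum(f[rows, cols] > 0)
  }, 0)
  expect_lt(area_t[1], area_t[2])        # live (nuclear only) then leaked
  expect_equal(area_t[2], area_t[3])     # dead render is static
  expect_equal(area_t[3], area_t[4])
})

test_that("identical seeds give bit-identical fields; shifts recorded", {
  cfg <- sim_config(n_cells = 6L, seed = 11L)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  for (k in seq_along(a$frames)) {
    expect_identical(a$frames[[k]]$morph, b$frames[[k]]$morph)
    expect_identical(a$frames[[k]]$gedi, b$frames[[k]]$gedi)
  }
  expect_identical(a$shifts, b$shifts)
  expect_true(all(a$shifts[1, ] == 0))
  expect_true(all(abs(a$shifts) <= cfg$drift_max))
})

test_that("impossible packing fails with an explicit message", {
  cfg <- sim_config(img_size = 160L, n_cells = 60L, seed = 1L)
  expect_error(simulate_field(cfg), "separation")
})

test_that("noise model: disabled noise reproduces the analytic template", {
  cfg <- sim_config(n_cells = 3L, seed = 2L)
  sim <- simulate_field(cfg, noise = FALSE)
  # rebuild the expected composite for timepoint 1 (no drift at t0)
  expect_true(all(sim$frames[[1]]$morph >= 0))
  # all cells render live at t = 0 (death times are post-treatment)
  r <- render_cell(list(marker = cfg$marker, alive = TRUE,
                        params = sim$truths[[1]]$params,
                        gedi_ratio = sim$truths[[1]]$ratio_live), cfg)
  off <- sim$truths[[1]]$patch_offset
  P <- cfg$patch_size
  sub <- sim$frames[[1]]$morph[(off[1] + 1):(off[1] + P),
                               (off[2] + 1):(off[2] + P)]
  expect_equal(sub, r$morph, tolerance = 1e-12)
})

test_that("dataset writing round-trips and refuses silent overwrite", {
  cfg <- sim_config(n_cells = 4L, img_size = 256L, seed = 3L)
  sim <- simulate_field(cfg)
  dir <- tempfile("ds")
  write_dataset(sim, dir)
  expect_error(write_dataset(sim, dir), "overwrite")
  back <- read_dataset(dir)
  expect_equal(nrow(back$manifest), 4)
  expect_length(back$morph, length(cfg$timepoints_h))
  for (k in seq_along(back$morph)) {
    expect_identical(back$morph[[k]], sim$frames[[k]]$morph)
    expect_identical(back$gedi[[k]], sim$frames[[k]]$gedi)
  }
  expect_equal(back$shifts$shift_row, unname(sim$shifts[, 1]))
  # masks round-trip
  tr <- sim$truths[[1]]
  key <- sprintf("cell%03d_live", tr$cell_id)
  expect_identical(back$masks[[key]]$soma, tr$masks_live$soma)
  unlink(dir, recursive = TRUE)
})
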