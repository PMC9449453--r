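# Synthetic two-channel neuron time-lapse simulator.
#
# Each simulated cell carries full ground truth: live/dead state and death
# time, phenotype masks (soma, nucleus, neurites, intranuclear punctum), the
# marker type, and the true death-indicator ratio.  The morphology channel
# renders the phenotypes the classifier must learn:
#   diffuse marker  - live: filled soma + intact neurites;
#                     dead: rounder, smaller soma + fragmented neurites
#                     (total fluorescent area strictly shrinks).
#   nuclear marker  - live: signal confined to the nucleus;
#                     dead: signal leaked over an enlarged region + fragmented
#                     neurites, plus a small dense intranuclear punctum whose
#                     peak is a configured multiple of the nuclear mean
#                     (total fluorescent area strictly grows).
# The death-indicator channel is proportional to the morphology template with
# the cell's true ratio as the constant, so the measured ratio of mask means
# recovers the truth by construction.

#' Simulation configuration
#'
#' Defaults encode the stated experimental world: fields imaged every 8 h over
#' 24 h after an excitotoxic insult, roughly half the cells dying, stage drift
#' within +/-5 px, and per-state log-normal death-indicator ratio
#' distributions that straddle the empirical live/dead thresholds
#' (diffuse 0.1/0.25, nuclear-localized 0.03/0.055).
#'
#' @param img_size field side length in pixels
#' @param patch_size per-cell render patch side (even)
#' @param n_cells cells per field
#' @param fraction_dead fraction of cells that die during the experiment
#' @param marker `"diffuse"` or `"nls"`
#' @param timepoints_h imaging times in hours, strictly increasing
#' @param death_time_h `NULL` to sample death times uniformly from the
#'   post-treatment timepoints, or a fixed hour
#' @param background camera background offset (intensity units)
#' @param gain photon gain of the Poisson-like shot-noise model; `0` disables
#'   shot noise
#' @param read_noise_sd Gaussian read-noise standard deviation; `0` disables
#' @param drift_max maximum absolute per-timepoint stage drift in pixels
#' @param soma_radius range of the soma major semi-axis (px)
#' @param soma_aspect range of the soma minor/major axis ratio
#' @param nucleus_frac range of nucleus/soma linear scale
#' @param neurite_n range (integer) of neurites per cell
#' @param neurite_len range of neurite length (px)
#' @param neurite_width neurite thickness in pixels (1 or 2)
#' @param dead_area_scale named vector: total fluorescent-area scale factor of
#'   the dead render relative to the live render, per marker
#' @param frag_keep fraction of neurite pixels surviving fragmentation
#' @param retract_frac fraction of neurite length kept after retraction
#'   (dead diffuse cells)
#' @param punctum_radius punctum radius (px)
#' @param punctum_brightness punctum peak intensity as a multiple of the
#'   surrounding nuclear mean
#' @param amp_meanlog,amp_sdlog log-normal parameters of the per-cell
#'   morphology amplitude (transfection-efficiency variation)
#' @param gedi_dist nested list `[[marker]][[state]] = c(meanlog, sdlog)` of
#'   the per-state log-normal ratio distributions
#' @param min_sep_factor minimum centroid separation as a multiple of the
#'   maximum soma diameter
#' @param seed RNG seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(img_size = 320L, patch_size = 64L, n_cells = 16L,
                       fraction_dead = 0.5, marker = c("diffuse", "nls"),
                       timepoints_h = c(0, 8, 16, 24), death_time_h = NULL,
                       background = 100, gain = 10, read_noise_sd = 20,
                       drift_max = 5L,
                       soma_radius = c(8, 14), soma_aspect = c(0.7, 1),
                       nucleus_frac = c(0.45, 0.6),
                       neurite_n = c(2L, 5L), neurite_len = c(20, 60),
                       neurite_width = 2L,
                       dead_area_scale = c(diffuse = 0.6, nls = 1.5),
                       frag_keep = 0.35, retract_frac = 0.7,
                       punctum_radius = 2, punctum_brightness = 4,
                       amp_meanlog = log(3000), amp_sdlog = 0.3,
                       gedi_dist = list(
                         diffuse = list(live = c(meanlog = log(0.05), sdlog = 0.35),
                                        dead = c(meanlog = log(0.5), sdlog = 0.35)),
                         nls = list(live = c(meanlog = log(0.02), sdlog = 0.2),
                                    dead = c(meanlog = log(0.1), sdlog = 0.3))),
                       min_sep_factor = 2, seed = 1L) {
  marker <- match.arg(marker)
  stopifnot(fraction_dead >= 0, fraction_dead <= 1,
            all(diff(timepoints_h) > 0),
            all(soma_radius > 0), all(nucleus_frac > 0),
            punctum_radius > 0, patch_size %% 2 == 0)
  if (any(unlist(lapply(gedi_dist, function(m)
    lapply(m, function(p) p[["sdlog"]] < 0)))))
    stop("gedi_dist standard deviations must be nonnegative")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Draw a death-indicator ratio for a cell state
#'
#' @param alive logical
#' @param marker `"diffuse"` or `"nls"`
#' @param config a [sim_config()]
#' @param n number of draws
#' @return numeric vector of nonnegative ratios
#' @export
sample_gedi_ratio <- function(alive, marker, config, n = 1L) {
  p <- config$gedi_dist[[marker]][[if (alive) "live" else "dead"]]
  if (any(!is.finite(p)) || p[["sdlog"]] < 0) stop("invalid ratio distribution")
  stats::rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
}

# Sample the geometry and photometry of one cell (uses the current RNG).
# Everything random about a cell is fixed here so the same cell can be
# rendered in both states.
sample_cell_params <- function(config) {
  a <- stats::runif(1, config$soma_radius[1], config$soma_radius[2])
  b <- a * stats::runif(1, config$soma_aspect[1], config$soma_aspect[2])
  theta <- stats::runif(1, 0, pi)
  nf <- stats::runif(1, config$nucleus_frac[1], config$nucleus_frac[2])
  n_neur <- sample(config$neurite_n[1]:config$neurite_n[2], 1)
  neurites <- vector("list", n_neur)
  phis <- stats::runif(n_neur, 0, 2 * pi)
  for (i in seq_len(n_neur)) {
    len <- round(stats::runif(1, config$neurite_len[1], config$neurite_len[2]))
    ang <- phis[i] + cumsum(stats::rnorm(len, 0, 0.12))
    # start just outside the soma boundary along the initial direction
    d0 <- c(cos(phis[i]), sin(phis[i]))
    u <- cos(theta) * d0[1] + sin(theta) * d0[2]
    v <- -sin(theta) * d0[1] + cos(theta) * d0[2]
    t0 <- 1 / sqrt((u / a)^2 + (v / b)^2)
    pts <- cbind(t0 * d0[1] + cumsum(cos(ang)), t0 * d0[2] + cumsum(sin(ang)))
    keep <- frag_pattern(len, config$frag_keep)
    neurites[[i]] <- list(pts = pts, keep = keep)
  }
  amp <- stats::rlnorm(1, config$amp_meanlog, config$amp_sdlog)
  # punctum center, relative to nucleus frame, guaranteed inside
  pu <- stats::runif(2, -1, 1) * 0.4
  list(a = a, b = b, theta = theta, nf = nf, neurites = neurites,
       amp = amp, punctum_rel = pu)
}

# Alternating keep/gap run pattern used for neurite fragmentation.
frag_pattern <- function(len, keep_frac) {
  keep <- logical(len)
  i <- 1L
  while (i <= len) {
    k <- sample(2:4, 1)
    g <- max(1L, round(k * (1 - keep_frac) / keep_frac))
    keep[i:min(len, i + k - 1L)] <- TRUE
    i <- i + k + sample(g:(g + 2L), 1)
  }
  keep
}

# Rasterize a polyline (offsets from patch center) into a logical matrix.
rasterize_polyline <- function(S, cr, cc, pts, keep, width = 2L) {
  m <- matrix(FALSE, S, S)
  rr <- round(cr + pts[, 1])[keep]
  cc_ <- round(cc + pts[, 2])[keep]
  ok <- rr >= 0 & rr < S & cc_ >= 0 & cc_ < S
  m[cbind(rr[ok] + 1L, cc_[ok] + 1L)] <- TRUE
  if (width >= 2L) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1))) {
      r2 <- rr + d[1]; c2 <- cc_ + d[2]
      ok <- r2 >= 0 & r2 < S & c2 >= 0 & c2 < S
      m[cbind(r2[ok] + 1L, c2[ok] + 1L)] <- TRUE
    }
  }
  m
}

#' Render one cell into a two-channel patch
#'
#' Produces the noise-free analytic template of a single cell in a square
#' patch centered on the cell, for its marker and state, together with the
#' phenotype masks of the rendered state.
#'
#' @param truth a list with fields `marker`, `alive`, `params` (from the
#'   sampler), and `gedi_ratio`
#' @param config a [sim_config()]
#' @return list with `morph`, `gedi` (numeric matrices, intensity units),
#'   `masks` (logical matrices `soma`, `nucleus`, `neurite`, `punctum`),
#'   `clipped` flag
#' @export
render_cell <- function(truth, config) {
  if (!truth$marker %in% c("diffuse", "nls")) stop("invalid marker")
  S <- config$patch_size
  p <- truth$params
  ctr <- S / 2  # 0-based center index
  soma_live <- ellipse_mask(S, S, ctr, ctr, p$a, p$b, p$theta)
  nuc_live <- ellipse_mask(S, S, ctr, ctr, p$a * p$nf, p$b * p$nf, p$theta)
  neur_live <- matrix(FALSE, S, S)
  for (nr in p$neurites) {
    neur_live <- neur_live |
      rasterize_polyline(S, ctr, ctr, nr$pts, rep(TRUE, nrow(nr$pts)),
                         config$neurite_width)
  }
  neur_live <- neur_live & !soma_live
  morph <- matrix(0, S, S)
  masks <- list(soma = soma_live, nucleus = nuc_live, neurite = neur_live,
                punctum = matrix(FALSE, S, S))

  frag_mask <- function(retract) {
    m <- matrix(FALSE, S, S)
    for (nr in p$neurites) {
      len <- nrow(nr$pts)
      keep <- nr$keep
      if (retract < 1) keep[-seq_len(max(1L, round(retract * len)))] <- FALSE
      m <- m | rasterize_polyline(S, ctr, ctr, nr$pts, keep,
                                  config$neurite_width)
    }
    m
  }

  if (truth$marker == "diffuse") {
    if (truth$alive) {
      morph[soma_live] <- p$amp
      morph[neur_live] <- 0.7 * p$amp
    } else {
      frag <- frag_mask(config$retract_frac)
      live_total <- sum(soma_live) + sum(neur_live)
      target <- config$dead_area_scale[["diffuse"]] * live_total
      r_dead <- sqrt(max(target - sum(frag & !soma_live), 12) / pi)
      soma_dead <- ellipse_mask(S, S, ctr, ctr, r_dead, r_dead, 0)
      frag <- frag & !soma_dead
      nuc_dead <- ellipse_mask(S, S, ctr, ctr, r_dead * p$nf, r_dead * p$nf, 0)
      morph[soma_dead] <- p$amp
      morph[frag] <- 0.7 * p$amp
      masks <- list(soma = soma_dead, nucleus = nuc_dead, neurite = frag,
                    punctum = matrix(FALSE, S, S))
    }
  } else {  # nuclear-localized marker
    if (truth$alive) {
      morph[nuc_live] <- p$amp
    } else {
      target <- config$dead_area_scale[["nls"]] * sum(nuc_live)
      # fragmented neurites must not blow the area budget: retract them
      # until they take at most ~a third of the target area, then size the
      # leaked region so region + fragments hit the configured scale
      q <- 1
      repeat {
        frag <- frag_mask(q)
        frag_only <- sum(frag & !nuc_live)
        if (frag_only <= 0.35 * target || q <= 0.15) break
        q <- q - 0.1
      }
      area_goal <- max(target - frag_only, 1)
      sc <- sqrt(area_goal / (pi * p$a * p$b))
      region <- ellipse_mask(S, S, ctr, ctr, p$a * sc, p$b * sc, p$theta)
      region <- region | nuc_live
      frag <- frag & !region
      leak_amp <- 0.8 * p$amp
      morph[region] <- leak_amp
      morph[frag] <- 0.7 * leak_amp
      # dense intranuclear punctum
      pr <- config$punctum_radius
      na_ <- p$a * p$nf; nb_ <- p$b * p$nf
      pu_r <- ctr + p$punctum_rel[1] * max(na_ - pr - 1, 0)
      pu_c <- ctr + p$punctum_rel[2] * max(nb_ - pr - 1, 0)
      punctum <- ellipse_mask(S, S, pu_r, pu_c, pr, pr, 0) & nuc_live
      nuc_mean <- mean(morph[nuc_live & !punctum])
      morph[punctum] <- config$punctum_brightness * nuc_mean
      masks <- list(soma = region, nucleus = nuc_live, neurite = frag,
                    punctum = punctum)
    }
  }
  gedi <- truth$gedi_ratio * morph
  border <- c(morph[1, ], morph[S, ], morph[, 1], morph[, S])
  list(morph = morph, gedi = gedi, masks = masks, clipped = any(border > 0))
}

# Camera model: Poisson-like shot noise at the configured gain, Gaussian read
# noise, constant background, clamped to the 16-bit range and rounded.
apply_noise <- function(template, config, noise = TRUE) {
  if (!noise) return(template)
  out <- template
  if (config$gain > 0) out <- stats::rpois(length(out), out / config$gain) * config$gain
  out <- out + config$background +
    stats::rnorm(length(out), 0, config$read_noise_sd)
  out <- round(pmin(pmax(out, 0), 65535))
  matrix(as.integer(out), nrow(template), ncol(template))
}

#' Simulate one imaging field over all timepoints
#'
#' Cells are placed with a minimum centroid separation, assigned live/dead
#' fates (an exact `round(n_cells * fraction_dead)` die), rendered live before
#' their death time and dead at and after it, composited into field frames,
#' shifted by a per-timepoint integer stage drift, and imaged through the
#' noise model.  Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()]
#' @param noise apply the camera noise model
#' @return object of class `sim_field`: `frames` (per timepoint, each with
#'   `gedi` and `morph` matrices and `timepoint_h`), `truths` (per cell),
#'   `shifts` (timepoints x 2 integer matrix), `config`
#' @export
simulate_field <- function(config, noise = TRUE) {
  stopifnot(config$n_cells >= 1)
  with_seed(config$seed, {
    S <- config$img_size; P <- config$patch_size
    min_sep <- config$min_sep_factor * 2 * max(config$soma_radius)
    margin <- P / 2
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < config$n_cells) {
      cand <- stats::runif(2, margin, S - margin)
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= min_sep) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1L
      if (tries > 2000L * config$n_cells) {
        stop("n_cells too large for the minimum-separation constraint; ",
             "reduce n_cells or enlarge img_size")
      }
    }
    centers <- round(centers)

    n_dead <- round(config$n_cells * config$fraction_dead)
    dead_idx <- if (n_dead > 0) sample(config$n_cells, n_dead) else integer(0)
    tp <- config$timepoints_h
    post <- tp[tp > min(tp)]
    truths <- vector("list", config$n_cells)
    renders <- vector("list", config$n_cells)
    for (i in seq_len(config$n_cells)) {
      params <- sample_cell_params(config)
      dies <- i %in% dead_idx
      dt <- if (!dies) NA_real_ else if (!is.null(config$death_time_h)) {
        config$death_time_h
      } else if (length(post)) sample(post, 1) else max(tp)
      ratio_live <- sample_gedi_ratio(TRUE, config$marker, config)
      ratio_dead <- sample_gedi_ratio(FALSE, config$marker, config)
      tl <- list(marker = config$marker, alive = TRUE, params = params,
                 gedi_ratio = ratio_live)
      td <- list(marker = config$marker, alive = FALSE, params = params,
                 gedi_ratio = ratio_dead)
      rl <- render_cell(tl, config)
      rd <- if (dies) render_cell(td, config) else NULL
      renders[[i]] <- list(live = rl, dead = rd)
      truths[[i]] <- list(
        cell_id = i, alive = !dies, death_time_h = dt, params = params,
        hours_since_death = if (dies) max(tp) - dt else NA_real_,
        marker = config$marker,
        true_gedi_ratio = if (dies) ratio_dead else ratio_live,
        ratio_live = ratio_live, ratio_dead = ratio_dead,
        center = centers[i, ],              # (row, col), 0-based, pre-drift
        patch_offset = centers[i, ] - P / 2, # top-left of patch, 0-based
        masks_live = rl$masks,
        masks_dead = if (dies) rd$masks else NULL,
        clipped = rl$clipped || (dies && rd$clipped))
    }

    shifts <- cbind(c(0L, sample(-config$drift_max:config$drift_max,
                                 length(tp) - 1, replace = TRUE)),
                    c(0L, sample(-config$drift_max:config$drift_max,
                                 length(tp) - 1, replace = TRUE)))
    colnames(shifts) <- c("row", "col")

    frames <- vector("list", length(tp))
    for (k in seq_along(tp)) {
      morph <- matrix(0, S, S); gedi <- matrix(0, S, S)
      for (i in seq_len(config$n_cells)) {
        tr <- truths[[i]]
        dead_now <- !tr$alive && tp[k] >= tr$death_time_h
        rn <- if (dead_now) renders[[i]]$dead else renders[[i]]$live
        r0 <- tr$patch_offset[1]; c0 <- tr$patch_offset[2]
        rows <- (r0 + 1):(r0 + P); cols <- (c0 + 1):(c0 + P)
        morph[rows, cols] <- morph[rows, cols] + rn$morph
        gedi[rows, cols] <- gedi[rows, cols] + rn$gedi
      }
      morph <- shift_matrix(morph, shifts[k, 1], shifts[k, 2])
      gedi <- shift_matrix(gedi, shifts[k, 1], shifts[k, 2])
      frames[[k]] <- list(gedi = apply_noise(gedi, config, noise),
                          morph = apply_noise(morph, config, noise),
                          timepoint_h = tp[k])
    }
    structure(list(frames = frames, truths = truths, shifts = shifts,
                   config = config),
              class = "sim_field")
  })
}

#' Generate a labeled single-cell crop dataset directly
#'
#' Fast path for classifier experiments: renders per-cell morphology crops
#' (through the noise model and median-background subtraction, as the imaging
#' pipeline would produce them) without compositing whole fields.
#'
#' @param n_per_class sets the dataset size (`2 * n_per_class` cells); the
#'   live/dead composition follows `config$fraction_dead` (the default 0.5
#'   gives exactly `n_per_class` of each)
#' @param marker `"diffuse"` or `"nls"`
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @param noise apply the camera noise model
#' @return list with `crops` (patch x patch x 2n array), `state` (0 live /
#'   1 dead), `gedi_ratio`, `masks` (per-crop phenotype masks), `marker`
#' @export
simulate_crop_dataset <- function(n_per_class, marker, config = sim_config(),
                                  seed = 1L, noise = TRUE) {
  with_seed(seed, {
    n <- 2L * n_per_class
    S <- config$patch_size
    crops <- array(0, c(S, S, n))
    gedi <- array(0, c(S, S, n))
    n_dead <- round(n * config$fraction_dead)
    state <- rep(c(0L, 1L), c(n - n_dead, n_dead))
    ratio <- numeric(n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      params <- sample_cell_params(config)
      alive <- state[i] == 0L
      r <- sample_gedi_ratio(alive, marker, config)
      rn <- render_cell(list(marker = marker, alive = alive, params = params,
                             gedi_ratio = r), config)
      m <- apply_noise(rn$morph, config, noise)
      g <- apply_noise(rn$gedi, config, noise)
      crops[, , i] <- subtract_background(m)
      gedi[, , i] <- subtract_background(g)
      ratio[i] <- r
      masks[[i]] <- rn$masks
    }
    list(crops = crops, gedi = gedi, state = state, gedi_ratio = ratio,
         masks = masks, marker = marker)
  })
}

#' Write a simulated field to disk
#'
#' Layout: one multi-page 16-bit TIFF per channel (page order = timepoint
#' order), a UTF-8 CSV manifest of per-cell ground truth, a CSV of applied
#' stage drifts, and per-cell multi-page 8-bit mask TIFFs (pages soma,
#' nucleus, neurite, punctum) per rendered state.
#'
#' @param sim a `sim_field` from [simulate_field()]
#' @param out_dir output directory (created if needed)
#' @param overwrite overwrite existing files
#' @return `out_dir`, invisibly
#' @export
write_dataset <- function(sim, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(man_path) && !overwrite) {
    stop("dataset already exists in ", out_dir, "; use overwrite = TRUE")
  }
  write_tiff(lapply(sim$frames, `[[`, "gedi"),
             file.path(out_dir, "field_gedi.tif"))
  write_tiff(lapply(sim$frames, `[[`, "morph"),
             file.path(out_dir, "field_morph.tif"))
  man <- do.call(rbind, lapply(sim$truths, function(tr) {
    data.frame(cell_id = tr$cell_id, marker = tr$marker, alive = tr$alive,
               death_time_h = tr$death_time_h,
               true_gedi_ratio = tr$true_gedi_ratio,
               ratio_live = tr$ratio_live, ratio_dead = tr$ratio_dead,
               center_row = tr$center[1], center_col = tr$center[2],
               clipped = tr$clipped)
  }))
  utils::write.csv(man, man_path, row.names = FALSE)
  utils::write.csv(data.frame(timepoint_h = vapply(sim$frames, `[[`, 0,
                                                   "timepoint_h"),
                              shift_row = sim$shifts[, 1],
                              shift_col = sim$shifts[, 2]),
                   file.path(out_dir, "shifts.csv"), row.names = FALSE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (tr in sim$truths) {
    for (st in c("live", "dead")) {
      mk <- tr[[paste0("masks_", st)]]
      if (is.null(mk)) next
      pages <- lapply(mk[c("soma", "nucleus", "neurite", "punctum")],
                      function(m) matrix(as.integer(m) * 255L,
                                         nrow(m), ncol(m)))
      write_tiff(pages, file.path(mask_dir,
                                  sprintf("cell%03d_%s.tif", tr$cell_id, st)),
                 bits = 8L)
    }
  }
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory
#' @return list with `gedi`, `morph` (lists of matrices per timepoint),
#'   `manifest`, `shifts` (data frames), and `masks` (per cell and state)
#' @export
read_dataset <- function(dir) {
  gedi <- read_tiff(file.path(dir, "field_gedi.tif"))
  morph <- read_tiff(file.path(dir, "field_morph.tif"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  shifts <- utils::read.csv(file.path(dir, "shifts.csv"))
  mask_files <- list.files(file.path(dir, "masks"), full.names = TRUE)
  masks <- list()
  for (f in mask_files) {
    key <- sub("\\.tif$", "", basename(f))
    pg <- read_tiff(f)
    names(pg) <- c("soma", "nucleus", "neurite", "punctum")
    masks[[key]] <- lapply(pg, function(m) m > 0)
  }
  list(gedi = gedi, morph = morph, manifest = manifest, shifts = shifts,
       masks = masks)
}
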