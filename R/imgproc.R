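# Image-processing workflow: median background subtraction, longitudinal
# registration by phase correlation, threshold segmentation with connected
# components, greedy centroid tracking, and centroid-centered crops.
#
# Conventions (stated once, used everywhere): pixel coordinates are 0-based
# (row, col); crop windows are half-open; the registration reference is the
# first timepoint.

#' Median background subtraction
#'
#' Subtracts the median intensity of the whole image and clips at zero.
#'
#' @param frame numeric matrix, finite
#' @return matrix of the same shape
#' @export
subtract_background <- function(frame) {
  if (length(frame) == 0) stop("empty frame")
  if (!all(is.finite(frame))) stop("frame contains non-finite values")
  pmax(frame - stats::median(frame), 0)
}

#' Register a longitudinal stack to its first frame
#'
#' Integer-precision phase correlation against the first timepoint.  The
#' estimated shift of frame k is the translation that maps the reference onto
#' frame k (positive = content moved down/right); aligned frames are shifted
#' back by the negated estimate with zero fill.
#'
#' @param stack list of numeric matrices with identical shape
#' @return list with `shifts` (n x 2 integer matrix), `aligned` (list of
#'   matrices), `flags` (character vector, `"blank"` where a frame was
#'   all-zero)
#' @export
register_timepoints <- function(stack) {
  stopifnot(length(stack) >= 2)
  dims <- dim(stack[[1]])
  for (f in stack) stopifnot(identical(dim(f), dims))
  ref <- stack[[1]]
  H <- dims[1]; W <- dims[2]
  Fr <- stats::fft(ref)
  n <- length(stack)
  shifts <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  flags <- character(n)
  aligned <- vector("list", n)
  aligned[[1]] <- ref
  for (k in 2:n) {
    fk <- stack[[k]]
    if (all(fk == 0) || all(ref == 0)) {
      flags[k] <- "blank"
      aligned[[k]] <- fk
      next
    }
    R <- stats::fft(fk) * Conj(Fr)
    mag <- Mod(R)
    R <- R / pmax(mag, 1e-12)
    corr <- Re(stats::fft(R, inverse = TRUE))
    pk <- which.max(corr) - 1L
    dr <- pk %% H
    dc <- pk %/% H
    if (dr > H / 2) dr <- dr - H
    if (dc > W / 2) dc <- dc - W
    shifts[k, ] <- c(dr, dc)
    aligned[[k]] <- shift_matrix(fk, -dr, -dc)
  }
  list(shifts = shifts, aligned = aligned, flags = flags)
}

#' Segment cells in a background-subtracted frame
#'
#' Global threshold (Otsu by default, or a fixed value), 8-connected
#' components, small components discarded, intensity-weighted centroids, and
#' per-channel mean intensities over each component mask.
#'
#' @param frame background-subtracted numeric matrix (the channel to segment,
#'   conventionally the morphology channel)
#' @param channels named list of intensity matrices over which mean
#'   intensities are measured (defaults to `list(morph = frame)`)
#' @param min_area minimum component area in pixels
#' @param threshold `"otsu"` or a fixed numeric threshold
#' @return list of cell observations; each has `cell_label`, `mask` (logical
#'   matrix), `centroid` ((row, col), 0-based, intensity-weighted), `area_px`,
#'   `mean_intensity` (named numeric)
#' @export
segment_cells <- function(frame, channels = list(morph = frame),
                          min_area = 30L, threshold = "otsu") {
  # Otsu on percentile-clipped intensities: a handful of very bright pixels
  # (e.g. the dense intranuclear punctum) must not drag the threshold above
  # the cell body.
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(pmin(frame, stats::quantile(frame, 0.995)))
  } else as.numeric(threshold)
  bin <- frame > thr
  if (!any(bin)) return(list())
  lab <- .label_components(bin)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  out <- list()
  nxt <- 1L
  for (id in ids) {
    mask <- lab == id
    area <- sum(mask)
    if (area < min_area) next
    w <- frame[mask]
    idx <- which(mask, arr.ind = TRUE) - 1  # 0-based
    if (sum(w) <= 0) w <- rep(1, length(w))
    centroid <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
    mi <- vapply(channels, function(ch) mean(ch[mask]), 0)
    out[[nxt]] <- list(cell_label = nxt, mask = mask, centroid = centroid,
                       area_px = area, mean_intensity = mi)
    nxt <- nxt + 1L
  }
  out
}

#' Track cells across timepoints by greedy nearest-centroid matching
#'
#' Consecutive timepoints are linked by repeatedly matching the globally
#' closest (track, observation) pair within `max_displacement`; distance ties
#' break toward the smaller cell label.  Unmatched observations seed new
#' tracks.
#'
#' @param obs_by_tp list over timepoints; each element is a list of
#'   observations from [segment_cells()] plus a `timepoint_h` attribute, or a
#'   list `list(timepoint_h =, observations =)`
#' @param max_displacement maximum allowed centroid displacement (px)
#' @return list of tracks: `track_id`, `observations` (each observation
#'   gains a `timepoint_h` field)
#' @export
track_cells <- function(obs_by_tp, max_displacement = 30) {
  norm_tp <- lapply(obs_by_tp, function(el) {
    if (!is.null(el$observations)) el
    else list(timepoint_h = attr(el, "timepoint_h"), observations = el)
  })
  for (el in norm_tp) {
    labs <- vapply(el$observations, function(o) as.numeric(o$cell_label), 0)
    if (anyDuplicated(labs)) stop("duplicate cell_label within a timepoint")
  }
  tracks <- list()
  active <- integer(0)  # track index ending at previous timepoint
  for (k in seq_along(norm_tp)) {
    obs <- norm_tp[[k]]$observations
    tp <- norm_tp[[k]]$timepoint_h
    matched_obs <- rep(FALSE, length(obs))
    matched_tr <- rep(FALSE, length(active))
    if (length(active) && length(obs)) {
      prev_cent <- t(vapply(active, function(ti) {
        tr <- tracks[[ti]]
        tr$observations[[length(tr$observations)]]$centroid
      }, c(0, 0)))
      cur_cent <- t(vapply(obs, `[[`, c(0, 0), "centroid"))
      D <- outer(seq_len(nrow(prev_cent)), seq_len(nrow(cur_cent)),
                 Vectorize(function(i, j)
                   sqrt(sum((prev_cent[i, ] - cur_cent[j, ])^2))))
      repeat {
        ok <- which(D <= max_displacement & !is.na(D), arr.ind = TRUE)
        if (nrow(ok) == 0) break
        dv <- D[ok]
        best <- ok[order(dv, ok[, 2], ok[, 1])[1], , drop = TRUE]
        ti <- best[1]; oj <- best[2]
        o <- obs[[oj]]
        o$timepoint_h <- tp
        tri <- active[ti]
        tracks[[tri]]$observations <-
          c(tracks[[tri]]$observations, list(o))
        matched_tr[ti] <- TRUE
        matched_obs[oj] <- TRUE
        D[ti, ] <- NA
        D[, oj] <- NA
      }
    }
    for (j in which(!matched_obs)) {
      o <- obs[[j]]
      o$timepoint_h <- tp
      tracks[[length(tracks) + 1]] <-
        list(track_id = length(tracks) + 1L, observations = list(o))
    }
    # active tracks for the next timepoint: those extended or started now
    ext <- active[matched_tr]
    new <- setdiff(seq_along(tracks), seq_len(length(tracks) - sum(!matched_obs)))
    active <- c(ext, new)
  }
  tracks
}

#' Extract a centroid-centered square crop
#'
#' Half-open window rows `[r - s/2, r + s/2)`, cols `[c - s/2, c + s/2)` with
#' `(r, c)` the rounded 0-based centroid; pixels outside the frame are zero
#' and counted in `pad_fraction`.
#'
#' @param frame numeric matrix
#' @param centroid (row, col), 0-based
#' @param crop_size even integer >= 16
#' @return list `pixels` (crop_size x crop_size), `pad_fraction`, `center`
#' @export
extract_crop <- function(frame, centroid, crop_size = 64L) {
  stopifnot(crop_size %% 2 == 0, crop_size >= 16)
  H <- nrow(frame); W <- ncol(frame)
  r <- round(centroid[1]); c <- round(centroid[2])
  if (r < 0 || r >= H || c < 0 || c >= W) stop("centroid outside frame")
  s <- crop_size
  out <- matrix(0, s, s)
  rows <- (r - s / 2):(r + s / 2 - 1)  # 0-based
  cols <- (c - s / 2):(c + s / 2 - 1)
  rin <- rows >= 0 & rows < H
  cin <- cols >= 0 & cols < W
  out[which(rin), which(cin)] <- frame[rows[rin] + 1, cols[cin] + 1]
  pad <- 1 - sum(rin) * sum(cin) / (s * s)
  list(pixels = out, pad_fraction = pad, center = c(r, c))
}

#' Run the full imaging workflow on a simulated field
#'
#' Background subtraction, registration to the first timepoint, segmentation
#' of the morphology channel, tracking, and per-observation feature
#' extraction.
#'
#' @param sim a `sim_field` (or the list returned by [read_dataset()], with
#'   `morph`/`gedi` as lists of matrices and timepoints from `shifts`)
#' @param min_area,threshold,max_displacement,crop_size see the stage
#'   functions
#' @return list with `features` (data frame: cell_label, timepoint_h,
#'   centroid_row, centroid_col, area_px, fluor_area_px, mean_gedi,
#'   mean_morph),
#'   `tracks`, `crops` (list of centroid-centered morphology crops with
#'   metadata), `shifts` (recovered registration shifts), `aligned`
#' @export
process_field <- function(sim, min_area = 30L, threshold = "otsu",
                          max_displacement = 30, crop_size = 64L) {
  if (inherits(sim, "sim_field")) {
    morph <- lapply(sim$frames, `[[`, "morph")
    gedi <- lapply(sim$frames, `[[`, "gedi")
    tps <- vapply(sim$frames, `[[`, 0, "timepoint_h")
  } else {
    morph <- sim$morph; gedi <- sim$gedi
    tps <- sim$shifts$timepoint_h
  }
  morph <- lapply(morph, subtract_background)
  gedi <- lapply(gedi, subtract_background)
  reg <- register_timepoints(morph)
  morph <- reg$aligned
  gedi <- lapply(seq_along(gedi), function(k)
    shift_matrix(gedi[[k]], -reg$shifts[k, 1], -reg$shifts[k, 2]))
  obs_by_tp <- lapply(seq_along(morph), function(k) {
    obs <- segment_cells(morph[[k]],
                         channels = list(morph = morph[[k]], gedi = gedi[[k]]),
                         min_area = min_area, threshold = threshold)
    list(timepoint_h = tps[k], observations = obs)
  })
  tracks <- track_cells(obs_by_tp, max_displacement = max_displacement)
  thr_by_tp <- vapply(morph, function(m)
    otsu_threshold(pmin(m, stats::quantile(m, 0.995))), 0)
  rows <- list()
  crops <- list()
  for (tr in tracks) {
    for (o in tr$observations) {
      k <- match(o$timepoint_h, tps)
      cr <- extract_crop(morph[[k]], o$centroid, crop_size)
      crops[[length(crops) + 1]] <- list(
        pixels = cr$pixels, pad_fraction = cr$pad_fraction,
        cell_label = tr$track_id, timepoint_h = o$timepoint_h)
      rows[[length(rows) + 1]] <- data.frame(
        cell_label = tr$track_id, timepoint_h = o$timepoint_h,
        centroid_row = o$centroid[1], centroid_col = o$centroid[2],
        area_px = o$area_px,
        # fluorescent area: all above-threshold pixels near the cell, so
        # detached neurite fragments still count toward the cell's area
        fluor_area_px = sum(cr$pixels > thr_by_tp[k]),
        mean_gedi = o$mean_intensity[["gedi"]],
        mean_morph = o$mean_intensity[["morph"]])
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_label = integer(0), timepoint_h = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               area_px = integer(0), fluor_area_px = integer(0),
               mean_gedi = numeric(0), mean_morph = numeric(0))
  list(features = features, tracks = tracks, crops = crops,
       shifts = reg$shifts, aligned = morph)
}
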