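# Weak labeling from the ratiometric death-indicator signal: per-cell ratio,
# three-way bucketing against empirical thresholds (boundary values fall in
# the intermediate bucket, which is discarded before training), stratified
# train/validation/test splitting with largest-remainder rounding, and class
# balancing.

#' Labeling configuration
#'
#' Default thresholds are the empirical values for each marker: cells under
#' `theta_live` are labeled live, above `theta_dead` dead, and everything in
#' between (inclusive) is an ambiguous intermediate discarded from training.
#'
#' @param marker `"diffuse"` (defaults 0.1 / 0.25) or `"nls"` (defaults
#'   0.03 / 0.055)
#' @param theta_live,theta_dead override the marker defaults
#' @return object of class `labeling_config`
#' @export
labeling_config <- function(marker = c("diffuse", "nls"),
                            theta_live = NULL, theta_dead = NULL) {
  marker <- match.arg(marker)
  defaults <- list(diffuse = c(0.1, 0.25), nls = c(0.03, 0.055))[[marker]]
  theta_live <- theta_live %||% defaults[1]
  theta_dead <- theta_dead %||% defaults[2]
  stopifnot(0 < theta_live, theta_live < theta_dead)
  structure(list(marker = marker, theta_live = theta_live,
                 theta_dead = theta_dead),
            class = "labeling_config")
}

#' Ratiometric death-indicator ratio
#'
#' Mean death-indicator intensity normalized to the mean morphology-marker
#' intensity of the same cell.
#'
#' @param mean_gedi,mean_morph per-cell mean intensities
#' @return ratio; `NA` (flagged invalid) where `mean_morph <= 0`
#' @export
compute_gedi_ratio <- function(mean_gedi, mean_morph) {
  out <- mean_gedi / mean_morph
  out[mean_morph <= 0] <- NA_real_
  out
}

#' Bucket ratios into live / intermediate / dead
#'
#' @param ratio nonnegative numeric vector
#' @param config a [labeling_config()]
#' @return factor with levels live, intermediate, dead
#' @export
bucket_label <- function(ratio, config) {
  if (any(ratio < 0, na.rm = TRUE)) stop("negative ratio")
  out <- ifelse(ratio < config$theta_live, "live",
                ifelse(ratio > config$theta_dead, "dead", "intermediate"))
  factor(out, levels = c("live", "intermediate", "dead"))
}

# Largest-remainder apportionment of n into parts proportional to fractions.
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a labeled dataset into train / validation / test
#'
#' Split sizes follow largest-remainder rounding of `n * fractions`;
#' assignment is a seeded shuffle, stratified by label (largest-remainder
#' within each label, then merged) so class balance is preserved per split.
#'
#' @param labels binary label vector (0 live / 1 dead)
#' @param fractions length-3 vector summing to 1 (train, val, test)
#' @param seed RNG seed
#' @param stratify stratify by label (default TRUE)
#' @return factor of `"train"`, `"val"`, `"test"` along `labels`
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          stratify = TRUE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  n <- length(labels)
  if (stratify && length(unique(labels)) < 2) {
    stop("a class is absent; cannot stratify the split")
  }
  out <- character(n)
  groups <- if (stratify) split(seq_len(n), labels) else list(seq_len(n))
  with_seed(seed, {
    for (idx in groups) {
      sizes <- largest_remainder(length(idx), fractions)
      if (any(sizes < 1)) stop("a split is empty after rounding")
      sh <- sample(idx)
      out[sh] <- rep(c("train", "val", "test"), sizes)
    }
  })
  factor(out, levels = c("train", "val", "test"))
}

#' Balance classes by downsampling the majority class
#'
#' @param labels binary label vector
#' @param seed RNG seed
#' @param mode only `"downsample"` is implemented
#' @return integer indices of the retained elements (live:dead 1:1)
#' @export
balance_classes <- function(labels, seed = 1L, mode = "downsample") {
  stopifnot(mode == "downsample")
  idx0 <- which(labels == 0)
  idx1 <- which(labels == 1)
  if (length(idx0) == 0 || length(idx1) == 0) stop("a class is empty")
  m <- min(length(idx0), length(idx1))
  with_seed(seed, {
    keep <- c(if (length(idx0) > m) sample(idx0, m) else idx0,
              if (length(idx1) > m) sample(idx1, m) else idx1)
  })
  sort(keep)
}

#' Per-crop channel means over the segmentation mask
#'
#' Segments each morphology crop (Otsu threshold, largest 8-connected
#' component) and measures the mean of both channels over that mask — the
#' mask-based convention used throughout the pipeline, which keeps background
#' pixels out of the ratio.
#'
#' @param morph,gedi H x W x N arrays of matched crops
#' @param min_area minimum component area; crops with no component yield NA
#' @return data frame with `mean_gedi`, `mean_morph`
#' @export
measure_crop_means <- function(morph, gedi, min_area = 30L) {
  n <- dim(morph)[3]
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    obs <- segment_cells(morph[, , i], channels = list(
      morph = morph[, , i], gedi = gedi[, , i]), min_area = min_area)
    if (length(obs) == 0) next
    areas <- vapply(obs, `[[`, 0L, "area_px")
    o <- obs[[which.max(areas)]]
    out[i, ] <- c(o$mean_intensity[["gedi"]], o$mean_intensity[["morph"]])
  }
  data.frame(mean_gedi = out[, 1], mean_morph = out[, 2])
}

#' Assemble a labeled crop dataset from features and crops
#'
#' Computes ratios, buckets them, drops intermediates and invalid records,
#' optionally balances classes, and assigns splits.
#'
#' @param crops list of crops (each with `pixels`) or a 3D array
#' @param mean_gedi,mean_morph per-crop mean intensities
#' @param config a [labeling_config()]
#' @param fractions split fractions
#' @param balance balance classes before splitting
#' @param seed RNG seed
#' @return object of class `labeled_dataset`: `crops` (H x W x N array),
#'   `labels` (0 live / 1 dead), `gedi_ratio`, `bucket`, `split`, `kept`
#'   (indices into the input retained after filtering)
#' @export
build_labeled_dataset <- function(crops, mean_gedi, mean_morph, config,
                                  fractions = c(0.8, 0.1, 0.1),
                                  balance = TRUE, seed = 1L) {
  ratio <- compute_gedi_ratio(mean_gedi, mean_morph)
  bucket <- bucket_label(ratio, config)
  keep <- which(!is.na(ratio) & bucket != "intermediate")
  labels <- as.integer(bucket[keep] == "dead")
  if (balance) {
    bal <- balance_classes(labels, seed = derive_seed(seed, "balance"))
    keep <- keep[bal]
    labels <- labels[bal]
  }
  if (length(unique(labels)) < 2) stop("a class is absent after labeling")
  split <- split_dataset(labels, fractions, seed = derive_seed(seed, "split"))
  if (is.array(crops) && length(dim(crops)) == 3) {
    arr <- crops[, , keep, drop = FALSE]
  } else {
    S <- nrow(crops[[1]]$pixels)
    arr <- array(0, c(S, S, length(keep)))
    for (i in seq_along(keep)) arr[, , i] <- crops[[keep[i]]]$pixels
  }
  structure(list(crops = arr, labels = labels, gedi_ratio = ratio[keep],
                 bucket = droplevels(bucket[keep]), split = split,
                 kept = keep),
            class = "labeled_dataset")
}
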