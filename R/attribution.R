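# Guided Grad-CAM feature-importance maps and quantitative localization
# against ground-truth phenotype masks.
#
# Grad-CAM at a chosen layer: channel weights are the spatial means of the
# class-score gradient, the weighted activation sum is ReLU'd and bilinearly
# upsampled to crop size.  The guided variant multiplies elementwise with the
# guided-backpropagation input gradient (negative gradients zeroed at every
# ReLU on the backward pass), clips at zero and normalizes to unit sum.

#' Guided Grad-CAM attribution for one crop
#'
#' @param model a trained `death_model`
#' @param crop numeric matrix (raw intensities; normalized internally)
#' @param target_class `"live"` or `"dead"` (or 0/1)
#' @param layer 1-based layer index whose output activations are used;
#'   defaults to the model's mid-depth residual stage (`model$cam_layer`)
#' @return object of class `attribution_map`: `importance` (same shape as
#'   crop, nonnegative, sums to 1 unless all-zero), `target_class`, `layer`,
#'   `flag` (`"zero"` when the map vanished everywhere)
#' @export
guided_gradcam <- function(model, crop, target_class, layer = NULL) {
  layer <- layer %||% model$cam_layer
  if (layer < 1 || layer > length(model$layers)) stop("layer does not exist")
  if (is.character(target_class)) {
    target_class <- match(match.arg(target_class, c("live", "dead")),
                          c("live", "dead")) - 1L
  }
  if (!target_class %in% c(0L, 1L)) stop("invalid class index")
  S <- nrow(crop)
  if (max(crop) == min(crop)) {
    # constant crop: no features to attribute
    return(structure(list(importance = matrix(0, S, ncol(crop)),
                          target_class = target_class, layer = layer,
                          flag = "zero"),
                     class = "attribution_map"))
  }
  x <- normalize_crops(crop)
  bw <- .nn_backward(model$layers, model$weights, crops_to_input(x),
                     S, ncol(crop), 1L, 1L, as.integer(target_class),
                     "class", TRUE, as.integer(layer), TRUE)
  dm <- bw$cam_dims  # H', W', C, N
  act <- bw$cam_act
  grad <- bw$cam_grad
  alpha <- rowMeans(grad)               # GAP of gradients per channel
  cam_flat <- as.numeric(alpha %*% act) # weighted activation sum
  cam <- matrix(pmax(cam_flat, 0), dm[1], dm[2])
  cam_up <- upsample_bilinear(cam, S, ncol(crop))
  gbp <- matrix(as.numeric(bw$input_grad), S, ncol(crop))
  imp <- pmax(cam_up * gbp, 0)
  tot <- sum(imp)
  flag <- NA_character_
  if (tot > 0) {
    imp <- imp / tot
  } else {
    flag <- "zero"
  }
  structure(list(importance = imp, target_class = target_class,
                 layer = layer, flag = flag),
            class = "attribution_map")
}

#' Attribution mass overlap with phenotype masks
#'
#' For each mask: the fraction of attribution mass inside it, the mask's area
#' fraction of the crop, and the enrichment (mass fraction / area fraction;
#' 1 = no localization).
#'
#' @param attribution an `attribution_map` (or a nonnegative matrix)
#' @param masks named list of logical matrices with the crop's shape
#' @return data frame with columns mask, mass_in_mask, mask_area_fraction,
#'   enrichment (`NA` enrichment for empty masks)
#' @export
overlap_score <- function(attribution, masks) {
  imp <- if (inherits(attribution, "attribution_map")) {
    attribution$importance
  } else attribution
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    stopifnot(identical(dim(m), dim(imp)))
    af <- mean(m)
    mi <- sum(imp[m])
    data.frame(mask = nm, mass_in_mask = mi, mask_area_fraction = af,
               enrichment = if (af > 0) mi / af else NA_real_)
  })
  do.call(rbind, rows)
}

#' Cohort-level attribution localization summary
#'
#' Computes guided Grad-CAM maps for correctly classified crops of each
#' class (attributed to the predicted class) and summarizes the mean
#' enrichment per phenotype mask.  The nuclear-membrane mask is derived as
#' the 2-px inner boundary ring of the nucleus mask.
#'
#' @param model a trained `death_model`
#' @param crops H x W x N array
#' @param labels 0/1 truth vector
#' @param masks per-crop named lists of phenotype masks (as produced by
#'   [simulate_crop_dataset()])
#' @param n_per_class maps computed per class (among correct predictions)
#' @param layer attribution layer (default `model$cam_layer`)
#' @param seed RNG seed for the per-class subsample
#' @return list with `summary` (data frame: class, mask, mean_enrichment, n;
#'   class `"live_on_dead"` rows score live-class maps on dead crops so the
#'   punctum contrast compares both classes on crops that have a punctum),
#'   `per_crop` (data frame of individual enrichments), `flag` (set when a
#'   class had fewer than `n_per_class` correct crops)
#' @export
cohort_localization <- function(model, crops, labels, masks,
                                n_per_class = 20L, layer = NULL, seed = 1L) {
  ev <- evaluate_model(model, crops, labels)
  correct <- which(ev$pred == labels)
  flag <- NA_character_
  per <- list()
  with_seed(seed, {
    for (cls in 0:1) {
      pool <- correct[labels[correct] == cls]
      if (length(pool) < n_per_class) {
        flag <- "insufficient correct classifications"
      }
      take <- if (length(pool) > n_per_class) sample(pool, n_per_class)
              else pool
      for (i in take) {
        am <- guided_gradcam(model, crops[, , i], cls, layer = layer)
        mk <- masks[[i]]
        mlist <- list(soma = mk$soma, nucleus = mk$nucleus,
                      neurite = mk$neurite,
                      nuclear_membrane = mask_boundary(mk$nucleus, 2L))
        if (any(mk$punctum)) mlist$punctum <- mk$punctum
        os <- overlap_score(am, mlist)
        os$class <- c("live", "dead")[cls + 1]
        os$crop <- i
        per[[length(per) + 1]] <- os
        if (cls == 1L && any(mk$punctum)) {
          # counterfactual live-class map on the same dead crop: the live/dead
          # punctum contrast requires both classes scored on crops that have
          # a punctum
          am0 <- guided_gradcam(model, crops[, , i], 0L, layer = layer)
          os0 <- overlap_score(am0, mlist["punctum"])
          os0$class <- "live_on_dead"
          os0$crop <- i
          per[[length(per) + 1]] <- os0
        }
      }
    }
  })
  per_crop <- do.call(rbind, per)
  agg <- stats::aggregate(enrichment ~ class + mask, per_crop, mean,
                          na.action = stats::na.omit)
  names(agg)[names(agg) == "enrichment"] <- "mean_enrichment"
  cnt <- stats::aggregate(crop ~ class + mask, per_crop, length)
  agg$n <- cnt$crop[match(paste(agg$class, agg$mask),
                          paste(cnt$class, cnt$mask))]
  list(summary = agg, per_crop = per_crop, flag = flag)
}
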