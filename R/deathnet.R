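# Biomarker-optimized convolutional classifier: residual architectures,
# Adam training with validation-loss checkpoint selection, evaluation, and
# zero-shot cross-marker testing.
#
# Two architectures are available: `resnet18`, the standard 18-layer residual
# network (batch normalization replaced by He initialization: pretrained and
# normalized variants are not reproducible offline), and `smallresnet`, a
# 4-residual-block reduction used for desk-scale experiments.  Convolution
# weights are stored as (C_out x C_in*k*k) matrices consumed directly by the
# im2col GEMM engine in src/nn.cpp.

conv_he_init <- function(k, cin, cout) {
  fan_in <- k * k * cin
  matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}

new_net_builder <- function() {
  env <- new.env()
  env$weights <- list()
  env$layers <- list()
  env$add_w <- function(w) {
    env$weights[[length(env$weights) + 1]] <- w
    length(env$weights)
  }
  env$conv <- function(k, stride, pad, cin, cout, relu = TRUE) {
    wi <- env$add_w(conv_he_init(k, cin, cout))
    bi <- env$add_w(matrix(0, cout, 1))
    env$layers[[length(env$layers) + 1]] <- list(
      type = "conv", k = k, stride = stride, pad = pad, relu = relu,
      w = wi, b = bi)
  }
  env$maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
    env$layers[[length(env$layers) + 1]] <- list(
      type = "maxpool", k = k, stride = stride, pad = pad)
  }
  env$resblock <- function(cin, cout, stride = 1L) {
    w1 <- env$add_w(conv_he_init(3, cin, cout))
    b1 <- env$add_w(matrix(0, cout, 1))
    # zero-init the residual branch output (batch-norm-free analog of
    # zero-init gamma): blocks start as identity, which stabilizes training
    w2 <- env$add_w(matrix(0, cout, 3 * 3 * cout))
    b2 <- env$add_w(matrix(0, cout, 1))
    l <- list(type = "resblock", stride = stride,
              w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    if (stride != 1L || cin != cout) {
      l$wp <- env$add_w(conv_he_init(1, cin, cout))
      l$bp <- env$add_w(matrix(0, cout, 1))
    }
    env$layers[[length(env$layers) + 1]] <- l
  }
  env$gap <- function() {
    env$layers[[length(env$layers) + 1]] <- list(type = "gap")
  }
  env$fc <- function(cin, cout = 2L) {
    wi <- env$add_w(matrix(stats::rnorm(cout * cin, 0, sqrt(1 / cin)),
                           cout, cin))
    bi <- env$add_w(matrix(0, cout, 1))
    env$layers[[length(env$layers) + 1]] <- list(
      type = "fc", w = wi, b = bi)
  }
  env
}

#' Build a live/dead classifier model
#'
#' @param architecture `"smallresnet"` (default; 4 residual blocks) or
#'   `"resnet18"` (standard 18-layer residual network)
#' @param input_size crop side length in pixels
#' @param base_channels stem width of `smallresnet`
#' @param seed RNG seed for the (He) random initialization
#' @return object of class `death_model`: `architecture`, `layers`,
#'   `weights`, `input_size`, `cam_layer` (default attribution layer: the
#'   mid-depth residual stage, "layer two" for resnet18), `history`,
#'   `selected_step`
#' @export
build_model <- function(architecture = c("smallresnet", "resnet18"),
                        input_size = 64L, base_channels = 8L, seed = 1L) {
  architecture <- match.arg(architecture)
  b <- new_net_builder()
  with_seed(seed, {
    if (architecture == "smallresnet") {
      c1 <- base_channels
      b$conv(3, 2, 1, 1, c1)            # 1: stem, /2
      b$maxpool()                       # 2: /4 (stem downsampling as in the
      b$resblock(c1, c1)                # 3     18-layer network)
      b$conv(3, 2, 1, c1, 2 * c1)       # 4: /8
      b$resblock(2 * c1, 2 * c1)        # 5  <- mid-depth attribution layer
      b$conv(3, 2, 1, 2 * c1, 4 * c1)   # 6: /16
      b$resblock(4 * c1, 4 * c1)        # 7
      b$resblock(4 * c1, 4 * c1)        # 8
      b$gap()                           # 9
      b$fc(4 * c1)                      # 10
      cam <- 5L
    } else {
      b$conv(7, 2, 3, 1, 64)            # 1: stem, /2
      b$maxpool()                       # 2: /4
      b$resblock(64, 64)                # 3
      b$resblock(64, 64)                # 4
      b$resblock(64, 128, stride = 2L)  # 5: /8
      b$resblock(128, 128)              # 6  <- "layer two" stage output
      b$resblock(128, 256, stride = 2L) # 7: /16
      b$resblock(256, 256)              # 8
      b$resblock(256, 512, stride = 2L) # 9: /32
      b$resblock(512, 512)              # 10
      b$gap()                           # 11
      b$fc(512)                         # 12
      cam <- 6L
    }
  })
  structure(list(architecture = architecture, layers = b$layers,
                 weights = b$weights, input_size = as.integer(input_size),
                 cam_layer = cam, history = NULL, selected_step = 0L),
            class = "death_model")
}

#' Min-max normalize crops to [0, 1] per crop
#'
#' @param crops H x W x N array (or a matrix for a single crop)
#' @return array of the same shape
#' @export
normalize_crops <- function(crops) {
  if (is.matrix(crops)) crops <- array(crops, c(dim(crops), 1))
  for (i in seq_len(dim(crops)[3])) {
    x <- crops[, , i]
    rng <- range(x)
    crops[, , i] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
                    else x * 0
  }
  crops
}

# Flatten an (H, W, N) crop array into the engine's channel-major matrix.
crops_to_input <- function(crops) {
  matrix(as.numeric(crops), nrow = 1)
}

model_forward <- function(model, crops, batch = 256L) {
  d <- dim(crops)
  n <- d[3]
  logits <- matrix(0, 2, n)
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    x <- crops_to_input(crops[, , s:e, drop = FALSE])
    logits[, s:e] <- .nn_forward(model$layers, model$weights, x,
                                 d[1], d[2], 1L, e - s + 1L)
  }
  logits
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

mean_ce_loss <- function(logits, y) {
  p <- softmax_cols(logits)
  -mean(log(pmax(p[cbind(y + 1L, seq_along(y))], 1e-300)))
}

#' Training configuration
#'
#' Defaults follow the training recipe: batches of 32 images, learning rate
#' 1e-3, Adam.  `max_steps` defaults to the desk-scale 2,000 (the full-scale
#' run used 200,000); validation loss is evaluated every `val_every` steps
#' and the checkpoint with the lowest validation loss is selected.
#'
#' @param batch_size,learning_rate,max_steps,val_every,seed scalars
#' @return list of class `train_config`
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         max_steps = 2000L, val_every = 100L, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_steps >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier on a labeled crop dataset
#'
#' Minimizes two-class cross-entropy with Adam; crops are min-max normalized
#' per crop.  Returns the model at the checkpoint with the lowest validation
#' loss (never simply the last step), with the training history attached.
#'
#' @param model a [build_model()] result
#' @param dataset a `labeled_dataset` (crops, labels, split) or a list with
#'   `crops`, `labels`, `split`
#' @param config a [train_config()]
#' @return the trained `death_model` (fields `history`, `selected_step`
#'   filled in)
#' @export
train_model <- function(model, dataset, config = train_config()) {
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "val")
  stopifnot(length(tr_idx) > 0, length(va_idx) > 0)
  crops <- normalize_crops(dataset$crops)
  y <- as.integer(dataset$labels)
  d <- dim(crops)
  xval <- crops[, , va_idx, drop = FALSE]
  yval <- y[va_idx]

  W <- model$weights
  mAdam <- lapply(W, function(w) w * 0)
  vAdam <- lapply(W, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate

  val_loss_of <- function(weights) {
    m2 <- model; m2$weights <- weights
    mean_ce_loss(model_forward(m2, xval), yval)
  }

  best_w <- W
  best_val <- val_loss_of(W)
  best_step <- 0L
  hist <- list(data.frame(step = 0L, train_loss = NA_real_,
                          val_loss = best_val))

  if (config$max_steps > 0) with_seed(config$seed, {
    for (step in seq_len(config$max_steps)) {
      bi <- sample(tr_idx, config$batch_size,
                   replace = length(tr_idx) < config$batch_size)
      x <- crops_to_input(crops[, , bi, drop = FALSE])
      bw <- .nn_backward(model$layers, W, x, d[1], d[2], 1L,
                         length(bi), y[bi], "loss", FALSE, 0L, FALSE)
      if (!is.finite(bw$loss)) {
        stop("NaN/Inf training loss at step ", step,
             "; reduce the learning rate")
      }
      g <- bw$grads
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (i in seq_along(W)) {
        mAdam[[i]] <- beta1 * mAdam[[i]] + (1 - beta1) * g[[i]]
        vAdam[[i]] <- beta2 * vAdam[[i]] + (1 - beta2) * g[[i]]^2
        W[[i]] <- W[[i]] - lr * (mAdam[[i]] / bc1) /
          (sqrt(vAdam[[i]] / bc2) + eps)
      }
      if (step %% config$val_every == 0 || step == config$max_steps) {
        vl <- val_loss_of(W)
        hist[[length(hist) + 1]] <-
          data.frame(step = step, train_loss = bw$loss, val_loss = vl)
        if (vl < best_val) {
          best_val <- vl
          best_w <- W
          best_step <- step
        }
      }
    }
  })
  model$weights <- best_w
  model$history <- do.call(rbind, hist)
  model$selected_step <- best_step
  model
}

#' Evaluate a classifier on crops
#'
#' @param model a trained `death_model`
#' @param crops H x W x N array (raw intensities; normalized internally)
#' @param labels 0/1 truth vector
#' @return object of class `eval_result`: `confusion` (2 x 2, rows = truth
#'   live/dead, cols = prediction), `accuracy`, `scores` (dead-class
#'   probability per crop), `pred`
#' @export
evaluate_model <- function(model, crops, labels) {
  d <- dim(crops)
  if (d[1] != model$input_size || d[2] != model$input_size) {
    stop("crop geometry does not match the model input size")
  }
  stopifnot(d[3] == length(labels), d[3] >= 1)
  logits <- model_forward(model, normalize_crops(crops))
  p <- softmax_cols(logits)
  scores <- p[2, ]
  pred <- as.integer(scores > 0.5)
  confusion <- table(factor(labels, 0:1), factor(pred, 0:1))
  dimnames(confusion) <- list(truth = c("live", "dead"),
                              pred = c("live", "dead"))
  structure(list(confusion = unclass(confusion),
                 accuracy = mean(pred == labels),
                 scores = scores, pred = pred, labels = as.integer(labels)),
            class = "eval_result")
}

#' Per-batch accuracies over random balanced batches
#'
#' Mirrors the benchmarking style of scoring accuracy across several randomly
#' sampled balanced batches of images.
#'
#' @param eval an `eval_result`
#' @param batch_size images per batch (balanced: half per class)
#' @param n_batches number of batches
#' @param seed RNG seed
#' @return numeric vector of per-batch accuracies (fractions)
#' @export
batch_accuracy <- function(eval, batch_size = 50L, n_batches = 7L, seed = 1L) {
  idx0 <- which(eval$labels == 0)
  idx1 <- which(eval$labels == 1)
  half <- batch_size %/% 2L
  if (length(idx0) < half || length(idx1) < half) {
    stop("not enough crops per class for balanced batches")
  }
  with_seed(seed, {
    vapply(seq_len(n_batches), function(b) {
      sel <- c(sample(idx0, half), sample(idx1, batch_size - half))
      mean(eval$pred[sel] == eval$labels[sel])
    }, 0)
  })
}

#' Zero-shot cross-marker evaluation
#'
#' Evaluates a model on crops from a marker it was never trained on, without
#' any weight update.
#'
#' @inheritParams evaluate_model
#' @return an `eval_result`
#' @export
zero_shot_transfer <- function(model, crops, labels) {
  evaluate_model(model, crops, labels)
}
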