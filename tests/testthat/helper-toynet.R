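# A hand-built one-filter network (3x3 positive convolution + ReLU, global
# average pool, linear readout) whose guided Grad-CAM map has a closed form:
# with a positive constant upstream gradient, the guided-backprop input
# gradient is the transposed convolution of the ReLU support and the CAM is
# proportional to the activation itself.
toy_model <- function(K, fc = c(1, -1), input_size = 16L) {
  structure(list(
    architecture = "toy",
    layers = list(
      list(type = "conv", k = 3L, stride = 1L, pad = 1L, relu = TRUE,
           w = 1L, b = 2L),
      list(type = "gap"),
      list(type = "fc", w = 3L, b = 4L)),
    weights = list(matrix(as.vector(K), 1), matrix(0, 1, 1),
                   matrix(fc, 2, 1), matrix(0, 2, 1)),
    input_size = as.integer(input_size), cam_layer = 1L,
    history = NULL, selected_step = 0L), class = "death_model")
}

# independent oracle: direct convolution + analytic guided Grad-CAM
toy_oracle_map <- function(x, K, fc = c(1, -1), target = 0L) {
  S <- nrow(x)
  act <- matrix(0, S, S)
  for (h in 1:S) for (w in 1:S) {
    s <- 0
    for (kr in 0:2) for (kc in 0:2) {
      hh <- h + kr - 1; ww <- w + kc - 1
      if (hh >= 1 && hh <= S && ww >= 1 && ww <= S) {
        s <- s + K[kr + 1, kc + 1] * x[hh, ww]
      }
    }
    act[h, w] <- max(s, 0)
  }
  # class-contrast upstream gradient through gap is a positive constant when
  # fc = (1, -1) and target = 0; guided ReLU keeps the support of act
  g <- (fc[target + 1] - fc[2 - target]) / (S * S)
  mask <- (act > 0) * max(g, 0)
  gbp <- matrix(0, S, S)
  for (h in 1:S) for (w in 1:S) {
    if (mask[h, w] == 0) next
    for (kr in 0:2) for (kc in 0:2) {
      hh <- h + kr - 1; ww <- w + kc - 1
      if (hh >= 1 && hh <= S && ww >= 1 && ww <= S) {
        gbp[hh, ww] <- gbp[hh, ww] + K[kr + 1, kc + 1] * mask[h, w]
      }
    }
  }
  cam <- pmax(g * act, 0)   # alpha = mean(grad) = g; single channel
  imp <- pmax(cam * gbp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

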