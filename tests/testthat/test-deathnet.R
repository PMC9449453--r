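test_that("model construction: output contract, seeding, numerical sanity", {
  m <- build_model("smallresnet", seed = 1)
  z <- array(0, c(64, 64, 1))
  logits <- nucmorph:::model_forward(m, z)
  expect_equal(dim(logits), c(2L, 1L))
  expect_true(all(is.finite(logits)))
  # same seed -> identical initial weights; different seed -> different
  m2 <- build_model("smallresnet", seed = 1)
  expect_identical(m$weights, m2$weights)
  m3 <- build_model("smallresnet", seed = 2)
  expect_false(identical(m$weights, m3$weights))
  expect_error(build_model("vgg"), "arg")
  # the 18-layer architecture builds and runs forward
  m18 <- build_model("resnet18", seed = 1)
  l18 <- nucmorph:::model_forward(m18, array(stats::runif(64 * 64), c(64, 64, 1)))
  expect_equal(dim(l18), c(2L, 1L))
  expect_true(all(is.finite(l18)))
  # 18 weighted layers: stem + 8 blocks x 2 convs + fc
  n_conv <- sum(vapply(m18$layers, function(l)
    switch(l$type, conv = 1L, resblock = 2L, 0L), 0L))
  expect_equal(n_conv + 1L, 18L)
})

test_that("zero training steps returns the initialized model unchanged", {
  lab <- fixture_dataset("nls")
  m <- build_model("smallresnet", seed = 3)
  m0 <- train_model(m, lab, train_config(max_steps = 0L))
  expect_identical(m0$weights, m$weights)
  expect_equal(m0$selected_step, 0L)
})

test_that("training is seed-reproducible", {
  lab <- fixture_dataset("nls", n_per_class = 60L, seed = 77L)
  m <- build_model("smallresnet", seed = 4)
  a <- train_model(m, lab, train_config(max_steps = 120L, seed = 5))
  b <- train_model(m, lab, train_config(max_steps = 120L, seed = 5))
  expect_equal(a$history$val_loss, b$history$val_loss, tolerance = 1e-10)
  expect_identical(a$selected_step, b$selected_step)
})

test_that("checkpoint selection always takes the minimum validation loss", {
  m <- fixture_model("nls")
  h <- m$history
  evaluated <- h[!is.na(h$val_loss), ]
  expect_equal(m$selected_step, evaluated$step[which.min(evaluated$val_loss)])
})

test_that("the desk-scale classifier reaches >= 95% held-out accuracy", {
  m <- fixture_model("nls")
  ts <- fixture_test_split("nls")
  ev <- evaluate_model(m, ts$crops, ts$labels)
  expect_gte(ev$accuracy, 0.95)
  # confusion matrix conservation and definition
  expect_equal(sum(ev$confusion), length(ts$labels))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(unname(rowSums(ev$confusion)),
               as.integer(table(factor(ts$labels, 0:1))))
})

test_that("training on permuted labels yields chance-level accuracy", {
  lab <- fixture_dataset("nls", n_per_class = 100L, seed = 55L)
  perm <- lab
  perm$labels <- nucmorph:::with_seed(13, sample(lab$labels))
  m <- train_model(build_model(seed = 6), perm,
                   train_config(max_steps = 300L, seed = 6))
  te <- which(perm$split == "test")
  # score against the TRUE labels: shuffling destroyed the association
  ev <- evaluate_model(m, perm$crops[, , te, drop = FALSE], lab$labels[te])
  expect_gte(ev$accuracy, 0.3)
  expect_lte(ev$accuracy, 0.7)
})

test_that("batch accuracies are balanced samples consistent with the mean", {
  m <- fixture_model("nls")
  ts <- fixture_test_split("nls")
  ev <- evaluate_model(m, ts$crops, ts$labels)
  ba <- batch_accuracy(ev, batch_size = 50L, n_batches = 7L, seed = 3)
  expect_length(ba, 7)
  expect_true(all(ba >= 0 & ba <= 1))
  # binomial sampling-error oracle: |mean(batches) - overall| <= 3 SE
  se <- sqrt(ev$accuracy * (1 - ev$accuracy) / (7 * 50))
  expect_lte(abs(mean(ba) - ev$accuracy), 3 * se + 1e-12)
  expect_identical(ba, batch_accuracy(ev, seed = 3))
  expect_error(batch_accuracy(ev, batch_size = 10000L), "enough")
})

test_that("more training data does not hurt (median over 3 seeds)", {
  accs <- vapply(1:3, function(sd) {
    vapply(c(50L, 500L), function(npc) {
      lab <- fixture_dataset("nls", n_per_class = npc, seed = 200L + sd)
      m <- train_model(build_model(seed = sd), lab,
                       train_config(max_steps = 300L, seed = sd))
      te <- which(lab$split == "test")
      evaluate_model(m, lab$crops[, , te, drop = FALSE], lab$labels[te])$accuracy
    }, 0)
  }, c(0, 0))
  expect_gte(stats::median(accs[2, ]), stats::median(accs[1, ]))
})

test_that("zero-shot transfer is evaluation without adaptation", {
  m <- fixture_model("nls")
  ts <- fixture_test_split("nls")
  a <- zero_shot_transfer(m, ts$crops, ts$labels)
  b <- evaluate_model(m, ts$crops, ts$labels)
  expect_identical(a$scores, b$scores)
  expect_error(zero_shot_transfer(m, array(0, c(32, 32, 4)), rep(0:1, 2)),
               "geometry")
})

test_that("engine gradients match central finite differences", {
  # checked away from the zero-init ReLU kinks: perturb all weights so no
  # pre-activation sits exactly at zero
  m <- build_model("smallresnet", input_size = 16L, base_channels = 2L,
                   seed = 3)
  m$weights <- nucmorph:::with_seed(4, lapply(m$weights, function(w)
    w + matrix(stats::rnorm(length(w), 0, 0.05), nrow(w), ncol(w))))
  S <- 16L; N <- 3L
  x <- nucmorph:::with_seed(5, array(stats::rnorm(S * S * N), c(S, S, N)))
  xin <- nucmorph:::crops_to_input(x)
  y <- c(0L, 1L, 0L)
  bw <- nucmorph:::.nn_backward(m$layers, m$weights, xin, S, S, 1L, N, y,
                                "loss", FALSE, 0L, TRUE)
  loss_at <- function(weights) {
    nucmorph:::.nn_backward(m$layers, weights, xin, S, S, 1L, N, y,
                            "loss", FALSE, 0L, FALSE)$loss
  }
  eps <- 1e-6
  idx <- nucmorph:::with_seed(6, lapply(seq_along(m$weights), function(wi)
    sample(length(m$weights[[wi]]), 2)))
  for (wi in seq_along(m$weights)) {
    for (i in idx[[wi]]) {
      wp <- m$weights; wp[[wi]][i] <- wp[[wi]][i] + eps
      wm <- m$weights; wm[[wi]][i] <- wm[[wi]][i] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(bw$grads[[wi]][i], fd, tolerance = 1e-4)
    }
  }
  # input gradient too (used by guided backprop)
  for (i in nucmorph:::with_seed(7, sample(length(xin), 4))) {
    xp <- xin; xp[i] <- xp[i] + eps
    xm <- xin; xm[i] <- xm[i] - eps
    fd <- (nucmorph:::.nn_backward(m$layers, m$weights, xp, S, S, 1L, N, y,
                                   "loss", FALSE, 0L, FALSE)$loss -
           nucmorph:::.nn_backward(m$layers, m$weights, xm, S, S, 1L, N, y,
                                   "loss", FALSE, 0L, FALSE)$loss) / (2 * eps)
    expect_equal(bw$input_grad[i], fd, tolerance = 1e-4)
  }
})
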