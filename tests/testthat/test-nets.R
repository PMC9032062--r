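## a miniature CRNN (same layer chain as the full network, smaller tensors)
tiny_crnn <- function(dropout = 0) {
  crnn_spec(pad = 3L, filters = c(3L, 4L, 4L), kernel = c(5L, 3L),
            pool_kernels = list(c(2L, 2L), c(3L, 3L), c(4L, 1L)),
            pool_strides = list(c(2L, 1L), c(3L, 3L), c(4L, 1L)),
            dropout = dropout, gru_units = 4L)
}

test_that("the CRNN shape chain follows pad/conv/pool arithmetic", {
  fs <- forward_shapes(crnn_spec(), c(250, 20))
  pools <- which(names(fs) == "maxpool")
  expect_equal(fs[["zeropad_time"]], c(324L, 20L, 1L))
  expect_equal(fs[[pools[1]]][1], 162L)
  expect_equal(fs[[pools[2]]][1], 54L)
  expect_equal(fs[[pools[3]]][1], 13L)
  expect_equal(fs[["to_sequence"]], c(13L, 64L))
  ## the time padding keeps short windows viable; the electrode axis is
  ## what the pooling chain can exhaust
  expect_error(forward_shapes(crnn_spec(), c(1250, 1)), "too short")
})

test_that("model builds are seeded and emit probabilities in [0, 1]", {
  m1 <- build_model(tiny_crnn(0.3), c(60L, 6L), seed = 42L)
  m2 <- build_model(tiny_crnn(0.3), c(60L, 6L), seed = 42L)
  w1 <- rotoregm:::net_get_weights(m1$net)
  w2 <- rotoregm:::net_get_weights(m2$net)
  expect_identical(w1, w2)

  x <- array(runif(60 * 6 * 2), c(60, 6, 1, 2))
  p <- predict_model(m1, x)
  expect_length(p$prob, 2L)
  expect_true(all(p$prob >= 0 & p$prob <= 1))

  ## thresholds: 0 marks everything positive, 1 only exact ones
  expect_equal(predict_model(m1, x, threshold = 0)$label, c(1L, 1L))
  expect_equal(predict_model(m1, x, threshold = 1)$label, c(0L, 0L))

  expect_error(predict_model(m1, array(0, c(50, 6, 1, 2))), "shape")
})

test_that("dense baseline has exactly the published parameter count", {
  m <- build_model(simple_spec(), c(1250L, 20L), seed = 1L)
  expect_equal(rotoregm:::net_n_params(m$net),
               (25000 * 128 + 128) + (128 * 64 + 64) + (64 * 1 + 1))
  denses <- Filter(function(l) l$type == "dense", m$net$layers)
  expect_length(denses, 3L)
})

test_that("the comparator CNN has 13 convolution and 2 memory layers", {
  m <- build_model(aticnn_spec(), c(200L, 15L), seed = 1L)
  types <- vapply(m$net$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv2d"), 13L)
  expect_equal(sum(types == "lstm"), 2L)
  p <- predict_model(m, array(runif(200 * 15 * 2), c(200, 15, 1, 2)))
  expect_true(all(p$prob >= 0 & p$prob <= 1))
})

test_that("backpropagation matches finite-difference gradients", {
  eng <- asNamespace("rotoregm")
  m <- build_model(tiny_crnn(0), c(60L, 6L), seed = 42L)
  net <- m$net
  set.seed(7)
  x <- array(runif(60 * 6 * 3), c(60, 6, 1, 3))
  y <- c(1, 0, 1)
  loss_at <- function() eng$bce_logits(eng$net_forward(net, x, TRUE), y)$loss
  z <- eng$net_forward(net, x, TRUE)
  eng$net_backward(net, eng$bce_logits(z, y)$dz)
  h <- 1e-4
  set.seed(8)
  for (l in net$layers) {
    if (!length(l$params)) next
    for (nm in names(l$params)) {
      for (i in sample(length(l$params[[nm]]), min(3, length(l$params[[nm]])))) {
        orig <- l$params[[nm]][i]
        l$params[[nm]][i] <- orig + h; lp <- loss_at()
        l$params[[nm]][i] <- orig - h; lm <- loss_at()
        l$params[[nm]][i] <- orig
        num <- (lp - lm) / (2 * h)
        ana <- l$grads[[nm]][i]
        ## single-precision convolution kernels put a noise floor of ~1e-4
        ## on the numerical difference; compare only meaningful gradients
        ok <- abs(num - ana) < 5e-4 ||
          abs(num - ana) / max(abs(num), abs(ana)) < 0.02
        expect_true(ok, label = sprintf("%s/%s[%d]: num %.3g ana %.3g",
                                        l$type, nm, i, num, ana))
      }
    }
  }
})

test_that("initial loss sits at chance for balanced labels", {
  eng <- asNamespace("rotoregm")
  m <- build_model(tiny_crnn(0), c(60L, 6L), seed = 3L)
  x <- array(runif(60 * 6 * 8), c(60, 6, 1, 8))
  y <- rep(c(0, 1), 4)
  z <- eng$net_forward(m$net, x, TRUE)
  expect_equal(eng$bce_logits(z, y)$loss, log(2), tolerance = 0.15)
})

test_that("training separates a linearly separable window set", {
  set.seed(10)
  n <- 200
  x <- array(runif(60 * 6 * n, 0, 0.3), c(60, 6, 1, n))
  y <- rep(c(0L, 1L), n / 2)
  x[, , , y == 1L] <- x[, , , y == 1L] + 0.5
  idx <- sample(n)
  tr <- list(x = x[, , , idx[1:160], drop = FALSE], y = y[idx[1:160]])
  va <- list(x = x[, , , idx[161:n], drop = FALSE], y = y[idx[161:n]])

  m <- build_model(tiny_crnn(0), c(60L, 6L), seed = 10L)
  fit <- train_model(m, tr, va,
                     train_config(lr_grid = 1e-2, epochs = 8L, patience = 8L,
                                  seed = 10L))
  pr <- predict_model(fit, tr$x)
  expect_gte(mean(pr$label == tr$y), 0.95)
  expect_gte(fit$val_accuracy, 0.9)

  ## determinism of the whole fit
  fit2 <- train_model(build_model(tiny_crnn(0), c(60L, 6L), seed = 10L),
                      tr, va,
                      train_config(lr_grid = 1e-2, epochs = 8L, patience = 8L,
                                   seed = 10L))
  expect_equal(fit2$val_accuracy, fit$val_accuracy)
  expect_identical(predict_model(fit2, tr$x)$prob, pr$prob)

  ## probabilities do not depend on prediction batching
  expect_equal(predict_model(fit, va$x, batch = 7L)$prob,
               predict_model(fit, va$x, batch = 64L)$prob, tolerance = 1e-12)
})

test_that("models survive a save/load round trip", {
  m <- build_model(tiny_crnn(0), c(60L, 6L), seed = 2L)
  x <- array(runif(60 * 6 * 3), c(60, 6, 1, 3))
  p0 <- predict_model(m, x)$prob
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_model(m2, x)$prob, p0, tolerance = 1e-12)
  unlink(path)
})
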