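#' Convolutional-recurrent network specification
#'
#' Architecture record of the rotor classifier: symmetric time-axis zero
#' padding, an input batch-normalization/dropout stage, three convolution
#' blocks (rectangular kernels, size-preserving padding, batch
#' normalization, leaky rectifier, boundary-truncating max pooling, 30
#' percent dropout), two gated-recurrent layers of 32 units (the first
#' returning its full sequence, the second its final state), and a single
#' sigmoid output unit. With the defaults, a 1250 x 20 input maps through
#' 1324 x 20 (padded), 662 x 19, 220 x 6 and 55 x 1 pooled stages into a
#' 55-step, 64-feature recurrent input.
#'
#' The kernel is rectangular, 23 x 5; its long side runs along the time axis
#' by default (`kernel_orientation = "time-major"`), placing the longer
#' receptive field on temporal context. `"electrode-major"` transposes it;
#' the layer shape chain is identical either way because convolutions are
#' size-preserving.
#'
#' @param pad symmetric time-axis zero padding, samples per side.
#' @param filters convolution filter counts for the three blocks.
#' @param kernel kernel size `c(time, electrode)`.
#' @param pool_kernels,pool_strides per-block pooling windows and strides,
#'   each a list of `c(time, electrode)` pairs.
#' @param dropout dropout rate after each pooling stage and before output.
#' @param gru_units units in each gated-recurrent layer.
#' @param leaky_alpha negative slope of the leaky rectifier.
#' @param kernel_orientation `"time-major"` (long side 23 along time) or
#'   `"electrode-major"`.
#' @return object of class `crnn_spec`.
#' @export
crnn_spec <- function(pad = 37L, filters = c(32L, 64L, 64L),
                      kernel = c(23L, 5L),
                      pool_kernels = list(c(2L, 2L), c(3L, 3L), c(4L, 4L)),
                      pool_strides = list(c(2L, 1L), c(3L, 3L), c(4L, 4L)),
                      dropout = 0.3, gru_units = 32L, leaky_alpha = 0.3,
                      kernel_orientation = c("time-major", "electrode-major")) {
  structure(list(pad = pad, filters = filters, kernel = kernel,
                 pool_kernels = pool_kernels, pool_strides = pool_strides,
                 dropout = dropout, gru_units = gru_units,
                 leaky_alpha = leaky_alpha,
                 kernel_orientation = match.arg(kernel_orientation)),
            class = c("crnn_spec", "net_spec"))
}

#' Dense baseline specification
#'
#' The baseline classifier: the input window is flattened and passed through
#' three fully connected layers of 128, 64 and 1 units (rectifier
#' activations, sigmoid output). It ignores all temporal structure and
#' serves as the floor against which the sequence models are compared.
#'
#' @param units the three dense layer widths.
#' @return object of class `simple_spec`.
#' @export
simple_spec <- function(units = c(128L, 64L, 1L)) {
  stopifnot(length(units) == 3L, units[3] == 1L)
  structure(list(units = units), class = c("simple_spec", "net_spec"))
}

#' Convolutional network with long short-term memory head
#'
#' Comparator modeled on deep time-incremental electrocardiogram
#' classifiers: 13 time-axis convolution layers of kernel size 3 arranged in
#' five blocks (2, 2, 3, 3, 3 layers; 64, 128, 256, 256, 256 channels) with
#' max pooling after each block, electrodes entering as input channels,
#' followed by two long short-term-memory layers and a sigmoid unit.
#'
#' @param block_layers convolution layers per block (must sum to 13).
#' @param block_channels channels per block.
#' @param lstm_units units in each recurrent layer.
#' @return object of class `aticnn_spec`.
#' @export
aticnn_spec <- function(block_layers = c(2L, 2L, 3L, 3L, 3L),
                        block_channels = c(64L, 128L, 256L, 256L, 256L),
                        lstm_units = 32L) {
  stopifnot(sum(block_layers) == 13L,
            length(block_layers) == length(block_channels))
  structure(list(block_layers = block_layers, block_channels = block_channels,
                 lstm_units = lstm_units),
            class = c("aticnn_spec", "net_spec"))
}

make_layers <- function(spec, ...) UseMethod("make_layers")

#' @export
make_layers.crnn_spec <- function(spec, ...) {
  k <- if (spec$kernel_orientation == "time-major") spec$kernel else rev(spec$kernel)
  layers <- list(layer_zeropad_time(spec$pad),
                 layer_batchnorm(),
                 layer_dropout(spec$dropout))
  for (i in seq_along(spec$filters)) {
    # batch normalization with the leaky rectifier fused onto its output
    layers <- c(layers, list(
      layer_conv2d(spec$filters[i], k),
      layer_batchnorm(activation_alpha = spec$leaky_alpha),
      layer_maxpool(spec$pool_kernels[[i]], spec$pool_strides[[i]]),
      layer_dropout(spec$dropout)))
  }
  c(layers, list(layer_to_sequence(),
                 layer_gru(spec$gru_units, return_sequences = TRUE),
                 layer_gru(spec$gru_units, return_sequences = FALSE),
                 layer_dropout(spec$dropout),
                 layer_dense(1L)))
}

#' @export
make_layers.simple_spec <- function(spec, ...) {
  list(layer_flatten(),
       layer_dense(spec$units[1], activation = "relu"),
       layer_dense(spec$units[2], activation = "relu"),
       layer_dense(1L))
}

#' @export
make_layers.aticnn_spec <- function(spec, ...) {
  layers <- list(layer_electrodes_to_channels())
  for (b in seq_along(spec$block_layers)) {
    for (i in seq_len(spec$block_layers[b]))
      layers <- c(layers, list(layer_conv2d(spec$block_channels[b], c(3L, 1L)),
                               layer_leakyrelu(0)))
    layers <- c(layers, list(layer_maxpool(c(2L, 1L), c(2L, 1L))))
  }
  c(layers, list(layer_to_sequence(),
                 layer_lstm(spec$lstm_units, return_sequences = TRUE),
                 layer_lstm(spec$lstm_units, return_sequences = FALSE),
                 layer_dense(1L)))
}

#' Layer-by-layer output shapes of a network
#'
#' Closed-form shape propagation: time padding adds `2 * pad`; convolutions
#' are size-preserving; pooling maps axis length `n` through
#' `floor((n - k) / s) + 1`. Shapes exclude the batch dimension.
#'
#' @param spec a network spec ([crnn_spec()], [simple_spec()],
#'   [aticnn_spec()]).
#' @param input_shape `c(time_samples, channels)`.
#' @return named list of integer shape vectors, one entry per layer plus the
#'   leading `"input"`.
#' @export
forward_shapes <- function(spec, input_shape) {
  layers <- make_layers(spec)
  shape <- c(as.integer(input_shape), 1L)
  out <- list(input = shape)
  set.seed(0L)
  for (l in layers) {
    shape <- l$init(shape)
    if (any(shape < 1L))
      stop("input too short for the pooling chain", call. = FALSE)
    out[[length(out) + 1L]] <- shape
    names(out)[length(out)] <- l$type
  }
  out
}

#' Instantiate a classifier
#'
#' Builds a parameterized model from an architecture spec. The forward pass
#' on a batch of normalized windows yields probabilities in `[0, 1]`;
#' identical seeds give identical initial parameters.
#'
#' @param spec a `net_spec`.
#' @param input_shape `c(time_samples, channels)`.
#' @param seed initialization seed.
#' @return object of class `rotor_model`.
#' @export
build_model <- function(spec, input_shape, seed = 1L) {
  layers <- make_layers(spec)
  net <- build_network(layers, c(as.integer(input_shape), 1L), seed = seed)
  structure(list(spec = spec, net = net, input_shape = as.integer(input_shape),
                 seed = seed, fitted = FALSE),
            class = "rotor_model")
}

#' @export
print.rotor_model <- function(x, ...) {
  cat(sprintf("<rotor_model> %s, input %d x %d, %s parameters%s\n",
              class(x$spec)[1], x$input_shape[1], x$input_shape[2],
              format(net_n_params(x$net), big.mark = ","),
              if (x$fitted) " (fitted)" else ""))
  invisible(x)
}

#' Training configuration
#'
#' @param lr_grid learning rates searched; the model with the best
#'   validation accuracy wins.
#' @param epochs maximum training epochs per grid point.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience, in validation evaluations.
#' @param eval_every evaluate the validation set every this many update
#'   steps (`NULL`: once per epoch).
#' @param seed seed for shuffling/dropout (model initialization uses the
#'   model's own seed).
#' @param verbose print progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr_grid = c(1e-2, 1e-3, 1e-4), epochs = 50L,
                         batch_size = 32L, patience = 10L, eval_every = NULL,
                         seed = 1L, verbose = FALSE) {
  stopifnot(length(lr_grid) >= 1L, batch_size >= 1L)
  structure(list(lr_grid = lr_grid, epochs = epochs, batch_size = batch_size,
                 patience = patience, eval_every = eval_every, seed = seed,
                 verbose = verbose),
            class = "train_config")
}

coerce_net_input <- function(data) {
  if (inherits(data, "window_set")) return(as_net_input(data))
  if (is.list(data) && !is.null(data$x)) return(data)
  stop("expected a window_set or list(x, y)", call. = FALSE)
}

#' Train a classifier
#'
#' Adam optimization of the binary cross-entropy over the learning-rate
#' grid, with early stopping (and final weight restoration) on validation
#' accuracy. The grid point with the best validation accuracy is returned.
#'
#' @param model an unfitted `rotor_model` (its spec and seed are reused for
#'   every grid point).
#' @param train,val training and validation data: `window_set`s or lists
#'   with `x` (time, channels, 1, n array) and `y`.
#' @param config a [train_config()].
#' @return fitted `rotor_model` with elements `history` (per-evaluation
#'   validation accuracy for the winning grid point), `lr` (selected rate),
#'   `val_accuracy`.
#' @export
train_model <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "rotor_model"))
  tr <- coerce_net_input(train)
  va <- coerce_net_input(val)
  if (!length(tr$y) || !length(va$y))
    stop("training and validation sets must be non-empty", call. = FALSE)
  best <- NULL
  for (lr in config$lr_grid) {
    m <- build_model(model$spec, model$input_shape, seed = model$seed)
    fit <- net_fit(m$net, tr$x, tr$y, va$x, va$y, lr = lr,
                   epochs = config$epochs, batch_size = config$batch_size,
                   patience = config$patience, eval_every = config$eval_every,
                   seed = config$seed, verbose = config$verbose)
    if (config$verbose)
      message(sprintf("lr %.0e: val accuracy %.3f", lr, fit$best_val_accuracy))
    if (is.null(best) || fit$best_val_accuracy > best$val_accuracy) {
      m$fitted <- TRUE
      m$history <- fit$history
      m$lr <- lr
      m$val_accuracy <- fit$best_val_accuracy
      best <- m
    }
  }
  best
}

#' Predict rotor probabilities for windows
#'
#' @param model a fitted `rotor_model`.
#' @param windows a `window_set`, a list with `x`, or a bare input array.
#' @param threshold decision threshold; a window is called positive when its
#'   probability is `>= threshold` (so `threshold = 0` marks everything
#'   positive and `threshold = 1` only windows with probability exactly 1).
#' @param batch forward-pass batch size (results are independent of it).
#' @return list with `prob` (probabilities) and `label` (0/1).
#' @export
predict_model <- function(model, windows, threshold = 0.5, batch = 64L) {
  stopifnot(inherits(model, "rotor_model"))
  x <- if (is.array(windows)) windows else coerce_net_input(windows)$x
  if (!identical(dim(x)[1:2], model$input_shape))
    stop("window shape does not match the model input", call. = FALSE)
  p <- net_predict_prob(model$net, x, batch = batch)
  list(prob = p, label = as.integer(p >= threshold))
}

#' Save / load a fitted model
#'
#' Weights, running statistics and the architecture spec are serialized with
#' base R serialization.
#'
#' @param model a `rotor_model`.
#' @param path file path.
#' @return `load_model` returns the restored `rotor_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, input_shape = model$input_shape,
               seed = model$seed, weights = net_get_weights(model$net),
               fitted = model$fitted, lr = model$lr,
               val_accuracy = model$val_accuracy, history = model$history),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- readRDS(path)
  m <- build_model(s$spec, s$input_shape, seed = s$seed)
  net_set_weights(m$net, s$weights)
  m$fitted <- s$fitted; m$lr <- s$lr
  m$val_accuracy <- s$val_accuracy; m$history <- s$history
  m
}
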