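#' Run the model / signal-type / length / rate experiment grid
#'
#' Trains and evaluates every combination of classifier, input
#' representation, window length and sampling rate on a simulated cohort,
#' producing one row per cell with validation accuracy and test-set
#' accuracy, precision, recall, specificity and Matthews correlation -- the
#' schema of a model-comparison table. Datasets are built once per
#' (type, length, rate) cell and shared across models; every cell gets a
#' deterministic seed derived from `seed`. A cell whose training fails is
#' marked `failed` and the run continues.
#'
#' @param cohort an `egm_cohort`.
#' @param models character subset of `c("simple", "aticnn", "crnn")`.
#' @param signal_types subset of `c("unipolar", "bipolar", "lat-train")`.
#' @param window_lengths window lengths, ms.
#' @param rates sampling rates, Hz.
#' @param config a [train_config()] applied to every cell.
#' @param max_train,augment,filter passed to [build_dataset()].
#' @param seed base seed.
#' @return data.frame with one row per grid cell.
#' @export
run_grid <- function(cohort,
                     models = c("simple", "aticnn", "crnn"),
                     signal_types = c("unipolar", "bipolar", "lat-train"),
                     window_lengths = c(500, 2500),
                     rates = c(500, 250, 100),
                     config = train_config(),
                     max_train = Inf, augment = "none", filter = TRUE,
                     seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  spec_of <- function(m) switch(m, simple = simple_spec(),
                                aticnn = aticnn_spec(), crnn = crnn_spec())
  rows <- list()
  cell <- 0L
  for (st in signal_types) for (wl in window_lengths) for (fs in rates) {
    ds <- tryCatch(
      build_dataset(cohort, signal_type = st, window_ms = wl, target_fs = fs,
                    augment = augment, filter = filter, max_train = max_train,
                    seed = seed),
      error = function(e) e)
    for (m in models) {
      cell <- cell + 1L
      cell_seed <- (seed + 104729L * cell) %% 2147483647L
      row <- data.frame(model = m, input = st, window_ms = wl, fs = fs,
                        seed = cell_seed, failed = FALSE,
                        val_accuracy = NA_real_, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        specificity = NA_real_, mcc = NA_real_,
                        auc = NA_real_)
      res <- tryCatch({
        if (inherits(ds, "error")) stop(ds)
        n_samp <- floor(wl * fs / 1000)
        n_ch <- nrow(ds$train[[1L]]$x)
        model <- build_model(spec_of(m), c(n_samp, n_ch), seed = cell_seed)
        cfg <- config; cfg$seed <- cell_seed
        fitted <- train_model(model, ds$train, ds$val, cfg)
        te <- as_net_input(ds$test)
        pr <- predict_model(fitted, te$x)
        ev <- evaluate_predictions(te$y, pr$prob)
        list(fitted = fitted, ev = ev)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$failed <- TRUE
        row$message <- conditionMessage(res)
      } else {
        row$message <- ""
        row$val_accuracy <- res$fitted$val_accuracy
        row$accuracy <- res$ev$accuracy
        row$precision <- res$ev$precision
        row$recall <- res$ev$recall
        row$specificity <- res$ev$specificity
        row$mcc <- res$ev$mcc
        row$auc <- res$ev$auc
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
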