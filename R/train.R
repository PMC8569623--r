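# ---------------------------------------------------------------------------
# Dataset splitting, the training loop, evaluation metrics and the four-way
# ablation.
# ---------------------------------------------------------------------------

#' Training hyperparameters
#'
#' @param batch_size Minibatch size (default 128).
#' @param epochs Number of training epochs (default 200).
#' @param lr Adam learning rate, decayed with a cosine schedule.
#' @param seed Seed controlling shuffling and dropout; fixed seed gives
#'   reproducible training.
#' @param val_fraction Stratified fraction of the training data held out for
#'   per-epoch validation and checkpoint selection.
#' @export
train_config <- function(batch_size = 128, epochs = 200, lr = 1e-3,
                         seed = 1L, val_fraction = 0.1) {
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "semg_train_config")
}

#' Split a dataset into class-balanced train/test collections
#'
#' Samples `n_train_per_class + n_test_per_class` recording indices per
#' class without replacement (deterministically under `seed`) and assigns
#' the first block to train, the rest to test, so the splits are disjoint.
#'
#' @param dataset A `semg_dataset`.
#' @param n_train_per_class,n_test_per_class Recordings per class.
#' @param seed Integer seed.
#' @return List with `semg_dataset` elements `train` and `test`, plus the
#'   index vectors `train_idx`/`test_idx` into the source dataset.
#' @export
split_dataset <- function(dataset, n_train_per_class, n_test_per_class,
                          seed = 1L) {
  stopifnot(inherits(dataset, "semg_dataset"))
  need <- n_train_per_class + n_test_per_class
  tr <- integer(0); te <- integer(0)
  with_local_seed(seed, {
    for (cl in 0:(dataset$n_classes - 1L)) {
      idx <- which(dataset$labels == cl)
      if (length(idx) < need) {
        stop_config("class %d has %d recordings, need %d", cl, length(idx),
                    need)
      }
      pick <- sample(idx, need)
      tr <- c(tr, pick[seq_len(n_train_per_class)])
      te <- c(te, pick[n_train_per_class + seq_len(n_test_per_class)])
    }
  })
  take <- function(idx) {
    structure(list(recordings = dataset$recordings[idx],
                   labels = dataset$labels[idx],
                   n_classes = dataset$n_classes, fs = dataset$fs),
              class = "semg_dataset")
  }
  list(train = take(tr), test = take(te), train_idx = tr, test_idx = te)
}

adam_update <- function(params, grads, opt, lr) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]] %||% (g * 0)
    v <- opt$v[[nm]] %||% (g * 0)
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    mhat <- m / (1 - 0.9^opt$t)
    vhat <- v / (1 - 0.999^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(params = params, opt = opt)
}

eval_pass <- function(cfg, params, state, data, batch_size = 256) {
  n <- length(data$y)
  probs <- matrix(0, n, cfg$n_classes)
  loss <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    ctx <- new_ctx(params, state, training = FALSE)
    scores <- network_forward(ctx, cfg, data$emg[, , , b, drop = FALSE],
                              if (cfg$use_acc) data$acc[b, , drop = FALSE])
    sm <- softmax_ce(scores, data$y[b])
    probs[b, ] <- sm$probs
    loss <- loss + sm$loss * length(b)
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  list(probs = probs, pred = pred, loss = loss / n,
       accuracy = mean(pred == data$y))
}

#' Train the recognition network
#'
#' Minimises softmax cross-entropy with Adam (cosine learning-rate decay)
#' on minibatches, holding out a stratified validation split for per-epoch
#' monitoring, and returns the weights of the epoch with the best
#' validation accuracy. All randomness (shuffling, dropout) derives from
#' `train_cfg$seed`.
#'
#' @param model A freshly initialised `semg_model` (see [init_model()]).
#' @param inputs Prepared training data from [prepare_model_inputs()].
#' @param train_cfg A [train_config()].
#' @param quiet Suppress per-epoch progress.
#' @return A list: `model` (best-validation checkpoint), `final_model`,
#'   and `history` (data.frame of per-epoch train loss, validation loss and
#'   validation accuracy).
#' @export
train_model <- function(model, inputs, train_cfg = train_config(),
                        quiet = TRUE) {
  cfg <- model$cfg
  params <- model$params
  state <- model$state
  n <- length(inputs$y)
  with_local_seed(train_cfg$seed, {
    # stratified validation split
    val_idx <- integer(0)
    if (train_cfg$val_fraction > 0) {
      for (cl in unique(inputs$y)) {
        idx <- which(inputs$y == cl)
        k <- max(1L, round(length(idx) * train_cfg$val_fraction))
        val_idx <- c(val_idx, sample(idx, k))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr <- subset_inputs(inputs, tr_idx)
    va <- if (length(val_idx)) subset_inputs(inputs, val_idx) else NULL
    ntr <- length(tr$y)

    opt <- list(m = list(), v = list(), t = 0)
    best <- list(acc = -Inf, params = params, state = state)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), val_accuracy = numeric(0))
    for (epoch in seq_len(train_cfg$epochs)) {
      lr <- train_cfg$lr * 0.5 *
        (1 + cos(pi * (epoch - 1) / max(1, train_cfg$epochs)))
      ord <- sample(ntr)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      epoch_loss <- 0
      for (b in batches) {
        ctx <- new_ctx(params, state, training = TRUE)
        emg_b <- tr$emg[, , , b, drop = FALSE]
        acc_b <- if (cfg$use_acc) tr$acc[b, , drop = FALSE]
        scores <- network_forward(ctx, cfg, emg_b, acc_b)
        sm <- softmax_ce(scores, tr$y[b])
        if (!is.finite(sm$loss)) {
          stop_config("training diverged (non-finite loss) at epoch %d",
                      epoch)
        }
        epoch_loss <- epoch_loss + sm$loss * length(b)
        d <- dim(emg_b)
        network_backward(ctx, cfg, sm$dscores,
                         list(H = d[1], wp = d[2] %/% cfg$streams,
                              steps = d[3], B = d[4]))
        state <- ctx$state
        opt$t <- opt$t + 1
        upd <- adam_update(params, ctx$grads, opt, lr)
        params <- upd$params; opt <- upd$opt
      }
      epoch_loss <- epoch_loss / ntr
      if (!is.null(va)) {
        ev <- eval_pass(cfg, params, state, va)
        if (ev$accuracy >= best$acc) {
          best <- list(acc = ev$accuracy, params = params, state = state)
        }
        history <- rbind(history, data.frame(epoch = epoch,
                                             train_loss = epoch_loss,
                                             val_loss = ev$loss,
                                             val_accuracy = ev$accuracy))
        if (!quiet) {
          message(sprintf("epoch %3d  loss %.4f  val %.4f (acc %.3f)",
                          epoch, epoch_loss, ev$loss, ev$accuracy))
        }
      } else {
        best <- list(acc = NA_real_, params = params, state = state)
        history <- rbind(history, data.frame(epoch = epoch,
                                             train_loss = epoch_loss,
                                             val_loss = NA_real_,
                                             val_accuracy = NA_real_))
      }
    }
  })
  mk <- function(p, s) structure(list(cfg = cfg, params = p, state = s),
                                 class = "semg_model")
  list(model = mk(best$params, best$state),
       final_model = mk(params, state), history = history)
}

#' Evaluate a model on prepared test data
#'
#' Runs inference (dropout off, batch norm in inference mode) and reports
#' accuracy, per-class recall and the confusion matrix.
#'
#' @param model A `semg_model`.
#' @param inputs Prepared data from [prepare_model_inputs()].
#' @return An object of class `semg_metrics`: list with `accuracy`,
#'   `per_class_recall` (NA for classes absent from the test set),
#'   `confusion` (true x predicted counts) and `n`.
#' @export
evaluate_model <- function(model, inputs) {
  ev <- eval_pass(model$cfg, model$params, model$state, inputs)
  k <- model$cfg$n_classes
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(inputs$y)) {
    confusion[inputs$y[i] + 1L, ev$pred[i] + 1L] <-
      confusion[inputs$y[i] + 1L, ev$pred[i] + 1L] + 1L
  }
  rs <- rowSums(confusion)
  recall <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  structure(list(accuracy = ev$accuracy, per_class_recall = recall,
                 confusion = confusion, n = length(inputs$y)),
            class = "semg_metrics")
}

#' @export
print.semg_metrics <- function(x, ...) {
  cat(sprintf("<semg_metrics> accuracy %.4f on %d samples\n", x$accuracy, x$n))
  invisible(x)
}

#' Configuration for the four-way ablation
#'
#' The four experiments mirror the method's ablation: (1) single-stream
#' network on raw sEMG images; (2) multi-stream network on raw images;
#' (3) multi-stream on raw images with the accelerometer branch;
#' (4) multi-stream on feature images with the accelerometer branch.
#'
#' @param n_train_per_class,n_test_per_class,n_classes Dataset size.
#' @param snr_db Action-to-rest SNR of the synthetic recordings.
#' @param duration_s,fs Recording duration and sampling rate.
#' @param seeds Integer vector; the whole suite is repeated per seed and
#'   accuracies are averaged.
#' @param streams Stream count of the multi-stream experiments.
#' @param widths,lstm_hidden,fc_dim,acc_hidden Reduced network widths used
#'   for the suite.
#' @param epochs,batch_size,lr Training-loop settings.
#' @export
ablation_config <- function(n_train_per_class = 12, n_test_per_class = 15,
                            n_classes = 6, snr_db = 12, duration_s = 2,
                            fs = 1000, seeds = 1:3, streams = 4,
                            widths = c(8, 8, 8), lstm_hidden = 8,
                            fc_dim = 32, acc_hidden = c(8, 4),
                            epochs = 20, batch_size = 16, lr = 5e-3) {
  as.list(environment())
}

ablation_model_cfg <- function(sc, mode, streams, use_acc) {
  model_config(mode = mode, streams = streams, widths = sc$widths,
               groups = 2, se_ratio = 4, lstm_hidden = sc$lstm_hidden,
               fc_dim = sc$fc_dim, n_classes = sc$n_classes,
               use_acc = use_acc, acc_hidden = sc$acc_hidden)
}

#' Run the four-way ablation on synthetic data
#'
#' For each seed: generates a synthetic dataset, prepares raw and feature
#' inputs (normalisation fitted on the training split only), then trains
#' and evaluates the four experiment configurations on identical data.
#'
#' @param suite_cfg An [ablation_config()].
#' @param quiet Suppress progress messages.
#' @return A data.frame with one row per (seed, experiment): experiment id,
#'   description, seed and test accuracy. The per-experiment mean accuracy
#'   across seeds is attached as attribute `summary`.
#' @export
run_ablation <- function(suite_cfg = ablation_config(), quiet = TRUE) {
  sc <- suite_cfg
  experiments <- list(
    list(id = 1L, mode = "raw", streams = 1L, use_acc = FALSE,
         desc = "single-stream, raw sEMG image"),
    list(id = 2L, mode = "raw", streams = sc$streams, use_acc = FALSE,
         desc = "multi-stream, raw sEMG image"),
    list(id = 3L, mode = "raw", streams = sc$streams, use_acc = TRUE,
         desc = "multi-stream, raw sEMG image + ACC"),
    list(id = 4L, mode = "feature", streams = sc$streams, use_acc = TRUE,
         desc = "multi-stream, feature image + ACC"))
  rows <- list()
  for (seed in sc$seeds) {
    ncfg <- noise_config(snr_db = sc$snr_db, seed = seed)
    ds <- generate_dataset(sc$n_train_per_class, sc$n_test_per_class,
                           n_classes = sc$n_classes, fs = sc$fs, cfg = ncfg,
                           duration_s = sc$duration_s)
    # condition each recording once; both input representations share it
    ds$train$recordings <- lapply(ds$train$recordings, preprocess_recording)
    ds$test$recordings <- lapply(ds$test$recordings, preprocess_recording)
    prep <- list()
    for (mode in c("raw", "feature")) {
      mcfg <- ablation_model_cfg(sc, mode, sc$streams, TRUE)
      tr <- prepare_model_inputs(ds$train, mcfg, condition = FALSE)
      te <- prepare_model_inputs(ds$test, mcfg, condition = FALSE,
                                 norm_stats = tr$norm_stats)
      prep[[mode]] <- list(train = tr, test = te)
    }
    for (ex in experiments) {
      mcfg <- ablation_model_cfg(sc, ex$mode, ex$streams, ex$use_acc)
      # paired design: all four experiments share the same initialisation
      # and training seeds within a suite seed, so their accuracies differ
      # only through the configuration under test
      model <- init_model(mcfg, seed = derive_seed(seed, 7L))
      fit <- train_model(model, prep[[ex$mode]]$train,
                         train_config(batch_size = sc$batch_size,
                                      epochs = sc$epochs, lr = sc$lr,
                                      seed = derive_seed(seed, 55L)))
      met <- evaluate_model(fit$model, prep[[ex$mode]]$test)
      if (!quiet) {
        message(sprintf("seed %d experiment %d (%s): accuracy %.3f",
                        seed, ex$id, ex$desc, met$accuracy))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(experiment = ex$id, description = ex$desc, seed = seed,
                   accuracy = met$accuracy)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(accuracy ~ experiment, out, mean)
  out
}
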