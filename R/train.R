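#' Training configuration
#'
#' Fold-wise training uses Adam (conventional moments), binary
#' cross-entropy with logits, and a piecewise learning-rate schedule:
#' constant at `lr0`, linear decay between `decay_start_epoch` and
#' `decay_end_epoch`, then constant at `final_lr_factor * lr0`. The
#' reference protocol trains 150 epochs at `lr0` of 5.00e-5 or 3.00e-5
#' with batch size 16 or 32 and decay from epoch 100 to 105; scaled-down
#' runs shorten the epoch budget and raise `lr0` accordingly. No weight
#' decay is applied.
#'
#' @param lr0 initial learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param decay_start_epoch,decay_end_epoch linear-decay window.
#' @param final_lr_factor final/initial learning-rate ratio (default 0.01).
#' @param decision_threshold probability threshold of the decision rule.
#' @param augment apply the random 2-of-7 waveform augmentation to training
#'   samples (never to test samples).
#' @param seed RNG seed controlling initialization, shuffling and
#'   augmentation draws.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(lr0 = 5e-5, batch_size = 16L, epochs = 150L,
                        decay_start_epoch = 100L, decay_end_epoch = 105L,
                        final_lr_factor = 0.01, decision_threshold = 0.5,
                        augment = TRUE, seed = 1L) {
  stopifnot(lr0 > 0, batch_size >= 1, epochs >= 1,
            decay_start_epoch < decay_end_epoch,
            final_lr_factor > 0, final_lr_factor <= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decay_start_epoch = as.integer(decay_start_epoch),
                 decay_end_epoch = as.integer(decay_end_epoch),
                 final_lr_factor = final_lr_factor,
                 decision_threshold = decision_threshold,
                 augment = augment, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' Closed form of the schedule: `lr0` for `e <= decay_start_epoch`, linear
#' interpolation down to `final_lr_factor * lr0` at `decay_end_epoch`, and
#' constant afterwards.
#'
#' @param e epoch index, `0 <= e <= epochs`.
#' @param cfg a [trainConfig()].
#' @return learning rate.
#' @export
lrAtEpoch <- function(e, cfg = trainConfig()) {
  if (any(e < 0 | e > cfg$epochs)) stop("epoch index out of range")
  s <- cfg$decay_start_epoch; f <- cfg$decay_end_epoch
  frac <- pmin(1, pmax(0, (e - s) / (f - s)))
  cfg$lr0 * (1 - (1 - cfg$final_lr_factor) * frac)
}

.pairs_to_waves <- function(pairs, rate) {
  list(pre = lapply(pairs$pre, decodeClip, target_rate = rate),
       post = lapply(pairs$post, decodeClip, target_rate = rate))
}

.mel_batch <- function(waves, idx, mel_config, augment_cfg = NULL) {
  stackSpectrograms(lapply(idx, function(i) {
    w <- waves[[i]]
    if (!is.null(augment_cfg)) w <- composeRandomTwo(w, augment_cfg)
    melStandardize(.mel_matrix(w, mel_config))
  }))
}

.eval_logits <- function(det, pre_specs, post_specs, batch = 32L) {
  n <- length(pre_specs)
  out <- numeric(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    out[chunk] <- forwardDetector(det, stackSpectrograms(pre_specs[chunk]),
                                  stackSpectrograms(post_specs[chunk]),
                                  train = FALSE)
  }
  out
}

#' Train the detector on one fold
#'
#' Trains on `/fold{i}/train` of the store and evaluates on the untouched
#' `/fold{i}/test` split. Augmentation (random two of seven waveform
#' transforms) is applied to training waveforms only; test spectrograms
#' are computed once, unaugmented. Fully seeded: identical inputs and seed
#' reproduce the run.
#'
#' @param store path to a dataset store from [writeDatasetStore()].
#' @param fold fold index in `0:(k-1)`.
#' @param model_cfg a [modelConfig()].
#' @param train_cfg a [trainConfig()].
#' @param mel_config a [MelConfig-class].
#' @param augment_cfg an [augmentConfig()].
#' @param verbose print one line per epoch.
#' @return list with `detector`, `history` (per-epoch data.frame: epoch,
#'   lr, train_loss, train_accuracy, test_loss), `test` (per-pair
#'   data.frame: subject_id, label, prob) and `metrics`
#'   (a [metricsReport()] row).
#' @export
trainFold <- function(store, fold, model_cfg = modelConfig(),
                      train_cfg = trainConfig(), mel_config = MelConfig(),
                      augment_cfg = augmentConfig(), verbose = FALSE) {
  train_pairs <- readDatasetStore(store, fold, "train")
  test_pairs <- readDatasetStore(store, fold, "test")
  if (!nrow(train_pairs) || !nrow(test_pairs))
    stop("fold ", fold, " has an empty split")
  set.seed(train_cfg$seed)
  det <- buildDetector(model_cfg, seed = train_cfg$seed + 1L)
  rate <- mel_config@sample_rate
  tr <- .pairs_to_waves(train_pairs, rate)
  te <- .pairs_to_waves(test_pairs, rate)
  test_pre <- lapply(te$pre, function(w)
    melStandardize(.mel_matrix(w, mel_config)))
  test_post <- lapply(te$post, function(w)
    melStandardize(.mel_matrix(w, mel_config)))
  y <- train_pairs$label
  n <- nrow(train_pairs)
  units <- .detector_units(det)
  aug <- if (train_cfg$augment) augment_cfg else NULL
  t_adam <- 0L
  history <- vector("list", train_cfg$epochs)
  for (e in seq_len(train_cfg$epochs)) {
    lr <- lrAtEpoch(e - 1L, train_cfg)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (chunk in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
      xpre <- .mel_batch(tr$pre, chunk, mel_config, aug)
      xpost <- .mel_batch(tr$post, chunk, mel_config, aug)
      fw <- .detector_fwd(det, xpre, xpost, train = TRUE)
      yb <- y[chunk]
      p <- predictProba(fw$logits)
      ep_loss <- ep_loss + sum(bceWithLogits(fw$logits, yb, reduce = FALSE))
      pred <- as.integer(classifyProb(p, train_cfg$decision_threshold) ==
                           "aspiration")
      ep_correct <- ep_correct + sum(pred == yb)
      for (u in units) .unit_zero_grads(u)
      .detector_bwd(det, fw, (p - yb) / length(chunk))
      t_adam <- t_adam + 1L
      for (u in units) .unit_adam_step(u, lr, t_adam)
    }
    test_logits <- .eval_logits(det, test_pre, test_post)
    history[[e]] <- data.frame(
      epoch = e, lr = lr, train_loss = ep_loss / n,
      train_accuracy = 100 * ep_correct / n,
      test_loss = mean(bceWithLogits(test_logits, test_pairs$label)))
    if (verbose)
      message(sprintf("fold %d epoch %3d lr %.2e loss %.4f acc %.1f%%",
                      fold, e, lr, ep_loss / n, 100 * ep_correct / n))
  }
  history <- do.call(rbind, history)
  test_logits <- .eval_logits(det, test_pre, test_post)
  probs <- predictProba(test_logits)
  metrics <- metricsReport(
    test_pairs$label, probs, threshold = train_cfg$decision_threshold,
    loss = mean(bceWithLogits(test_logits, test_pairs$label)),
    train_accuracy = history$train_accuracy[train_cfg$epochs],
    train_loss = history$train_loss[train_cfg$epochs])
  list(detector = det, history = history,
       test = data.frame(subject_id = test_pairs$subject_id,
                         label = test_pairs$label, prob = probs,
                         stringsAsFactors = FALSE),
       metrics = metrics)
}

#' Run the full cross-validation
#'
#' Trains one detector per fold and summarizes the per-fold test metrics
#' as mean, 95% confidence interval and maximum.
#'
#' @inheritParams trainFold
#' @param folds fold indices to run (default: all folds in the store).
#' @return list with `reports` (one [metricsReport()] row per fold),
#'   `summary` (from [summarizeFolds()]), and `tests` (per-fold test
#'   predictions).
#' @export
runCV <- function(store, model_cfg = modelConfig(),
                  train_cfg = trainConfig(), mel_config = MelConfig(),
                  augment_cfg = augmentConfig(), folds = NULL,
                  verbose = FALSE) {
  k <- datasetStoreInfo(store)$k
  if (is.null(folds)) folds <- seq_len(k) - 1L
  reports <- list(); tests <- list()
  for (i in folds) {
    cfg_i <- train_cfg
    cfg_i$seed <- train_cfg$seed + as.integer(i)
    r <- trainFold(store, i, model_cfg, cfg_i, mel_config, augment_cfg,
                   verbose = verbose)
    reports[[length(reports) + 1L]] <- cbind(fold = i, r$metrics)
    tests[[length(tests) + 1L]] <- cbind(fold = i, r$test)
  }
  reports <- do.call(rbind, reports)
  list(reports = reports, summary = summarizeFolds(reports),
       tests = do.call(rbind, tests))
}
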