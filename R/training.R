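#' Training configuration
#'
#' The optimisation protocol: per-pixel cross-entropy loss minimised with
#' Adam at learning rate `alpha = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`,
#' `epsilon = 1e-7`, batch size 8, for 5 epochs.
#'
#' @param alpha Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam numerical stabiliser.
#' @param batch_size Frames per optimisation step.
#' @param epochs Passes over the pool (0 is allowed and leaves the model at
#'   its initialisation).
#' @param seed Integer seed controlling weight initialisation and shuffling.
#' @param shuffle Reshuffle the pool every epoch.
#' @param resample_aug If `TRUE`, augmentation flips/angles are re-drawn
#'   every epoch instead of using the fixed per-copy draws of the pool
#'   manifest (the fixed draws are the default, matching a pool that stacks
#'   a literal set of augmented copies).
#' @return An object of class `mvm_train_config`.
#' @export
train_config <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, batch_size = 8L, epochs = 5L,
                         seed = 1L, shuffle = TRUE, resample_aug = FALSE) {
  if (alpha <= 0 || beta1 <= 0 || beta2 <= 0 || epsilon <= 0) {
    config_error("Adam rates must be positive")
  }
  if (epochs < 0L) config_error("epochs must be >= 0")
  if (batch_size < 1L) config_error("batch_size must be >= 1")
  structure(list(loss = "cross_entropy", alpha = alpha, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), resample_aug = isTRUE(resample_aug)),
            class = "mvm_train_config")
}

# Materialise, normalise and channel-select a batch of pooled frames.
assemble_batch <- function(pool, idx, spec, resample = FALSE) {
  n <- length(idx)
  first <- pool_frame(pool, idx[1])
  h <- dim(first$frame)[1]; w <- dim(first$frame)[2]
  nc <- length(model_channels(spec))
  x <- array(0, c(h, w, nc, n))
  y <- array(0L, c(h, w, n))
  for (b in seq_len(n)) {
    pf <- if (b == 1L) first else pool_frame(pool, idx[b])
    fr <- pf$frame
    mk <- pf$mask
    if (resample && pf$info$aug_id > 0L) {
      aug <- augment_frame(pool$slices[[pf$info$slice_id]]$frames[, , pf$info$frame, ],
                           pool$masks[[pf$info$slice_id]]$labels[, , pf$info$frame])
      fr <- aug$frame
      mk <- aug$mask
    }
    if (is.null(mk)) data_error("training pool has no masks")
    xb <- normalize_input(fr, spec, pool$mag_max[[pf$info$slice_id]])
    x[, , , b] <- xb[, , , 1]
    y[, , b] <- mk
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Trains a network from scratch (or continues a given model) on a training
#' pool with per-pixel cross-entropy and Adam.  Fully seeded: the same seed
#' yields an identical loss history and final weights in single-threaded
#' execution.
#'
#' @param spec A [net_spec()] (a fresh model is built) or an existing
#'   `mvm_model` (training continues).
#' @param pool An [build_training_pool()] pool with masks.
#' @param config A [train_config()].
#' @return An object of class `mvm_fit`: a list with the trained `model`,
#'   the per-epoch `history` tibble (`epoch`, `mean_loss`) and the `config`.
#' @export
train_model <- function(spec, pool, config = train_config()) {
  stopifnot(inherits(config, "mvm_train_config"))
  n <- pool_size(pool)
  if (n == 0L) data_error("empty training pool")
  if (config$batch_size > n) data_error("batch size exceeds pool size")
  with_seed(config$seed, {
    model <- if (inherits(spec, "mvm_model")) spec else build_model(spec)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      tot <- 0
      nb <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- assemble_batch(pool, idx, model$spec, config$resample_aug)
        loss <- nn_train_batch(model$ptr, batch$x, batch$y,
                               config$alpha, config$beta1, config$beta2,
                               config$epsilon)
        tot <- tot + loss * length(idx)
        nb <- nb + length(idx)
      }
      losses[ep] <- tot / nb
    }
    history <- tibble::tibble(epoch = seq_len(config$epochs),
                              mean_loss = losses)
  })
  structure(list(model = model, history = history, config = config,
                 n_frames = n),
            class = "mvm_fit")
}

#' @export
print.mvm_fit <- function(x, ...) {
  cat(sprintf("<mvm_fit %s: %d epochs over %d frames%s>\n",
              x$model$spec$variant, nrow(x$history), x$n_frames,
              if (nrow(x$history) > 0) {
                sprintf(", final mean loss %.4g",
                        x$history$mean_loss[nrow(x$history)])
              } else ""))
  invisible(x)
}

#' Cross-validate a segmentation network over cine slices
#'
#' Runs the k-fold protocol: for each fold, a training pool of original plus
#' augmented frames is built from the training slices only (a leakage audit
#' asserts the held-out slices are absent), a fresh model is trained, and the
#' original (never augmented) frames of the held-out slices are predicted.
#' Every slice is therefore predicted exactly once, by the model whose
#' training pool excluded it.
#'
#' @param data A tibble with columns `slice_id`, `subject_id` and list
#'   columns `slice`, `mask` (e.g. from [generate_phantom_dataset()]).
#' @param spec A [net_spec()].
#' @param config A [train_config()]; fold `f` trains with seed
#'   `config$seed + f`.
#' @param folds Optional fold assignment tibble from [make_cv_folds()];
#'   built from `config$seed` when omitted.
#' @param k Number of folds when `folds` is omitted.
#' @param n_aug Augmented copies per training slice.
#' @param split_level `"slice"` (default) or `"subject"`: whether folds
#'   partition slices directly or whole subjects.
#' @return An object of class `mvm_cv`: the input tibble gains a `pred`
#'   list column of predicted masks; `$fits` holds the per-fold `mvm_fit`s
#'   and `$folds` the assignment.
#' @export
cross_validate <- function(data, spec, config = train_config(), folds = NULL,
                           k = 5L, n_aug = 4L,
                           split_level = c("slice", "subject")) {
  split_level <- match.arg(split_level)
  stopifnot(all(c("slice_id", "slice", "mask") %in% names(data)))
  if (is.null(folds)) {
    folds <- if (split_level == "subject") {
      subj <- unique(data$subject_id)
      sf <- make_cv_folds(subj, k = k, seed = config$seed)
      tibble::tibble(slice_id = data$slice_id,
                     fold = sf$fold[match(data$subject_id, sf$slice_id)])
    } else {
      make_cv_folds(data$slice_id, k = k, seed = config$seed)
    }
  }
  if (!setequal(folds$slice_id, data$slice_id)) {
    config_error("fold assignment does not cover the dataset")
  }
  preds <- vector("list", nrow(data))
  names(preds) <- data$slice_id
  fits <- list()
  for (f in sort(unique(folds$fold))) {
    held <- folds$slice_id[folds$fold == f]
    train_rows <- data[!data$slice_id %in% held, ]
    if (nrow(train_rows) == 0L) config_error("fold without training data")
    pool <- build_training_pool(train_rows, n_aug = n_aug,
                                seed = config$seed + f)
    audit_pool_leakage(pool, held)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_model(spec, pool, cfg_f)
    for (sid in held) {
      sl <- data$slice[[which(data$slice_id == sid)]]
      preds[[sid]] <- predict_mask(fit$model, sl)
    }
    fits[[paste0("fold", f)]] <- fit
  }
  out <- data
  out$pred <- preds[out$slice_id]
  structure(list(data = out, folds = folds, fits = fits, spec = spec,
                 config = config),
            class = "mvm_cv")
}

#' @export
print.mvm_cv <- function(x, ...) {
  cat(sprintf("<mvm_cv %s: %d slices, %d folds>\n",
              x$spec$variant, nrow(x$data), length(x$fits)))
  invisible(x)
}
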