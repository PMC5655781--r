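# Trial-wise and cropped training: crop enumeration, the dense multi-crop
# forward pass, loss assembly (plain NLL or tied neighbour-crop loss) and
# the Adam optimization loop with early stopping.

#' Crop configuration for cropped training
#'
#' @param crop_length_s crop length in seconds (default 2).
#' @param n_simultaneous_crops how many crops a single dense forward pass
#'   may cover; longer trials are processed in overlapping segments
#'   (default 625, i.e. a whole -0.5..4 s trial at 250 Hz in one pass).
#' @param tied_loss add the cross-entropy between neighbouring crop
#'   predictions to the loss (default FALSE).
#' @return object of class `crop_config`.
#' @export
crop_config <- function(crop_length_s = 2, n_simultaneous_crops = 625,
                        tied_loss = FALSE) {
  structure(list(crop_length_s = crop_length_s,
                 n_simultaneous_crops = as.integer(n_simultaneous_crops),
                 tied_loss = tied_loss),
            class = "crop_config")
}

#' Enumerate the crops of a trial
#'
#' One crop per sample: crop t (0-based) covers samples `[t, t + T')`, for
#' t in 0 .. T - T' - 1, giving T - T' crops, each inheriting the trial's
#' label.
#'
#' @param trial E x T matrix.
#' @param crop_length T' in samples (< T).
#' @return list of E x T' matrices with attribute `starts` (0-based).
#' @export
extract_crops <- function(trial, crop_length) {
  T_len <- ncol(trial)
  if (crop_length >= T_len) {
    stop("crop length ", crop_length, " must be smaller than the trial ",
         "length ", T_len)
  }
  n <- T_len - crop_length
  crops <- lapply(seq_len(n) - 1L, function(t) {
    trial[, (t + 1L):(t + crop_length), drop = FALSE]
  })
  attr(crops, "starts") <- seq_len(n) - 1L
  crops
}

#' Dense multi-crop forward pass
#'
#' Computes per-crop class scores for every possible crop start of
#' `super_input` in a single forward pass, reusing shared convolution
#' outputs. Strided layers are handled by keeping one stream per stride
#' offset and interleaving only after the final layer, so the outputs equal
#' (to float precision) running each crop through the network separately.
#' Models containing padded ("same") convolutions are refused, since
#' padding breaks this equivalence.
#'
#' @param model an `eeg_network` built for crop-length inputs.
#' @param super_input E x T_in matrix with T_in >= the model's input length.
#' @return list with `scores` (K x n_crops), `probabilities` (K x n_crops)
#'   and `starts` (0-based crop starts, 0 .. T_in - T').
#' @export
dense_multi_crop_forward <- function(model, super_input) {
  T_in <- ncol(super_input)
  T_crop <- model$spec$input_shape[2]
  if (T_in < T_crop) {
    stop("input (", T_in, " samples) shorter than the model's crop length (",
         T_crop, ")")
  }
  fw <- network_forward(model, super_input, dense = TRUE)
  scores <- fw$scores; probs <- fw$probabilities
  dim(scores) <- dim(scores)[1:2]
  dim(probs) <- dim(probs)[1:2]
  list(scores = scores, probabilities = probs, starts = fw$positions)
}

#' Aggregate per-crop predictions into a trial prediction
#'
#' The arithmetic mean of the per-crop probability vectors; the predicted
#' label is the argmax (ties broken toward the lower class index).
#'
#' @param per_crop K x n_crops matrix (or list of probability vectors).
#' @return list with `probabilities` (length K, sums to 1) and `label`
#'   (0-based).
#' @export
aggregate_crop_predictions <- function(per_crop) {
  if (is.list(per_crop)) per_crop <- do.call(cbind, per_crop)
  if (is.null(dim(per_crop)) || ncol(per_crop) < 1) {
    stop("need at least one per-crop prediction")
  }
  p <- rowMeans(per_crop)
  list(probabilities = p, label = which.max(p) - 1L)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,adam_eps Adam moment decays and epsilon.
#' @param batch_size trials per mini-batch (default 16).
#' @param max_epochs epoch budget (default 100).
#' @param valid_fraction fraction of training trials held out for early
#'   stopping, in (0, 0.5] (default 0.2).
#' @param patience epochs without validation-accuracy improvement before
#'   stopping (default 80).
#' @param second_phase after early stopping, retrain on all trials until the
#'   combined loss falls below the best first-phase training loss
#'   (default FALSE).
#' @param seed integer seed controlling the split, shuffling, dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, batch_size = 16, max_epochs = 100,
                         valid_fraction = 0.2, patience = 80,
                         second_phase = FALSE, seed = 1L) {
  stopifnot(valid_fraction > 0, valid_fraction <= 0.5)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 valid_fraction = valid_fraction,
                 patience = as.integer(patience),
                 second_phase = second_phase, seed = as.integer(seed)),
            class = "train_config")
}

# --- Adam over the nested parameter list -----------------------------------
# batchnorm running statistics carry NULL gradients and stay untouched

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "replace", classes = c("numeric", "array", "matrix"))
}

adam_step <- function(params, grads, state, t, cfg) {
  step_one <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- step_one(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
    s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g * g
    mhat <- s$m / (1 - cfg$beta1^t)
    vhat <- s$v / (1 - cfg$beta2^t)
    list(p = p - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps), s = s)
  }
  out_p <- params; out_s <- state
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    r <- step_one(params[[i]], grads[[i]], state[[i]])
    out_p[[i]] <- r$p
    out_s[[i]] <- r$s
  }
  list(params = out_p, state = out_s)
}

# loss and score-gradient for a (K, P, B) score block; labels length B.
# With tied = TRUE the cross-entropy between each crop and its right
# neighbour (within the trial) is added.
score_loss_grad <- function(scores, labels, tied = FALSE) {
  K <- dim(scores)[1]; P <- dim(scores)[2]; B <- dim(scores)[3]
  total <- 0
  dscores <- array(0, dim(scores))
  for (b in seq_len(B)) {
    z <- matrix(scores[, , b], K, P)
    p <- softmax(z)
    pc <- pmax(p, PROB_EPS)
    onehot <- numeric(K); onehot[labels[b] + 1L] <- 1
    total <- total + sum(-log(pc[labels[b] + 1L, ]))
    g <- p - onehot
    if (tied && P > 1) {
      for (t in seq_len(P - 1L)) {
        q <- p[, t + 1L]
        total <- total - sum(log(pc[, t]) * q)
        # d/dz_t of -sum_k q_k log p_k  (q fixed): p_t * sum(q) - q
        g[, t] <- g[, t] + p[, t] - q
        # d/dz_{t+1}: softmax Jacobian applied to a = -log p_t
        a <- -log(pc[, t])
        g[, t + 1L] <- g[, t + 1L] + q * (a - sum(a * q))
      }
    }
    dscores[, , b] <- g
  }
  n_pred <- P * B
  list(loss = total / n_pred, dscores = dscores / n_pred)
}

#' Train a network on a dataset
#'
#' Mini-batch Adam with early stopping: a stratified validation split is
#' held out, training stops when validation accuracy has not improved for
#' `patience` epochs (the best-epoch parameters are kept). With
#' `strategy = "cropped"` every trial is decoded densely into per-crop
#' predictions (one per sample) in a single pass and the loss is the mean
#' per-crop loss, optionally with the tied neighbour-crop term.
#'
#' @param model an `eeg_network`; for cropped training its input length must
#'   be the crop length.
#' @param dataset a (standardized) `eeg_dataset`.
#' @param strategy "trial" or "cropped".
#' @param config a [train_config()].
#' @param crops a [crop_config()] (cropped strategy only).
#' @param verbose print per-epoch progress.
#' @return the trained `eeg_network`, with the training log (per-epoch
#'   train/valid loss and accuracy, data.frame) in `$log`.
#' @export
fit <- function(model, dataset, strategy = c("trial", "cropped"),
                config = train_config(), crops = crop_config(),
                verbose = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "eeg_network"), inherits(dataset, "eeg_dataset"))
  n <- dim(dataset$trials)[1]
  T_trial <- dim(dataset$trials)[3]
  T_model <- model$spec$input_shape[2]
  if (strategy == "trial" && T_trial != T_model) {
    stop("trial length ", T_trial, " does not match the model input length ",
         T_model)
  }
  if (strategy == "cropped" && T_model >= T_trial) {
    stop("cropped training needs a model input (crop) length below the ",
         "trial length")
  }
  tied <- strategy == "cropped" && isTRUE(crops$tied_loss)

  withr::with_seed(config$seed, {
    valid_idx <- stratified_holdout(dataset$labels, config$valid_fraction)
    train_idx <- setdiff(seq_len(n), valid_idx)
    state <- adam_init(model$params)
    best <- list(acc = -Inf, loss = Inf, params = model$params, epoch = 0L,
                 train_loss = Inf)
    log <- list()
    t_adam <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        batch <- dataset$trials[idx, , , drop = FALSE]
        labels <- dataset$labels[idx]
        fw <- forward_chain(model$spec$layers, model$params,
                            trials_to_stream(batch), training = TRUE,
                            dense = strategy == "cropped")
        model$params <- fw$params  # batchnorm running statistics
        pred <- collect_predictions(fw$streams)
        if (strategy == "cropped") {
          keep <- seq_len(T_trial - T_model)  # crop enumeration count
          pred$scores <- pred$scores[, keep, , drop = FALSE]
        }
        lg <- score_loss_grad(pred$scores, labels, tied)
        if (!is.finite(lg$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; lower the learning rate or check standardization")
        }
        dsc <- lg$dscores
        if (strategy == "cropped") {
          full <- array(0, c(dim(dsc)[1], length(pred$positions), dim(dsc)[3]))
          full[, keep, ] <- dsc
          dsc <- full
        }
        dstreams <- scatter_dscores(fw$streams, pred, dsc)
        bw <- backward_chain(model$spec$layers, model$params, fw$caches,
                             dstreams)
        t_adam <- t_adam + 1L
        up <- adam_step(model$params, bw$dparams, state, t_adam, config)
        model$params <- up$params
        state <- up$state
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_n <- ep_n + length(idx)
        mean_p <- apply(softmax_block(pred$scores), c(1, 3), mean)
        ep_correct <- ep_correct + sum(max.col(t(mean_p),
                                               ties.method = "first") - 1L ==
                                       labels)
      }
      val <- evaluate_network(model, dataset, valid_idx, strategy)
      log[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n,
        train_acc = ep_correct / ep_n,
        valid_loss = val$loss, valid_acc = val$acc)
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | valid loss %.4f acc %.3f",
                        epoch, ep_loss / ep_n, ep_correct / ep_n,
                        val$loss, val$acc))
      }
      # accuracy decides; validation loss breaks ties between equal epochs
      if (val$acc > best$acc ||
          (val$acc == best$acc && val$loss < best$loss)) {
        best <- list(acc = val$acc, loss = val$loss, params = model$params,
                     epoch = epoch, train_loss = ep_loss / ep_n)
      }
      if (epoch - best$epoch >= config$patience) break
    }
    model$params <- best$params
    log <- do.call(rbind, log)

    if (isTRUE(config$second_phase)) {
      target <- best$train_loss
      for (epoch2 in seq_len(config$max_epochs)) {
        ord <- sample(n)
        ep_loss <- 0; ep_n <- 0
        for (start in seq(1, n, by = config$batch_size)) {
          idx <- ord[start:min(start + config$batch_size - 1L, n)]
          batch <- dataset$trials[idx, , , drop = FALSE]
          fw <- forward_chain(model$spec$layers, model$params,
                              trials_to_stream(batch), training = TRUE,
                              dense = strategy == "cropped")
          model$params <- fw$params
          pred <- collect_predictions(fw$streams)
          if (strategy == "cropped") {
            keep <- seq_len(T_trial - T_model)
            pred$scores <- pred$scores[, keep, , drop = FALSE]
          }
          lg <- score_loss_grad(pred$scores, dataset$labels[idx], tied)
          dsc <- lg$dscores
          if (strategy == "cropped") {
            full <- array(0, c(dim(dsc)[1], length(pred$positions),
                               dim(dsc)[3]))
            full[, seq_len(T_trial - T_model), ] <- dsc
            dsc <- full
          }
          dstreams <- scatter_dscores(fw$streams, pred, dsc)
          bw <- backward_chain(model$spec$layers, model$params, fw$caches,
                               dstreams)
          t_adam <- t_adam + 1L
          up <- adam_step(model$params, bw$dparams, state, t_adam, config)
          model$params <- up$params
          state <- up$state
          ep_loss <- ep_loss + lg$loss * length(idx)
          ep_n <- ep_n + length(idx)
        }
        if (ep_loss / ep_n <= target) break
      }
    }
    model$log <- log
    model$train_idx <- train_idx
    model$valid_idx <- valid_idx
    model
  })
}

softmax_block <- function(scores) {
  out <- scores
  for (b in seq_len(dim(scores)[3])) {
    out[, , b] <- softmax(matrix(scores[, , b], dim(scores)[1]))
  }
  out
}

stratified_holdout <- function(labels, fraction) {
  idx <- unlist(lapply(unique(labels), function(k) {
    ks <- which(labels == k)
    sample(ks, max(1L, round(length(ks) * fraction)))
  }))
  sort(idx)
}

evaluate_network <- function(model, dataset, idx, strategy,
                             chunk = 32L) {
  preds <- predict_network(model, dataset$trials[idx, , , drop = FALSE],
                           strategy = strategy, chunk = chunk)
  labels <- dataset$labels[idx]
  ll <- -mean(log(pmax(preds$probabilities[cbind(seq_along(idx),
                                                 labels + 1L)], PROB_EPS)))
  list(acc = mean(preds$labels == labels), loss = ll)
}

#' Predict trial labels with a trained network
#'
#' Trial-wise models score each trial directly; cropped models are applied
#' densely and the mean of the per-crop probabilities is the trial
#' prediction.
#'
#' @param model a trained `eeg_network`.
#' @param trials array (n, E, T) or an `eeg_dataset`.
#' @param strategy "trial" or "cropped".
#' @param chunk trials per forward pass (memory control).
#' @return list with `labels` (0-based) and `probabilities` (n x K).
#' @export
predict_network <- function(model, trials, strategy = c("trial", "cropped"),
                            chunk = 32L) {
  strategy <- match.arg(strategy)
  if (inherits(trials, "eeg_dataset")) trials <- trials$trials
  n <- dim(trials)[1]
  K <- model$spec$n_classes
  probs <- matrix(0, n, K)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- network_forward(model, trials[idx, , , drop = FALSE],
                          dense = strategy == "cropped")
    # mean over prediction positions (one position trial-wise)
    probs[idx, ] <- t(apply(fw$probabilities, c(1, 3), mean))
  }
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}
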