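# Feature-attribution methods: input-feature unit-output correlation maps,
# envelope/unit class correlations, and input-perturbation
# network-prediction correlation maps.

# Pearson correlation that returns 0 (with a flag) for degenerate variance
safe_cor <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(x, y)
}

cor_matrix_safe <- function(X, Y) {
  # columns with zero variance yield r = 0 instead of NA
  sx <- apply(X, 2, stats::sd)
  sy <- apply(Y, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X, Y))
  r[sx < 1e-12, ] <- 0
  r[, sy < 1e-12] <- 0
  r
}

# unit outputs of a given top-level layer: returns list per trial-chunk of
# arrays (C, 1|E, T_layer, B)
layer_outputs <- function(model, trials, layer_index, chunk = 32L) {
  n <- dim(trials)[1]
  outs <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    streams <- trials_to_stream(trials[idx, , , drop = FALSE])
    fw <- forward_chain(model$spec$layers[seq_len(layer_index)],
                        model$params[seq_len(layer_index)],
                        streams, training = FALSE, dense = FALSE)
    x <- fw$streams[[1]]$x
    outs <- if (is.null(outs)) x else {
      d <- dim(x)
      big <- array(0, c(d[1], d[2], d[3], dim(outs)[4] + d[4]))
      big[, , , seq_len(dim(outs)[4])] <- outs
      big[, , , dim(outs)[4] + seq_len(d[4])] <- x
      big
    }
  }
  outs
}

# default filter bank for the correlation maps: contiguous `width`-Hz bands
# from 0 up to `f_max` (0-119 Hz at width 6 -> 7-13 style bands are among
# band aggregates, see band_aggregate)
correlation_filter_bank <- function(fs, f_max = min(119, floor(fs / 2) - 1),
                                    width = 6) {
  lows <- seq(0, f_max - width, by = width)
  lapply(lows, function(lo) band_spec(lo, lo + width))
}

#' Input-feature unit-output correlation map
#'
#' For a chosen layer: band-pass each electrode signal into every band of a
#' filter bank (zero-phase), compute the Hilbert envelope, the moving-window
#' mean of the squared envelope with the window equal to the layer's
#' temporal receptive field, and correlate these band-power features (at the
#' receptive-field positions of the layer's units, concatenated over all
#' samples of all trials) with the unit outputs of every convolutional
#' filter. Computed for the trained model and an untrained reference model
#' (same architecture, fresh seeded initialization); the difference isolates
#' training effects from architecture effects.
#'
#' @param trained_model,untrained_model `eeg_network`s sharing a spec.
#' @param dataset an `eeg_dataset` (use the trials the model was trained on,
#'   standardized the same way).
#' @param layer_index top-level layer whose outputs are analyzed (default:
#'   last conv-pool block output).
#' @param bands list of [band_spec()]; default a filter bank from 0 to
#'   min(119, Nyquist-1) Hz.
#' @return object of class `correlation_map`: arrays
#'   `trained`, `untrained`, `difference` of dimension
#'   (electrode, band, filter), plus `scalp` (electrode x band, mean |r|
#'   over filters, trained minus untrained) and metadata.
#' @export
unit_output_correlation_map <- function(trained_model, untrained_model,
                                        dataset, layer_index = NULL,
                                        bands = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (is.null(layer_index)) {
    layer_index <- utils::tail(block_output_layers(trained_model$spec), 1)
  }
  if (is.null(bands)) bands <- correlation_filter_bank(dataset$fs)
  rf <- receptive_field(trained_model$spec, layer_index)
  dims <- dataset_dims(dataset)
  if (rf["temporal"] > dims["T"]) {
    stop("receptive field (", rf["temporal"], " samples) exceeds the trial ",
         "length (", dims["T"], ")")
  }
  feats <- envelope_features(dataset, bands, rf["temporal"])

  one_model <- function(model) {
    outs <- layer_outputs(model, dataset$trials, layer_index)
    d <- dim(outs)  # (C, 1, T_layer, B)
    jump <- unit_jump(model$spec, layer_index)
    # unit t (0-based) sees input starting at sample t * jump
    pos <- (seq_len(d[3]) - 1L) * jump + 1L
    U <- matrix(0, d[3] * d[4], d[1])  # (positions*trials) x filters
    for (c_i in seq_len(d[1])) {
      U[, c_i] <- as.vector(outs[c_i, 1, , ])
    }
    r <- array(0, c(dims["E"], length(bands), d[1]))
    for (b_i in seq_along(bands)) {
      Fm <- feats[[b_i]][, pos, , drop = FALSE]  # (E, positions, trials)
      Fmat <- matrix(0, d[3] * d[4], dims["E"])
      for (e in seq_len(dims["E"])) Fmat[, e] <- as.vector(Fm[e, , ])
      r[, b_i, ] <- cor_matrix_safe(Fmat, U)
    }
    r
  }
  r_tr <- one_model(trained_model)
  r_un <- one_model(untrained_model)
  band_names <- vapply(bands, `[[`, "", "name")
  dn <- list(dataset$electrodes$name, band_names, NULL)
  dimnames(r_tr) <- dimnames(r_un) <- dn
  diff <- r_tr - r_un
  scalp <- apply(abs(r_tr), c(1, 2), mean) - apply(abs(r_un), c(1, 2), mean)
  structure(list(trained = r_tr, untrained = r_un, difference = diff,
                 scalp = scalp, bands = bands, layer_index = layer_index,
                 receptive_field = rf, electrodes = dataset$electrodes),
            class = "correlation_map")
}

# product of strides up to layer_index (input-sample spacing of that
# layer's units)
unit_jump <- function(spec, layer_index) {
  jump <- 1L
  for (i in seq_len(layer_index)) {
    s <- spec$layers[[i]]$stride
    if (!is.null(s)) jump <- jump * s
  }
  jump
}

# per-band moving mean-squared-envelope features for all trials:
# list over bands of arrays (E, T - window + 1, n)
envelope_features <- function(dataset, bands, window) {
  dims <- dataset_dims(dataset)
  lapply(bands, function(b) {
    out <- array(0, c(dims["E"], dims["T"] - window + 1L, dims["n"]))
    for (j in seq_len(dims["n"])) {
      env <- band_envelope(dataset$trials[j, , ], b, dataset$fs)
      out[, , j] <- receptive_field_mean_sq_envelope(env, window)
    }
    out
  })
}

#' Envelope band-power vs class correlation map
#'
#' Correlates moving-window mean squared envelope values (window =
#' `window`, by default the receptive field of a network's last layer, i.e.
#' the trial length here) with the one-hot-encoded class labels,
#' concatenated over all window positions of all trials: one Pearson r per
#' (class, electrode, band).
#'
#' @param dataset an `eeg_dataset` with at least two classes present.
#' @param bands list of [band_spec()] (default: alpha/beta/gamma).
#' @param window window length in samples (default: trial length).
#' @return array (class, electrode, band) of correlations, class
#'   `class_correlation_map`.
#' @export
envelope_class_correlation <- function(dataset, bands = canonical_bands(),
                                       window = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (length(unique(dataset$labels)) < 2) {
    stop("class correlations need at least two classes in the dataset")
  }
  dims <- dataset_dims(dataset)
  if (is.null(window)) window <- dims["T"]
  feats <- envelope_features(dataset, bands, window)
  K <- length(dataset$class_names)
  n_pos <- dims["T"] - window + 1L
  onehot <- matrix(0, n_pos * dims["n"], K)
  for (k in seq_len(K)) {
    onehot[, k] <- rep(as.numeric(dataset$labels == k - 1L), each = n_pos)
  }
  r <- array(0, c(K, dims["E"], length(bands)),
             dimnames = list(dataset$class_names, dataset$electrodes$name,
                             vapply(bands, `[[`, "", "name")))
  for (b_i in seq_along(bands)) {
    Fmat <- matrix(0, n_pos * dims["n"], dims["E"])
    for (e in seq_len(dims["E"])) Fmat[, e] <- as.vector(feats[[b_i]][e, , ])
    r[, , b_i] <- t(cor_matrix_safe(Fmat, onehot))
  }
  structure(r, class = "class_correlation_map")
}

#' Layer-wise unit-output vs class correlation profile
#'
#' For each conv-pool block output, correlates every unit output (mean over
#' the layer's time positions, per trial) with the one-hot class labels and
#' summarizes per layer as (a) the mean absolute correlation over all
#' classes and filters and (b) the mean over classes of the maximum
#' absolute correlation over filters. Reported for the trained model, the
#' untrained reference, and their difference.
#'
#' @param trained_model,untrained_model `eeg_network`s sharing a spec.
#' @param dataset an `eeg_dataset`.
#' @param layer_indices layers to profile (default: all block outputs plus
#'   the final layer).
#' @return data.frame with columns layer_index, mean_abs / mean_max for
#'   trained, untrained and difference.
#' @export
unit_class_correlation_profile <- function(trained_model, untrained_model,
                                           dataset, layer_indices = NULL) {
  if (is.null(layer_indices)) {
    layer_indices <- c(block_output_layers(trained_model$spec),
                       length(trained_model$spec$layers))
  }
  K <- length(dataset$class_names)
  n <- dim(dataset$trials)[1]
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), dataset$labels + 1L)] <- 1
  one <- function(model, li) {
    outs <- layer_outputs(model, dataset$trials, li)
    d <- dim(outs)
    U <- matrix(0, n, d[1])
    for (c_i in seq_len(d[1])) {
      U[, c_i] <- colMeans(matrix(outs[c_i, , , ], d[2] * d[3], d[4]))
    }
    r <- abs(cor_matrix_safe(U, onehot))  # filters x classes
    c(mean_abs = mean(r), mean_max = mean(apply(r, 2, max)))
  }
  rows <- lapply(layer_indices, function(li) {
    tr <- one(trained_model, li)
    un <- one(untrained_model, li)
    data.frame(layer_index = li,
               mean_abs_trained = tr["mean_abs"],
               mean_max_trained = tr["mean_max"],
               mean_abs_untrained = un["mean_abs"],
               mean_max_untrained = un["mean_max"],
               mean_abs_difference = tr["mean_abs"] - un["mean_abs"],
               mean_max_difference = tr["mean_max"] - un["mean_max"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# real-input FFT decomposition of trials: amplitudes and phases per
# (electrode, bin); bins cover 0 .. floor(T/2) * fs / T
trial_rfft <- function(trials) {
  d <- dim(trials)  # (n, E, T)
  n_bins <- d[3] %/% 2L + 1L
  amps <- array(0, c(d[1], d[2], n_bins))
  phases <- array(0, c(d[1], d[2], n_bins))
  for (j in seq_len(d[1])) {
    for (e in seq_len(d[2])) {
      X <- stats::fft(trials[j, e, ])[seq_len(n_bins)]
      amps[j, e, ] <- Mod(X)
      phases[j, e, ] <- Arg(X)
    }
  }
  list(amps = amps, phases = phases, T_len = d[3])
}

rfft_to_signal <- function(amp, phase, T_len) {
  # rebuild the full Hermitian spectrum from the half spectrum
  n_bins <- length(amp)
  X <- complex(modulus = amp, argument = phase)
  if (T_len %% 2L == 0L) {
    full <- c(X, Conj(X[(n_bins - 1L):2L]))
  } else {
    full <- c(X, Conj(X[n_bins:2L]))
  }
  Re(stats::fft(full, inverse = TRUE)) / T_len
}

#' Input-perturbation network-prediction correlation map
#'
#' Transforms the trials to the frequency domain, adds one Gaussian noise
#' field (per repetition, shared across trials) to the spectral amplitudes
#' — phases untouched, amplitudes floored at zero —, retransforms, and runs
#' the model. The change in pre-softmax class outputs (averaged over
#' trials) is correlated, across repetitions, with the amplitude change per
#' (electrode, frequency bin): a causal attribution map. The fraction of
#' unperturbed classification accuracy retained under perturbation is always
#' computed as a safeguard against adversarial-like behaviour.
#'
#' @param model a trained `eeg_network`.
#' @param trials array (n, E, T) or `eeg_dataset`, standardized as in
#'   training.
#' @param labels 0-based labels (needed for the robustness ratio; taken from
#'   the dataset when one is supplied).
#' @param n_perturbations repetitions (default 400; must be >= 3).
#' @param noise_sd standard deviation of the amplitude noise (default 1).
#' @param seed RNG seed for the noise fields.
#' @param chunk trials per forward pass.
#' @return object of class `perturbation_result`: `correlations`
#'   (electrode x bin x class), `freqs` (Hz per bin), `robustness_ratio`
#'   (percent of unperturbed accuracy retained), `unperturbed_accuracy`,
#'   `mean_perturbed_accuracy`, `n_perturbations`.
#' @export
perturbation_correlation_map <- function(model, trials, labels = NULL,
                                         n_perturbations = 400,
                                         noise_sd = 1, seed = 1L,
                                         chunk = 32L, fs = NULL) {
  if (inherits(trials, "eeg_dataset")) {
    labels <- trials$labels
    fs <- trials$fs
    trials <- trials$trials
  }
  if (n_perturbations < 3) {
    stop("need at least 3 perturbations for a correlation")
  }
  d <- dim(trials)
  spec <- trial_rfft(trials)
  n_bins <- dim(spec$amps)[3]
  K <- model$spec$n_classes

  base <- predict_scores(model, trials, chunk)
  base_mean <- colMeans(base$scores)  # per class, mean over trials
  base_acc <- if (!is.null(labels)) mean(base$labels == labels) else NA_real_

  noise_mat <- matrix(0, n_perturbations, d[2] * n_bins)
  dscore_mat <- matrix(0, n_perturbations, K)
  acc_sum <- 0
  withr::with_seed(seed, {
    for (r in seq_len(n_perturbations)) {
      noise <- matrix(stats::rnorm(d[2] * n_bins, sd = noise_sd),
                      d[2], n_bins)
      pert <- trials
      for (j in seq_len(d[1])) {
        for (e in seq_len(d[2])) {
          amp <- pmax(spec$amps[j, e, ] + noise[e, ], 0)
          pert[j, e, ] <- rfft_to_signal(amp, spec$phases[j, e, ], d[3])
        }
      }
      ps <- predict_scores(model, pert, chunk)
      noise_mat[r, ] <- as.vector(noise)
      dscore_mat[r, ] <- colMeans(ps$scores) - base_mean
      if (!is.null(labels)) acc_sum <- acc_sum + mean(ps$labels == labels)
    }
  })
  r_flat <- cor_matrix_safe(noise_mat, dscore_mat)  # (E*bins) x K
  correlations <- array(r_flat, c(d[2], n_bins, K))
  mean_acc <- if (!is.null(labels)) acc_sum / n_perturbations else NA_real_
  structure(list(
    correlations = correlations,
    freqs = if (!is.null(fs)) (seq_len(n_bins) - 1L) * fs / d[3] else NULL,
    robustness_ratio = if (!is.null(labels)) 100 * mean_acc / base_acc else
      NA_real_,
    unperturbed_accuracy = base_acc, mean_perturbed_accuracy = mean_acc,
    n_perturbations = n_perturbations, noise_sd = noise_sd
  ), class = "perturbation_result")
}

predict_scores <- function(model, trials, chunk = 32L) {
  n <- dim(trials)[1]
  K <- model$spec$n_classes
  scores <- matrix(0, n, K)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- network_forward(model, trials[idx, , , drop = FALSE])
    scores[idx, ] <- t(apply(fw$scores, c(1, 3), mean))
  }
  list(scores = scores,
       labels = max.col(scores, ties.method = "first") - 1L)
}

#' Aggregate a perturbation map over frequency bands; frequency profile
#'
#' The band value per (electrode, class) is the mean correlation over the
#' frequency bins inside the band; the overall frequency profile is the
#' mean absolute correlation over all classes and electrodes per bin.
#'
#' @param result a `perturbation_result` (or any array electrode x bin x
#'   class with a `freqs` vector).
#' @param bands list of [band_spec()] (default alpha/beta/gamma).
#' @param freqs bin frequencies in Hz (taken from `result` if present).
#' @return list with `band_maps` (electrode x class matrix per band) and
#'   `profile` (data.frame freq, mean_abs_r).
#' @export
band_aggregate_and_frequency_profile <- function(result,
                                                 bands = canonical_bands(),
                                                 freqs = NULL) {
  if (inherits(result, "perturbation_result")) {
    freqs <- result$freqs
    arr <- result$correlations
  } else {
    arr <- result
  }
  stopifnot(!is.null(freqs), length(freqs) == dim(arr)[2])
  band_maps <- lapply(bands, function(b) {
    sel <- which(freqs >= b$low & freqs <= b$high)
    if (!length(sel)) {
      stop("band ", b$name, " [", b$low, ", ", b$high,
           "] Hz contains no frequency bin")
    }
    apply(arr[, sel, , drop = FALSE], c(1, 3), mean)
  })
  names(band_maps) <- vapply(bands, `[[`, "", "name")
  profile <- data.frame(
    freq = freqs,
    mean_abs_r = apply(abs(arr), 2, mean)
  )
  list(band_maps = band_maps, profile = profile)
}

#' Scalp map of per-electrode values
#'
#' Draws one colored dot per electrode at its 2-D projected position
#' (the rendering used throughout the correlation-map figures); blue =
#' negative, red = positive, scaled symmetrically.
#'
#' @param values named numeric vector (one per electrode).
#' @param electrodes data.frame with `name`, `x`, `y`.
#' @param main plot title.
#' @param cex dot size.
#' @return invisibly, the values.
#' @export
plot_scalp_map <- function(values, electrodes, main = "", cex = 4) {
  lim <- max(abs(values), 1e-9)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  col <- pal[round(50 * values / lim) + 51]
  graphics::plot(electrodes$x, electrodes$y, pch = 21, bg = col, cex = cex,
                 xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "", ylab = "", axes = FALSE, main = main)
  graphics::symbols(0, 0, circles = 1.05, inches = FALSE, add = TRUE)
  graphics::text(electrodes$x, electrodes$y - 0.13, electrodes$name,
                 cex = 0.7)
  invisible(values)
}
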