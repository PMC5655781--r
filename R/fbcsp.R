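#' Common spatial patterns for two classes
#'
#' Computes spatial filters as generalized eigenvectors of the class
#' covariance pair (C_A, C_A + C_B): the first filter maximizes the variance
#' ratio var_A / (var_A + var_B) of the filtered signal, the last minimizes
#' it. Returned filters satisfy W' (C_A + C_B) W = I and the `n_filters`
#' columns are taken alternately from both spectral extremes (largest and
#' smallest generalized eigenvalues).
#'
#' @param trials_a,trials_b arrays (n x E x T) of band-passed trials.
#' @param n_filters even number of filters to keep (default 4).
#' @param shrinkage Ledoit-Wolf-style scalar shrinkage of each class
#'   covariance toward the scaled identity: `NULL` (automatic intensity),
#'   a number in \[0, 1\], or 0 to disable.
#' @param trace_norm normalize each trial covariance by its trace before
#'   averaging (default TRUE; robust to trial-amplitude outliers).
#' @return list with `W` (E x n_filters), `eigenvalues` (all E, sorted
#'   decreasing) and `selected` (indices of kept eigenvectors).
#' @export
csp_fit <- function(trials_a, trials_b, n_filters = 4, shrinkage = NULL,
                    trace_norm = TRUE) {
  stopifnot(dim(trials_a)[1] >= 2, dim(trials_b)[1] >= 2,
            n_filters %% 2 == 0, n_filters >= 2)
  C_a <- class_covariance(trials_a, shrinkage, trace_norm)
  C_b <- class_covariance(trials_b, shrinkage, trace_norm)
  C_sum <- C_a + C_b
  es <- eigen(C_sum, symmetric = TRUE)
  if (min(es$values) < 1e-10 * max(es$values)) {
    stop("composite covariance is (near) rank-deficient; enable shrinkage ",
         "(csp_fit(..., shrinkage = NULL) uses an automatic intensity)")
  }
  # whiten, then eigendecompose the whitened C_a
  P <- es$vectors %*% diag(1 / sqrt(es$values), nrow(C_sum)) %*% t(es$vectors)
  ew <- eigen(P %*% C_a %*% P, symmetric = TRUE)  # eigenvalues in [0,1], desc
  W_full <- P %*% ew$vectors
  half <- n_filters / 2
  sel <- c(seq_len(half), nrow(C_sum) - rev(seq_len(half)) + 1L)
  list(W = W_full[, sel, drop = FALSE], eigenvalues = ew$values,
       selected = sel)
}

class_covariance <- function(trials, shrinkage, trace_norm) {
  n <- dim(trials)[1]; E <- dim(trials)[2]
  C <- matrix(0, E, E)
  for (j in seq_len(n)) {
    X <- trials[j, , ]
    Cj <- tcrossprod(X) / ncol(X)
    if (trace_norm) Cj <- Cj / sum(diag(Cj))
    C <- C + Cj
  }
  C <- C / n
  if (is.null(shrinkage)) {
    lambda <- ledoit_wolf_intensity(trials, C, trace_norm)
  } else {
    lambda <- shrinkage
  }
  mu <- mean(diag(C))
  (1 - lambda) * C + lambda * mu * diag(E)
}

# scalar shrinkage intensity: dispersion of per-trial covariances around the
# mean, relative to the mean's distance from the scaled identity target
ledoit_wolf_intensity <- function(trials, C, trace_norm) {
  n <- dim(trials)[1]; E <- dim(trials)[2]
  mu <- mean(diag(C))
  denom <- sum((C - mu * diag(E))^2)
  if (denom < 1e-12) return(0)
  num <- 0
  for (j in seq_len(n)) {
    X <- trials[j, , ]
    Cj <- tcrossprod(X) / ncol(X)
    if (trace_norm) Cj <- Cj / sum(diag(Cj))
    num <- num + sum((Cj - C)^2)
  }
  num <- num / (n^2)
  max(0, min(1, num / denom))
}

#' Log-variance features of spatially filtered band-passed trials
#'
#' For each trial, band and spatial filter: `log(var(w' X_band) + eps)`.
#'
#' @param band_trials list (one per band) of arrays (n x E x T), already
#'   band-pass filtered.
#' @param W_per_band list of spatial filter matrices (E x n_filters), one per
#'   band.
#' @param eps variance guard (default 1e-12).
#' @return feature matrix n x (n_bands * n_filters).
#' @export
log_var_features <- function(band_trials, W_per_band, eps = 1e-12) {
  stopifnot(length(band_trials) == length(W_per_band))
  n <- dim(band_trials[[1]])[1]
  feats <- lapply(seq_along(band_trials), function(b) {
    W <- W_per_band[[b]]
    out <- matrix(0, n, ncol(W))
    for (j in seq_len(n)) {
      Y <- crossprod(W, band_trials[[b]][j, , ])
      out[j, ] <- log(apply(Y, 1, stats::var) + eps)
    }
    out
  })
  do.call(cbind, feats)
}

default_filter_bank <- function(fs, f_low = 4, f_high = NULL, width = 4) {
  if (is.null(f_high)) f_high <- min(38, floor(fs / 2) - 1)
  lows <- seq(f_low, f_high - width, by = width)
  lapply(lows, function(lo) band_spec(lo, lo + width))
}

#' Train an FBCSP decoder
#'
#' The filter-bank common spatial patterns pipeline: band-pass filter each
#' trial into the filter-bank bands (causal Butterworth, order 3), fit CSP
#' spatial filters per band, build log-variance features, and train a
#' classifier. Multiclass problems use one-vs-rest binary CSP sub-problems
#' whose classifier log-odds are combined by softmax (pairwise voting
#' available as an option).
#'
#' @param dataset an `eeg_dataset` (training trials).
#' @param bands list of [band_spec()]; default 4 Hz-wide bands from 4 Hz up
#'   to min(38, Nyquist - 1) Hz.
#' @param n_filters CSP filters per band (default 4).
#' @param classifier "rlda" (regularized linear discriminant, default) or
#'   "logistic".
#' @param shrinkage covariance shrinkage passed to [csp_fit()].
#' @param multiclass "ovr" (one-vs-rest, default) or "pairwise".
#' @param select_features if a positive integer m, keep only the m features
#'   with the highest (binned) mutual information with the labels in each
#'   binary sub-problem; 0 (default) keeps all.
#' @return an object of class `fbcsp_model`.
#' @export
fbcsp_train <- function(dataset, bands = NULL, n_filters = 4,
                        classifier = c("rlda", "logistic"),
                        shrinkage = NULL, multiclass = c("ovr", "pairwise"),
                        select_features = 0) {
  classifier <- match.arg(classifier)
  multiclass <- match.arg(multiclass)
  stopifnot(inherits(dataset, "eeg_dataset"))
  K <- length(dataset$class_names)
  if (length(unique(dataset$labels)) < 2) stop("need at least 2 classes")
  if (is.null(bands)) bands <- default_filter_bank(dataset$fs)
  band_trials <- filter_bank_apply(dataset$trials, bands, dataset$fs)

  problems <- if (multiclass == "ovr") {
    lapply(seq_len(K) - 1L, function(k) {
      list(pos = which(dataset$labels == k),
           neg = which(dataset$labels != k), tag = k)
    })
  } else {
    combs <- utils::combn(seq_len(K) - 1L, 2, simplify = FALSE)
    lapply(combs, function(kk) {
      list(pos = which(dataset$labels == kk[1]),
           neg = which(dataset$labels == kk[2]), tag = kk)
    })
  }

  sub_models <- lapply(problems, function(pr) {
    W_per_band <- lapply(band_trials, function(bt) {
      csp_fit(bt[pr$pos, , , drop = FALSE], bt[pr$neg, , , drop = FALSE],
              n_filters = n_filters, shrinkage = shrinkage)$W
    })
    idx <- c(pr$pos, pr$neg)
    feats <- log_var_features(
      lapply(band_trials, function(bt) bt[idx, , , drop = FALSE]), W_per_band)
    y <- rep(c(1L, 0L), c(length(pr$pos), length(pr$neg)))
    mask <- rep(TRUE, ncol(feats))
    if (select_features > 0 && select_features < ncol(feats)) {
      mi <- apply(feats, 2, binned_mutual_information, y = y)
      mask <- rank(-mi, ties.method = "first") <= select_features
    }
    clf <- fit_binary_classifier(feats[, mask, drop = FALSE], y, classifier)
    list(W_per_band = W_per_band, clf = clf, mask = mask, tag = pr$tag)
  })

  structure(list(bands = bands, n_filters = n_filters, fs = dataset$fs,
                 classifier = classifier, multiclass = multiclass,
                 sub_models = sub_models, K = K,
                 class_names = dataset$class_names),
            class = "fbcsp_model")
}

filter_bank_apply <- function(trials, bands, fs) {
  n <- dim(trials)[1]
  lapply(bands, function(b) {
    out <- trials
    for (j in seq_len(n)) {
      out[j, , ] <- causal_butterworth_filter(trials[j, , ], b, fs)
    }
    out
  })
}

binned_mutual_information <- function(f, y, n_bins = 4) {
  br <- stats::quantile(f, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  fb <- cut(f, unique(br))
  tab <- table(fb, y) + 0.5  # light smoothing against empty cells
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  sum(p * log(p / outer(px, py)))
}

fit_binary_classifier <- function(X, y, type, ridge = 1e-3) {
  if (type == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    list(type = "logistic", coef = fit$coefficients)
  } else {
    mu1 <- colMeans(X[y == 1, , drop = FALSE])
    mu0 <- colMeans(X[y == 0, , drop = FALSE])
    S <- (stats::cov(X[y == 1, , drop = FALSE]) * (sum(y == 1) - 1) +
          stats::cov(X[y == 0, , drop = FALSE]) * (sum(y == 0) - 1)) /
         (length(y) - 2)
    S <- S + ridge * mean(diag(S)) * diag(ncol(X))
    w <- solve(S, mu1 - mu0)
    b <- -sum(w * (mu1 + mu0)) / 2 + log(sum(y == 1) / sum(y == 0))
    list(type = "rlda", w = w, b = b)
  }
}

binary_log_odds <- function(clf, X) {
  if (clf$type == "logistic") {
    as.numeric(cbind(1, X) %*% clf$coef)
  } else {
    as.numeric(X %*% clf$w + clf$b)
  }
}

#' Predict with a trained FBCSP model
#'
#' @param model an `fbcsp_model`.
#' @param trials array (n x E x T) or an `eeg_dataset`.
#' @return list with `labels` (0-based predicted classes) and `probabilities`
#'   (n x K matrix).
#' @export
fbcsp_predict <- function(model, trials) {
  if (inherits(trials, "eeg_dataset")) trials <- trials$trials
  band_trials <- filter_bank_apply(trials, model$bands, model$fs)
  n <- dim(trials)[1]
  scores <- matrix(0, n, model$K)
  for (sm in model$sub_models) {
    feats <- log_var_features(band_trials, sm$W_per_band)
    lo <- binary_log_odds(sm$clf, feats[, sm$mask, drop = FALSE])
    if (model$multiclass == "ovr") {
      scores[, sm$tag + 1L] <- scores[, sm$tag + 1L] + lo
    } else {
      scores[, sm$tag[1] + 1L] <- scores[, sm$tag[1] + 1L] + lo
      scores[, sm$tag[2] + 1L] <- scores[, sm$tag[2] + 1L] - lo
    }
  }
  probs <- t(apply(scores, 1, function(z) {
    z <- z - max(z); exp(z) / sum(exp(z))
  }))
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}

#' Classification accuracy of predictions against true labels
#' @param predicted 0-based predicted labels (or a list with `$labels`).
#' @param truth 0-based true labels (or an `eeg_dataset`).
#' @return fraction correct.
#' @export
accuracy <- function(predicted, truth) {
  if (is.list(predicted)) predicted <- predicted$labels
  if (inherits(truth, "eeg_dataset")) truth <- truth$labels
  mean(predicted == truth)
}
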