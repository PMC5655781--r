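#' Frequency band specification
#'
#' @param low lower edge in Hz (>= 0).
#' @param high upper edge in Hz (> low).
#' @param name optional band name.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(low, high, name = paste0(low, "-", high, "Hz")) {
  stopifnot(low >= 0, high > low)
  structure(list(low = low, high = high, name = name), class = "band_spec")
}

#' Canonical analysis bands
#'
#' alpha 7-13 Hz, beta 13-31 Hz, gamma 71-91 Hz.
#' @return named list of [band_spec()]s.
#' @export
canonical_bands <- function() {
  list(alpha = band_spec(7, 13, "alpha"),
       beta = band_spec(13, 31, "beta"),
       gamma = band_spec(71, 91, "gamma"))
}

check_band <- function(band, fs) {
  if (is.numeric(band) && length(band) == 2) band <- band_spec(band[1], band[2])
  stopifnot(inherits(band, "band_spec"))
  if (band$high >= fs / 2) {
    stop("band edge ", band$high, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  band
}

butter_for <- function(band, fs, order) {
  if (band$low <= 0) {
    signal::butter(order, band$high / (fs / 2), type = "low")
  } else {
    signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  }
}

#' Causal Butterworth filtering
#'
#' Third-order (by default) causal Butterworth filter applied along time to
#' each electrode row: the output at sample t depends only on samples <= t.
#' Used for decoding preprocessing (e.g. the 4 Hz high-pass variant of the
#' data); zero-phase filtering for visualization is provided by
#' [zero_phase_bandpass()].
#'
#' @param x numeric vector or E x T matrix.
#' @param band a [band_spec()] / `c(low, high)` for band-pass, or a single
#'   number for a high-pass cutoff in Hz.
#' @param fs sampling rate (Hz).
#' @param order filter order (default 3).
#' @return filtered signal, same shape as `x`.
#' @export
causal_butterworth_filter <- function(x, band, fs, order = 3) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  stopifnot(all(is.finite(x)))
  if (is.numeric(band) && length(band) == 1) {
    if (band >= fs / 2) stop("cutoff ", band, " Hz >= Nyquist (", fs / 2, " Hz)")
    bf <- signal::butter(order, band / (fs / 2), type = "high")
  } else {
    band <- check_band(band, fs)
    bf <- butter_for(band, fs, order)
  }
  out <- t(apply(x, 1, function(row) {
    as.numeric(signal::filter(bf, row))
  }))
  if (vec) as.numeric(out) else out
}

#' Zero-phase band-pass filtering
#'
#' Forward-backward Butterworth band-pass (no phase delay) used by the
#' visualization pipeline so envelope features stay aligned in time with
#' unit outputs.
#'
#' @inheritParams causal_butterworth_filter
#' @return filtered signal, same shape as `x`.
#' @export
zero_phase_bandpass <- function(x, band, fs, order = 3) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  band <- check_band(band, fs)
  bf <- butter_for(band, fs, order)
  out <- t(apply(x, 1, function(row) as.numeric(signal::filtfilt(bf, row))))
  if (vec) as.numeric(out) else out
}

#' Cut a continuous recording into labeled trials
#'
#' Trials are half-open sample windows `[start, end)` of length
#' `round((t_end - t_start) * fs)` anchored at each event sample (0-based
#' sample index of the cue).
#'
#' @param continuous E x T_total matrix.
#' @param event_samples integer vector of 0-based cue sample indices.
#' @param t_start,t_end window in seconds relative to the cue (t_start may be
#'   negative).
#' @param fs sampling rate (Hz).
#' @return array (n_events x E x T_trial).
#' @export
epoch <- function(continuous, event_samples, t_start, t_end, fs) {
  stopifnot(t_end > t_start)
  T_total <- ncol(continuous)
  len <- round((t_end - t_start) * fs)
  start <- event_samples + round(t_start * fs)  # 0-based
  bad <- which(start < 0 | start + len > T_total)
  if (length(bad)) {
    stop("epoch window [", t_start, ", ", t_end, "] s out of recording bounds",
         " for event(s) at sample(s) ",
         paste(event_samples[bad], collapse = ", "))
  }
  out <- array(0, dim = c(length(event_samples), nrow(continuous), len))
  for (i in seq_along(start)) {
    out[i, , ] <- continuous[, (start[i] + 1):(start[i] + len)]
  }
  out
}

#' Per-electrode z-scoring from training statistics
#'
#' Computes per-electrode mean and standard deviation from the training
#' subset only (pooling all trials and samples) and applies the same affine
#' transform to the whole dataset, so held-out trials carry no statistics of
#' their own (no leakage). Standard deviations below `eps` are clamped to
#' `eps` with a warning (constant channels map to zero).
#'
#' @param dataset an `eeg_dataset`.
#' @param stats_from integer indices of the training trials (default: all).
#' @param eps variance guard (default 1e-8).
#' @return the standardized `eeg_dataset`; the applied `mean`/`sd` per
#'   electrode are stored in `$meta$standardize`.
#' @export
standardize <- function(dataset, stats_from = NULL, eps = 1e-8) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (is.null(stats_from)) stats_from <- seq_len(dim(dataset$trials)[1])
  if (!length(stats_from)) stop("training subset for statistics is empty")
  E <- dim(dataset$trials)[2]
  tr <- dataset$trials[stats_from, , , drop = FALSE]
  mu <- apply(tr, 2, mean)
  sd_e <- apply(tr, 2, stats::sd)
  if (any(sd_e < eps)) {
    warning("electrode(s) with (near-)zero variance: ",
            paste(dataset$electrodes$name[sd_e < eps], collapse = ", "))
    sd_e <- pmax(sd_e, eps)
  }
  out <- dataset$trials
  for (e in seq_len(E)) out[, e, ] <- (out[, e, ] - mu[e]) / sd_e[e]
  dataset$trials <- out
  dataset$meta$standardize <- list(mean = mu, sd = sd_e, eps = eps,
                                   stats_from = stats_from)
  dataset
}

# analytic signal via FFT (frequency-domain Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited envelope
#'
#' Zero-phase band-pass to `band` followed by the magnitude of the analytic
#' signal (Hilbert envelope). Nonnegative; for a pure sinusoid of amplitude
#' A inside the band, approximately A away from the edges.
#'
#' @param x numeric vector or E x T matrix.
#' @param band a [band_spec()] or `c(low, high)` in Hz.
#' @param fs sampling rate (Hz).
#' @return envelope, same shape as `x`.
#' @export
band_envelope <- function(x, band, fs) {
  bp <- zero_phase_bandpass(x, band, fs)
  if (is.null(dim(bp))) return(Mod(analytic_signal(bp)))
  t(apply(bp, 1, function(row) Mod(analytic_signal(row))))
}

#' Moving-window mean of the squared envelope
#'
#' `out[i] = mean(env[i..i+window-1]^2)` — the band-power feature seen by a
#' unit whose temporal receptive field spans `window` samples starting at
#' sample i.
#'
#' @param envelope numeric vector or E x T matrix (an envelope, see
#'   [band_envelope()]).
#' @param window window length in samples (<= T).
#' @return vector (or matrix) of length T - window + 1 per row.
#' @export
receptive_field_mean_sq_envelope <- function(envelope, window) {
  one <- function(v) {
    if (window > length(v)) {
      stop("window (", window, ") exceeds signal length (", length(v), ")")
    }
    cs <- cumsum(c(0, v^2))
    (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  }
  if (is.null(dim(envelope))) one(envelope) else t(apply(envelope, 1, one))
}
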