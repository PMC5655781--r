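#' Synthetic EEG generator configuration
#'
#' Describes a simulated motor-decoding experiment: band-limited oscillatory
#' sources whose amplitude is modulated per class (event-related
#' desynchronization / synchronization), mixed linearly onto electrodes, on
#' top of 1/f background noise.
#'
#' @param n_classes number of classes K (>= 2).
#' @param n_trials_per_class trials generated per class.
#' @param fs sampling rate in Hz; must exceed twice the highest source
#'   frequency.
#' @param trial_window numeric `c(t_start, t_end)` in seconds relative to the
#'   cue; the cue sits at t = 0 and amplitude modulation applies for t >= 0.
#' @param electrodes data.frame with columns `name`, `x`, `y` (2-D projected
#'   scalp positions in \[-1, 1\]^2).
#' @param sources list of sources, each a list with `name`, `freq` (center
#'   frequency, Hz), `bandwidth` (Hz; the source occupies
#'   freq +/- bandwidth/2) and `weights` (mixing weight per electrode;
#'   normalized to unit norm internally).
#' @param modulation matrix (n_classes x n_sources) of relative band-power
#'   changes during the trial: -0.4 means 40% power decrease, +0.4 a 40%
#'   increase. Entries must be > -1.
#' @param noise_exponent slope of the 1/f background noise spectrum
#'   (amplitude ~ f^(-noise_exponent/2)).
#' @param snr source-to-noise root-mean-square amplitude ratio.
#' @param seed integer seed making generation deterministic.
#' @param class_names optional character vector of length `n_classes`.
#'
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()], [default_synth_config()]
#' @export
synth_config <- function(n_classes, n_trials_per_class, fs, trial_window,
                         electrodes, sources, modulation,
                         noise_exponent = 1, snr = 3, seed = 1L,
                         class_names = NULL) {
  stopifnot(n_classes >= 2, n_trials_per_class >= 1, fs > 0,
            length(trial_window) == 2, trial_window[2] > trial_window[1])
  electrodes <- as.data.frame(electrodes)
  stopifnot(all(c("name", "x", "y") %in% names(electrodes)))
  E <- nrow(electrodes)
  max_f <- max(vapply(sources, function(s) s$freq + s$bandwidth / 2, 0))
  if (fs <= 2 * max_f) {
    stop("sampling rate ", fs, " Hz too low for source reaching ", max_f,
         " Hz (need fs > 2 * max source frequency)")
  }
  modulation <- as.matrix(modulation)
  if (nrow(modulation) != n_classes || ncol(modulation) != length(sources)) {
    stop("modulation must be a ", n_classes, " x ", length(sources), " matrix")
  }
  if (any(modulation <= -1)) {
    stop("modulation entries must be > -1 (cannot remove more than all power)")
  }
  sources <- lapply(sources, function(s) {
    stopifnot(length(s$weights) == E)
    s$weights <- s$weights / sqrt(sum(s$weights^2))
    s
  })
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes) - 1L)
  structure(list(
    n_classes = as.integer(n_classes),
    n_trials_per_class = as.integer(n_trials_per_class),
    fs = fs, trial_window = trial_window, electrodes = electrodes,
    sources = sources, modulation = modulation,
    noise_exponent = noise_exponent, snr = snr, seed = as.integer(seed),
    class_names = class_names
  ), class = "synth_config")
}

#' Default 4-class synthetic motor-decoding configuration
#'
#' Mimics a left hand / right hand / feet / rest paradigm on a small
#' sensorimotor montage: contralateral alpha (10 Hz) and beta (20 Hz) power
#' decrease plus gamma (81 Hz) power increase for the hand classes, midline
#' modulation for feet, no modulation at rest. Trials span -0.5 s to 4 s
#' around the cue at 250 Hz (1125 samples).
#'
#' @param n_trials_per_class trials per class (default 75).
#' @param snr source-to-noise amplitude ratio (default 3).
#' @param seed integer seed.
#' @param modulation_scale multiplies all modulation depths; 0 yields a
#'   dataset with no class information (chance-level decodable).
#' @return a `synth_config`.
#' @export
default_synth_config <- function(n_trials_per_class = 75, snr = 3, seed = 1L,
                                 modulation_scale = 1) {
  electrodes <- data.frame(
    name = c("C3", "C4", "Cz", "FC3", "FC4", "CP3", "CP4", "Pz"),
    x = c(-0.4, 0.4, 0, -0.4, 0.4, -0.4, 0.4, 0),
    y = c(0, 0, 0, 0.35, 0.35, -0.35, -0.35, -0.6)
  )
  w <- function(...) c(...)  # weights in electrode order above
  sources <- list(
    list(name = "alpha_left",  freq = 10, bandwidth = 6,
         weights = w(1, 0, .2, .5, 0, .5, 0, .1)),
    list(name = "alpha_right", freq = 10, bandwidth = 6,
         weights = w(0, 1, .2, 0, .5, 0, .5, .1)),
    list(name = "alpha_mid",   freq = 10, bandwidth = 6,
         weights = w(.2, .2, 1, .1, .1, .2, .2, .5)),
    list(name = "beta_left",   freq = 20, bandwidth = 10,
         weights = w(1, 0, .2, .5, 0, .5, 0, .1)),
    list(name = "beta_right",  freq = 20, bandwidth = 10,
         weights = w(0, 1, .2, 0, .5, 0, .5, .1)),
    list(name = "gamma_left",  freq = 81, bandwidth = 20,
         weights = w(1, 0, .1, .4, 0, .4, 0, 0)),
    list(name = "gamma_right", freq = 81, bandwidth = 20,
         weights = w(0, 1, .1, 0, .4, 0, .4, 0)),
    list(name = "gamma_mid",   freq = 81, bandwidth = 20,
         weights = w(.1, .1, 1, 0, 0, .2, .2, .4))
  )
  # rows: Hand (L), Hand (R), Feet, Rest; columns follow `sources`
  modulation <- modulation_scale * rbind(
    c(  0, -.5,   0,   0, -.4,   0,  .5,   0),  # left hand: right-hemisphere ERD, gamma ERS
    c(-.5,   0,   0, -.4,   0,  .5,   0,   0),  # right hand: left-hemisphere
    c(-.15, -.15, -.5, 0,    0,   0,   0,  .5), # feet: midline
    c(  0,   0,   0,   0,   0,   0,   0,   0)   # rest
  )
  synth_config(
    n_classes = 4, n_trials_per_class = n_trials_per_class, fs = 250,
    trial_window = c(-0.5, 4), electrodes = electrodes, sources = sources,
    modulation = modulation, noise_exponent = 1, snr = snr, seed = seed,
    class_names = c("hand_left", "hand_right", "feet", "rest")
  )
}

# band-limited noise source: white noise band-passed to freq +/- bandwidth/2,
# zero-phase so the envelope is not skewed, normalized to unit RMS
band_limited_noise <- function(n, freq, bandwidth, fs) {
  pad <- min(n, 4L * ceiling(fs / max(bandwidth, 1)))
  x <- stats::rnorm(n + 2L * pad)
  lo <- max(freq - bandwidth / 2, 0.1)
  hi <- min(freq + bandwidth / 2, fs / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

# 1/f background noise via FFT amplitude shaping, unit RMS
one_over_f_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))  # avoid division by zero at DC
  f <- pmin(f, n - f + 1)    # mirror for negative frequencies
  X <- X * f^(-exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a labeled synthetic EEG dataset
#'
#' Each trial is the sum over sources of a band-limited oscillation with a
#' class-scaled amplitude (applied from the cue at t = 0 onward) projected
#' through the source's mixing weights, plus independent 1/f noise per
#' electrode. Deterministic for a fixed `config$seed`. Class labels are
#' balanced and trials are shuffled.
#'
#' @param config a [synth_config()].
#' @return an `eeg_dataset` (see [eeg_dataset()]); the generating config is
#'   kept in `$meta$config` so ground-truth structure remains available.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  t_axis <- seq(config$trial_window[1], config$trial_window[2] - 1 / fs, by = 1 / fs)
  T_len <- length(t_axis)
  E <- nrow(config$electrodes)
  n_src <- length(config$sources)
  n <- config$n_classes * config$n_trials_per_class
  labels <- rep(seq_len(config$n_classes) - 1L, each = config$n_trials_per_class)
  post_cue <- t_axis >= 0

  trials <- withr::with_seed(config$seed, {
    arr <- array(0, dim = c(n, E, T_len))
    for (j in seq_len(n)) {
      k <- labels[j] + 1L
      x <- matrix(0, E, T_len)
      for (s in seq_len(n_src)) {
        src <- config$sources[[s]]
        osc <- band_limited_noise(T_len, src$freq, src$bandwidth, fs)
        amp <- rep(1, T_len)
        amp[post_cue] <- sqrt(1 + config$modulation[k, s])
        x <- x + outer(src$weights, osc * amp)
      }
      src_rms <- sqrt(mean(x^2))
      for (e in seq_len(E)) {
        x[e, ] <- x[e, ] + (src_rms / config$snr) *
          one_over_f_noise(T_len, config$noise_exponent)
      }
      arr[j, , ] <- x
    }
    perm <- sample.int(n)
    list(trials = arr[perm, , , drop = FALSE], labels = labels[perm])
  })

  eeg_dataset(
    trials = trials$trials, labels = trials$labels, fs = fs,
    electrodes = config$electrodes, class_names = config$class_names,
    meta = list(generator = "eegdecode::generate_dataset", seed = config$seed,
                trial_window = config$trial_window, config = config)
  )
}

#' Ground-truth per-electrode correlation sign map for a frequency band
#'
#' For every class and electrode, the expected sign of the correlation
#' between band power and the class indicator: the sign of the summed
#' modulation of all sources overlapping `band`, weighted by the squared
#' mixing weight at that electrode (power scales with the square of the
#' mixing weight). Entries where no source projects are zero; electrodes
#' where opposing modulations cancel are flagged ambiguous and set to 0.
#'
#' @param config a [synth_config()].
#' @param band a [band_spec()] or numeric `c(low, high)` in Hz.
#' @return matrix (n_classes x E) of signs in \{-1, 0, 1\} with attributes
#'   `no_source` (TRUE when the band overlaps no configured source) and
#'   `ambiguous` (logical matrix of cancelled entries).
#' @export
ground_truth_topography <- function(config, band) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(band, "band_spec")) band <- c(band$low, band$high)
  E <- nrow(config$electrodes)
  K <- config$n_classes
  overlap <- vapply(config$sources, function(s) {
    s$freq - s$bandwidth / 2 < band[2] && s$freq + s$bandwidth / 2 > band[1]
  }, logical(1))
  net <- matrix(0, K, E, dimnames = list(config$class_names,
                                         config$electrodes$name))
  gross <- net
  for (s in which(overlap)) {
    w2 <- config$sources[[s]]$weights^2
    contrib <- outer(config$modulation[, s], w2)
    net <- net + contrib
    gross <- gross + abs(contrib)
  }
  tol <- 1e-8
  ambiguous <- abs(net) < tol & gross > tol
  signs <- sign(net)
  signs[abs(net) < tol] <- 0
  if (!any(overlap)) {
    warning("band [", band[1], ", ", band[2], "] Hz overlaps no configured source")
  }
  structure(signs, no_source = !any(overlap), ambiguous = ambiguous)
}
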