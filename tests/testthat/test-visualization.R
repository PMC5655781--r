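# hand-built band-power "network": select one electrode, band-pass it with a
# fixed sinusoidal kernel, square, moving-mean — its outputs are a known
# band-power feature, giving an oracle for both visualization methods.
bandpower_model <- function(E, T_len, electrode, freq, fs, k = 51,
                            pool_w = 101) {
  layers <- list(
    eegdecode:::layer_conv_spatial(1),
    eegdecode:::layer_conv_time(k, 1),
    eegdecode:::layer_act("square"),
    eegdecode:::layer_pool(pool_w, 1, "mean"),
    eegdecode:::layer_conv_class(1, 1))
  spec <- structure(list(name = "bandpower", layers = layers,
                         input_shape = c(E, T_len), n_classes = 1L,
                         choices = list()), class = "arch_spec")
  net <- init_network(spec, 1)
  sel <- matrix(0, E, 1); sel[electrode, 1] <- 1
  net$params[[1]] <- list(W = sel, b = 0)
  tt <- (seq_len(k) - (k + 1) / 2) / fs
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(k) - 1) / (k - 1))
  net$params[[2]] <- list(W = matrix(sin(2 * pi * freq * tt) * win, k, 1),
                          b = 0)
  net$params[[5]] <- list(W = matrix(1, 1, 1), b = 0)
  net
}

white_noise_dataset <- function(n = 24, E = 4, T_len = 300, fs = 250,
                                seed = 50) {
  trials <- withr::with_seed(seed, array(rnorm(n * E * T_len),
                                         c(n, E, T_len)))
  eeg_dataset(trials, rep(0:1, length.out = n), fs,
              data.frame(name = paste0("e", 1:E),
                         x = seq(-0.5, 0.5, length.out = E), y = 0),
              c("a", "b"))
}

test_that("a band-power oracle model lights up its electrode and band", {
  fs <- 250; E <- 4; T_len <- 500
  withr::with_seed(60, {
    n <- 30
    trials <- array(rnorm(n * E * T_len) * 0.2, c(n, E, T_len))
    for (j in seq_len(n)) {
      amp <- runif(1, 0.5, 3)
      trials[j, 3, ] <- trials[j, 3, ] +
        amp * eegdecode:::band_limited_noise(T_len, 10, 6, fs)
    }
    ds <- eeg_dataset(trials, rep(0:1, length.out = n), fs,
                      data.frame(name = paste0("e", 1:E),
                                 x = seq(-0.5, 0.5, length.out = E), y = 0),
                      c("a", "b"))
  })
  net <- bandpower_model(E, T_len, electrode = 3, freq = 10, fs)
  bands <- list(band_spec(7, 13, "alpha"), band_spec(30, 40, "high"))
  cm <- unit_output_correlation_map(net, net, ds, layer_index = 4,
                                    bands = bands)
  expect_gt(cm$trained["e3", "alpha", 1], 0.95)
  expect_equal(which.max(cm$trained[, "alpha", 1]), c(e3 = 3L))
  # same model as its own reference: difference map identically zero
  expect_true(all(cm$difference == 0))
})

test_that("random nets on white noise stay inside the null band", {
  ds <- white_noise_dataset()
  spec <- tiny_spec(4, 300, 2)
  # receptive field of the final layer spans the trial: one unit position
  # per trial, so correlations use n independent samples
  m1 <- init_network(spec, 101)
  m2 <- init_network(spec, 202)
  cm <- unit_output_correlation_map(m1, m2, ds,
                                    layer_index = length(spec$layers),
                                    bands = list(band_spec(7, 13, "alpha"),
                                                 band_spec(20, 40, "beta+")))
  n <- dim(ds$trials)[1]
  r_crit <- stats::qnorm(0.975) / sqrt(n)
  frac_below <- mean(abs(cm$difference) < 2 * r_crit)
  expect_gte(frac_below, 0.85)
})

test_that("envelope-class correlations recover the generator topography", {
  ds <- default_dataset()
  r <- envelope_class_correlation(ds, list(band_spec(7, 13, "alpha")))
  topo <- ground_truth_topography(ds$meta$config, band_spec(7, 13))
  # strongly modulated entries: sign must match
  expect_lt(r["hand_right", "C3", 1], -0.1)
  expect_lt(r["hand_left", "C4", 1], -0.1)
  expect_equal(sign(r["hand_right", "C3", 1]), topo["hand_right", "C3"])
  # duplicating every trial leaves correlations unchanged
  n <- dim(ds$trials)[1]
  dup <- eeg_dataset(ds$trials[rep(seq_len(n), 2), , ], rep(ds$labels, 2),
                     ds$fs, ds$electrodes, ds$class_names)
  r2 <- envelope_class_correlation(dup, list(band_spec(7, 13, "alpha")))
  expect_equal(unclass(r2), unclass(r), tolerance = 1e-10)
  expect_error(envelope_class_correlation(
    subset_trials(ds, which(ds$labels == 0L)),
    list(band_spec(7, 13, "alpha"))), "two classes")
})

test_that("unit-class correlation profile is zero for identical models and
           high for a separating softmax", {
  ds <- white_noise_dataset()
  spec <- tiny_spec(4, 300, 2)
  net <- init_network(spec, 77)
  prof <- unit_class_correlation_profile(net, net, ds)
  expect_true(all(prof$mean_abs_difference == 0))
  expect_true(all(prof$mean_max_difference == 0))
  # plant a perfectly separating signal (strong 20 Hz power on electrode 1
  # for class 1) and read it out with the band-power oracle model
  ds2 <- ds
  osc <- withr::with_seed(5, {
    t(vapply(seq_len(sum(ds2$labels == 1L)), function(i) {
      5 * eegdecode:::band_limited_noise(300, 20, 6, ds2$fs)
    }, numeric(300)))
  })
  ds2$trials[ds2$labels == 1L, 1, ] <- ds2$trials[ds2$labels == 1L, 1, ] + osc
  oracle <- bandpower_model(4, 300, electrode = 1, freq = 20, fs = 250)
  prof2 <- unit_class_correlation_profile(oracle, oracle, ds2,
                                          layer_indices = 4)
  # the band-power readout of the planted electrode separates the classes
  expect_gt(prof2$mean_max_trained, 0.9)
})

test_that("perturbation map localizes the causal electrode and frequency", {
  fs <- 250; E <- 3; T_len <- 250
  ds <- white_noise_dataset(n = 16, E = E, T_len = T_len, seed = 71)
  net <- bandpower_model(E, T_len, electrode = 2, freq = 20, fs)
  pr <- perturbation_correlation_map(net, ds$trials, labels = NULL,
                                     n_perturbations = 120, seed = 4,
                                     fs = fs)
  r <- pr$correlations[, , 1]
  freqs <- pr$freqs
  in_band <- freqs >= 15 & freqs <= 25
  far <- freqs >= 60
  # positive correlations at the read-out electrode in its band (each bin
  # shares the output variance with the ~10 other bins of the band, so
  # per-bin r is of order 1/sqrt(10))
  expect_gt(mean(r[2, in_band]), 0.15)
  expect_gt(mean(r[2, in_band]), 5 * abs(mean(r[2, far])))
  expect_gt(mean(r[2, in_band]), 5 * abs(mean(r[c(1, 3), in_band])))
})

test_that("degenerate outputs give zero correlations and tiny noise keeps
           full accuracy", {
  ds <- white_noise_dataset(n = 10)
  spec <- tiny_spec(4, 300, 2)
  net <- init_network(spec, 5)
  # constant-output model: zero final layer
  net0 <- net
  net0$params[[5]]$W[] <- 0
  net0$params[[5]]$b[] <- c(1, 0)
  pr0 <- perturbation_correlation_map(net0, ds$trials, labels = ds$labels,
                                      n_perturbations = 10, seed = 2,
                                      fs = ds$fs)
  expect_true(all(pr0$correlations == 0))
  # noise_sd -> 0: predictions unchanged, robustness ratio -> 100%
  pr1 <- perturbation_correlation_map(net, ds$trials, labels = ds$labels,
                                      n_perturbations = 5, noise_sd = 1e-9,
                                      seed = 3, fs = ds$fs)
  expect_equal(pr1$robustness_ratio, 100)
  expect_error(perturbation_correlation_map(net, ds$trials,
                                            n_perturbations = 2),
               "at least 3")
})

test_that("band aggregation and the frequency profile follow their
           definitions", {
  E <- 2; n_bins <- 50; K <- 3
  freqs <- seq(0, 98, length.out = n_bins)
  arr <- array(0.3, c(E, n_bins, K))
  agg <- band_aggregate_and_frequency_profile(
    arr, bands = list(band_spec(7, 13, "alpha"), band_spec(20, 30, "beta")),
    freqs = freqs)
  for (bm in agg$band_maps) expect_true(all(abs(bm - 0.3) < 1e-12))
  expect_true(all(abs(agg$profile$mean_abs_r - 0.3) < 1e-12))
  # disjoint bands draw on disjoint bins
  sel_a <- which(freqs >= 7 & freqs <= 13)
  sel_b <- which(freqs >= 20 & freqs <= 30)
  expect_length(intersect(sel_a, sel_b), 0)
  expect_error(band_aggregate_and_frequency_profile(
    arr, bands = list(band_spec(99, 100, "empty")), freqs = freqs),
    "no frequency bin")
})

test_that("scalp maps render without error", {
  el <- default_dataset()$electrodes
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, 300, 300)
  expect_silent(plot_scalp_map(stats::setNames(rnorm(nrow(el)), el$name),
                               el, main = "alpha"))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})
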