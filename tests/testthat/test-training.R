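test_that("losses match their closed forms", {
  expect_equal(nll_loss(rep(0.25, 4), 0L), log(4))
  onehot <- c(1, 0, 0, 0)
  expect_equal(nll_loss(onehot, 0L), 0)
  expect_equal(nll_loss(c(0.1, 0.9), 0L), -log(0.1))
  # batch loss is the sum of per-example losses
  P <- cbind(rep(0.25, 4), c(0.1, 0.3, 0.3, 0.3))
  expect_equal(nll_loss(P, c(0L, 0L)), log(4) - log(0.1))
})

test_that("tied loss adds the neighbour cross-entropy", {
  onehot <- c(1, 0, 0, 0)
  u <- rep(0.25, 4)
  expect_equal(tied_sample_loss(onehot, onehot, 0L), 0)
  expect_equal(tied_sample_loss(u, u, 0L), 2 * log(4))
  # one-hot pred_t with a spread-out neighbour hits the epsilon clamp but
  # stays finite
  v <- tied_sample_loss(onehot, u, 0L)
  expect_true(is.finite(v))
  expect_gt(v, 1)
  # tied loss >= plain loss, equality iff the neighbour matches a one-hot
  # pred_t support
  set.seed(2)
  for (i in 1:20) {
    p1 <- softmax(rnorm(4)); p2 <- softmax(rnorm(4))
    expect_gte(tied_sample_loss(p1, p2, 1L), nll_loss(p1, 1L))
  }
})

test_that("crop enumeration yields T - T' crops of the right content", {
  trial <- matrix(seq_len(2 * 1125), 2)
  crops <- extract_crops(trial, 500)
  expect_length(crops, 625)
  expect_equal(attr(crops, "starts")[1], 0)
  expect_equal(crops[[1]], trial[, 1:500])
  expect_equal(crops[[625]], trial[, 625:1124])
  # edge: T' = T - 1 gives a single crop
  expect_length(extract_crops(trial, 1124), 1)
  expect_error(extract_crops(trial, 1125), "smaller")
  # cropped training multiplies the number of training examples by T - T'
  expect_equal(length(crops) / 1, 625)
})

test_that("fig-4 style toy network: dense pass equals the hand oracle", {
  layers <- list(eegdecode:::layer_conv_time(2, 1),
                 eegdecode:::layer_conv_time(2, 1),
                 eegdecode:::layer_subsample(2),
                 eegdecode:::layer_conv_class(2, 1))
  spec <- structure(list(name = "toy", layers = layers,
                         input_shape = c(1L, 5L), n_classes = 1L,
                         choices = list()), class = "arch_spec")
  net <- init_network(spec, 1)
  net$params[[1]] <- list(W = matrix(1, 2, 1), b = 0)
  net$params[[2]] <- list(W = matrix(1, 2, 1), b = 0)
  net$params[[4]] <- list(W = matrix(1, 2, 1), b = 0)
  r <- dense_multi_crop_forward(net, matrix(1:7, 1))
  expect_equal(as.numeric(r$scores), c(24, 32, 40))
  expect_equal(r$starts, 0:2)
})

test_that("dense pass equals the naive per-crop loop on random nets", {
  set.seed(99)
  n_done <- 0
  while (n_done < 30) {
    E <- sample(2:4, 1); T_crop <- sample(25:60, 1); K <- sample(2:3, 1)
    spec <- random_valid_spec(E, T_crop, K)
    if (is.null(spec)) next
    net <- init_network(spec, n_done + 1)
    T_in <- T_crop + sample(5:50, 1)
    x <- matrix(rnorm(E * T_in), E)
    dense <- dense_multi_crop_forward(net, x)
    n_crops <- T_in - T_crop + 1
    expect_length(dense$starts, n_crops)
    naive <- vapply(seq_len(n_crops), function(t) {
      network_forward(net, x[, t:(t + T_crop - 1), drop = FALSE])$scores[, 1, 1]
    }, numeric(K))
    expect_lt(max(abs(dense$scores - naive)), 1e-5)
    n_done <- n_done + 1
  }
})

test_that("dense pass with input equal to crop length is a plain forward
           pass", {
  spec <- tiny_spec(3, 40, 2)
  net <- init_network(spec, 5)
  x <- matrix(rnorm(3 * 40), 3)
  plain <- network_forward(net, x)
  dense <- dense_multi_crop_forward(net, x)
  expect_equal(dim(dense$scores), c(2, 1))
  expect_equal(as.numeric(dense$scores), as.numeric(plain$scores))
})

test_that("padded convolutions are refused by the dense pass", {
  rs <- build_resnet(3, 60, 2, n_blocks = 2, widths = c(4, 4))
  net <- init_network(rs, 1)
  expect_error(dense_multi_crop_forward(net, matrix(rnorm(3 * 80), 3)),
               "valid")
})

test_that("crop predictions aggregate by the mean with low-index ties", {
  p <- matrix(c(1, 0, 0, 1), 2)
  agg <- aggregate_crop_predictions(p)
  expect_equal(agg$probabilities, c(0.5, 0.5))
  expect_equal(agg$label, 0L)
  same <- matrix(c(0.2, 0.8), 2, 10)
  expect_equal(aggregate_crop_predictions(same)$probabilities, c(0.2, 0.8))
  p_rand <- apply(matrix(runif(8), 2), 2, function(v) v / sum(v))
  expect_equal(sum(aggregate_crop_predictions(p_rand)$probabilities), 1,
               tolerance = 1e-12)
  expect_error(aggregate_crop_predictions(matrix(0, 2, 0)), "at least one")
})

test_that("training is deterministic given a seed and can overfit a small
           set", {
  el <- data.frame(name = c("A", "B", "C"), x = c(-0.5, 0.5, 0), y = 0)
  src <- list(list(name = "mu", freq = 11, bandwidth = 5,
                   weights = c(1, 0.2, 0.1)),
              list(name = "mu2", freq = 11, bandwidth = 5,
                   weights = c(0.1, 1, 0.2)))
  cfg <- synth_config(2, 20, 250, c(0, 2), el, src,
                      rbind(c(-0.6, 0.4), c(0.4, -0.6)), snr = 5, seed = 31,
                      class_names = c("l", "r"))
  ds <- standardize(generate_dataset(cfg))
  # dropout off: this checks that the optimizer can drive the net to zero
  # training error on an easy separable set
  spec <- build_shallow(3, 500, 2, choices = list(dropout = FALSE),
                        n_filters = c(8, 8))
  tc <- train_config(max_epochs = 30, patience = 30, seed = 4)
  m1 <- fit(init_network(spec, 1), ds, "trial", tc)
  # overfit sanity: the trained model classifies its training set perfectly
  expect_equal(accuracy(predict_network(m1, ds), ds), 1.0)
  m2 <- fit(init_network(spec, 1), ds, "trial", tc)
  expect_identical(m1$log, m2$log)
})

test_that("cropped training runs the dense path and predicts sensibly", {
  el <- data.frame(name = c("A", "B"), x = c(-0.5, 0.5), y = 0)
  src <- list(list(name = "mu", freq = 11, bandwidth = 5,
                   weights = c(1, 0.2)),
              list(name = "mu2", freq = 11, bandwidth = 5,
                   weights = c(0.2, 1)))
  cfg <- synth_config(2, 16, 250, c(0, 1.6), el, src,
                      rbind(c(-0.6, 0.4), c(0.4, -0.6)), snr = 5, seed = 17,
                      class_names = c("l", "r"))
  ds <- standardize(generate_dataset(cfg))  # 400-sample trials
  spec <- build_shallow(2, 150, 2, n_filters = c(6, 6))
  tc <- train_config(max_epochs = 20, patience = 20, seed = 3, batch_size = 8)
  m <- fit(init_network(spec, 2), ds, "cropped", tc,
           crops = crop_config(tied_loss = TRUE))
  pr <- predict_network(m, ds, "cropped")
  expect_gte(accuracy(pr, ds), 0.8)
  expect_equal(rowSums(pr$probabilities), rep(1, 32), tolerance = 1e-9)
})

test_that("a non-finite loss aborts training with a diagnostic", {
  ds <- generate_dataset(default_synth_config(n_trials_per_class = 3,
                                              seed = 2))
  ds <- standardize(ds)
  ds$trials[, 1, 5] <- NaN
  spec <- build_shallow(8, 1125, 4, n_filters = c(4, 4))
  expect_error(
    fit(init_network(spec, 1), ds, "trial",
        train_config(max_epochs = 2, seed = 1)),
    "diverged")
})
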