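test_that("final classification kernel lengths match the printed trial-wise
           arithmetic", {
  expect_equal(final_kernel_length(build_deep(22, 1125, 4)), 9)
  expect_equal(final_kernel_length(build_shallow(22, 1125, 4)), 69)
})

test_that("a toy one-block chain reproduces hand-computed sizing", {
  layers <- list(eegdecode:::layer_conv_time(10, 4),
                 eegdecode:::layer_pool(3, 3, "max"))
  # floor((31 - 9 - 3) / 3) + 1
  expect_equal(temporal_out_len(layers, 31), 7)
  expect_error(temporal_out_len(layers, 9), "does not fit")
})

test_that("shallow pool stride is uniquely forced by the printed output
           length", {
  # floor((1101 - 75) / s) + 1 == 69 has the unique integer solution s = 15
  sols <- Filter(function(s) (1101 - 75) %/% s + 1 == 69, 1:75)
  expect_equal(sols, 15)
})

test_that("hybrid concatenates 100 feature maps and outputs K classes", {
  hy <- build_hybrid(8, 1125, 4)
  expect_equal(hy$n_feature_maps, 100)
  net <- init_network(hy, 1)
  x <- array(rnorm(2 * 8 * 1125), c(2, 8, 1125))
  fw <- network_forward(net, x)
  expect_equal(dim(fw$scores), c(4, 1, 2))
  expect_equal(apply(fw$probabilities, c(2, 3), sum),
               matrix(1, 1, 2), tolerance = 1e-6)
})

test_that("gradients flow into both hybrid branches", {
  hy <- build_hybrid(4, 450, 2, choices = list(dropout = FALSE),
                     deep_features = 6, shallow_features = 4)
  net <- init_network(hy, 3)
  x <- array(rnorm(2 * 4 * 450), c(2, 4, 450))
  fw <- eegdecode:::forward_chain(hy$layers, net$params,
                                  eegdecode:::trials_to_stream(x),
                                  training = TRUE, dense = FALSE)
  pred <- eegdecode:::collect_predictions(fw$streams)
  lg <- eegdecode:::score_loss_grad(pred$scores, c(0L, 1L))
  ds <- eegdecode:::scatter_dscores(fw$streams, pred, lg$dscores)
  bw <- eegdecode:::backward_chain(hy$layers, fw$params, fw$caches, ds)
  gb <- bw$dparams[[1]]$branches
  expect_gt(max(abs(gb[[1]][[1]]$W)), 0)  # deep branch first conv
  expect_gt(max(abs(gb[[2]][[1]]$W)), 0)  # shallow branch first conv
})

test_that("resnet has 14 residual blocks, identity shortcuts, K outputs", {
  rs <- build_resnet(6, 400, 4)
  kinds <- vapply(rs$layers, `[[`, "", "kind")
  expect_equal(sum(kinds == "resblock"), 14)
  expect_equal(rs$n_residual_blocks, 14)
  net <- init_network(rs, 2)
  x <- array(rnorm(6 * 400), c(1, 6, 400))
  fw <- network_forward(net, x)
  expect_equal(dim(fw$scores)[1], 4)
  # zeroing a block's convolutions makes it the identity (plus ELU of the
  # already-ELU-positive input path): check directly on the primitive
  bi <- which(kinds == "resblock")[1]
  p <- net$params[[bi]]
  p$conv1$W[] <- 0; p$conv1$b[] <- 0
  p$conv2$W[] <- 0; p$conv2$b[] <- 0
  p$bn2$gamma[] <- 0  # second batchnorm output identically zero
  layer <- rs$layers[[bi]]
  xin <- abs(array(rnorm(prod(c(layer$n_filters, 1, 20, 2))),
                   c(layer$n_filters, 1, 20, 2)))  # positive: ELU(x) = x
  r <- eegdecode:::resblock_forward(list(list(x = xin, start = 0L,
                                              step = 1L)),
                                    layer, p, training = FALSE)
  expect_equal(r$streams[[1]]$x, xin, tolerance = 1e-12)
})

test_that("receptive fields follow the standard recursion", {
  d <- build_deep(8, 1125, 4)
  expect_equal(unname(receptive_field(d, 1)["temporal"]), 10)
  # conv k10 s1 then pool k3 s3: 10 + (3-1)*1 = 12
  pool1 <- which(vapply(d$layers, `[[`, "", "kind") == "pool")[1]
  expect_equal(unname(receptive_field(d, pool1)["temporal"]), 12)
  expect_equal(unname(receptive_field(d, pool1)["spatial"]), 8)
  # monotone non-decreasing with depth
  rfs <- vapply(seq_along(d$layers), function(i) {
    unname(receptive_field(d, i)["temporal"])
  }, 0)
  expect_true(all(diff(rfs) >= 0))
  # the final prediction covers (almost) the whole trial; strided pooling
  # discards a few trailing samples that fit no complete window
  expect_lte(rfs[length(rfs)], 1125)
  expect_gt(rfs[length(rfs)], 1000)
})

test_that("design-choice toggles are pure", {
  base <- build_deep(8, 1125, 4)
  relu <- build_deep(8, 1125, 4, choices = list(activation = "relu"))
  shape_of <- function(s) temporal_out_len(s$layers, s$input_shape[2])
  expect_equal(shape_of(base), shape_of(relu))
  expect_equal(param_count(base), param_count(relu))
  # removing batchnorm removes exactly the normalization parameters
  nobn <- build_deep(8, 1125, 4, choices = list(batchnorm = FALSE))
  n_bn_layers <- sum(vapply(base$layers, `[[`, "", "kind") == "batchnorm")
  bn_params <- vapply(which(vapply(base$layers, `[[`, "", "kind") ==
                              "batchnorm"),
                      function(i) 2L * base$layers[[i - 1L]]$n_filters, 0L)
  expect_equal(param_count(base) - param_count(nobn), sum(bn_params))
  expect_gt(n_bn_layers, 0)
})

test_that("one-step first convolution changes parameter count as computed", {
  split <- build_deep(8, 1125, 4, choices = list(batchnorm = FALSE,
                                                 dropout = FALSE))
  fused <- build_deep(8, 1125, 4, choices = list(split_first_layer = FALSE,
                                                 batchnorm = FALSE,
                                                 dropout = FALSE))
  # split: 10*25 + 25 + (8*25)*25 + 25 ; fused: (8*10)*25 + 25
  diff_expected <- (10 * 25 + 25 + 8 * 25 * 25 + 25) - (8 * 10 * 25 + 25)
  expect_equal(param_count(split) - param_count(fused), diff_expected)
})

test_that("softmax outputs are normalized for random inputs on every
           architecture", {
  set.seed(31)
  x <- array(rnorm(2 * 6 * 600), c(2, 6, 600))
  for (spec in list(build_deep(6, 600, 3, n_filters = c(4, 4, 5, 6, 7)),
                    build_shallow(6, 600, 3, n_filters = c(5, 5)),
                    build_resnet(6, 600, 3, n_blocks = 4, widths = c(4, 6)))) {
    fw <- network_forward(init_network(spec, 4), x)
    sums <- apply(fw$probabilities, c(2, 3), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
})

test_that("nonlinearities follow their closed forms", {
  x <- array(c(-2, -0.5, 0, 0.5, 2, 1, -1, 3), c(2, 1, 2, 2))
  elu <- eegdecode:::act_forward(x, "elu")$y
  expect_equal(elu[x > 0], x[x > 0])
  expect_equal(elu[x <= 0], exp(x[x <= 0]) - 1)
  expect_equal(eegdecode:::act_forward(x, "square")$y, x^2)
  relu <- eegdecode:::act_forward(x, "relu")$y
  expect_equal(relu, pmax(x, 0) * 1)
})

test_that("too-short inputs raise a sizing error naming the layer", {
  expect_error(build_deep(8, 200, 4), "layer")
  expect_error(build_shallow(8, 60, 4), "does not fit")
})
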