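# Shared fixtures. Expensive objects (datasets, trained networks) are built
# once per test run and cached in this environment so several test files can
# reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the default 4-class study dataset (75 trials/class, -0.5..4 s @ 250 Hz)
default_dataset <- function() {
  fixture("default_dataset", function() {
    generate_dataset(default_synth_config(seed = 5))
  })
}

# standardized copy plus a fixed stratified train/test split (15/class out)
default_split <- function() {
  fixture("default_split", function() {
    ds <- default_dataset()
    n <- dim(ds$trials)[1]
    test_idx <- withr::with_seed(11, {
      unlist(lapply(0:3, function(k) {
        sample(which(ds$labels == k), 15)
      }))
    })
    train_idx <- setdiff(seq_len(n), test_idx)
    std <- standardize(ds, stats_from = train_idx)
    list(dataset = std, train = subset_trials(std, train_idx),
         test = subset_trials(std, test_idx),
         train_idx = train_idx, test_idx = test_idx)
  })
}

# the desk-scale deep ConvNet: half the figure-drawn filter counts, 2-s
# crop input, dropout off (see the methods vignette); trained with the
# cropped strategy, which is what makes the deep net generalize here
desk_deep_spec <- function(E, K = 4) {
  build_deep(E, 500, K, choices = list(dropout = FALSE),
             n_filters = c(12, 12, 25, 50, 100))
}

# deep ConvNet trained on the default dataset (shared by the perturbation,
# visualization and end-to-end tests)
trained_deep <- function() {
  fixture("trained_deep", function() {
    sp <- default_split()
    dims <- dataset_dims(sp$train)
    spec <- desk_deep_spec(dims[["E"]])
    net <- init_network(spec, seed = 1)
    fit(net, sp$train, "cropped",
        train_config(lr = 5e-3, batch_size = 32, max_epochs = 10,
                     patience = 10, seed = 2))
  })
}

# the 400-repetition amplitude-perturbation analysis of the trained deep
# net on a seeded subset of its training trials (shared by the robustness
# and topography-recovery tests)
perturbation_analysis <- function() {
  fixture("perturbation_analysis", function() {
    sp <- default_split()
    net <- trained_deep()
    idx <- withr::with_seed(21, sample(dim(sp$train$trials)[1], 32))
    perturbation_correlation_map(net, subset_trials(sp$train, idx),
                                 n_perturbations = 400, seed = 7,
                                 chunk = 32)
  })
}

# a small fast architecture for engine-level tests
tiny_spec <- function(E = 3, T_len = 40, K = 2, seed = 1) {
  layers <- list(
    eegdecode:::layer_conv_time(5, 4),
    eegdecode:::layer_conv_spatial(4),
    eegdecode:::layer_act("elu"),
    eegdecode:::layer_pool(3, 3, "max"),
    eegdecode:::layer_conv_class(
      (((T_len - 5 + 1) - 3) %/% 3 + 1) - 0, K))
  # classification kernel spans the remaining length
  len <- eegdecode:::temporal_out_len(layers[1:4], T_len)
  layers[[5]] <- eegdecode:::layer_conv_class(len, K)
  structure(list(name = "tiny", layers = layers,
                 input_shape = c(E, T_len), n_classes = K,
                 choices = list()),
            class = "arch_spec")
}

# independent brute-force oracle for the signed-rank test: enumerate all
# sign assignments of the nonzero differences directly on W+, applying the
# same averaged-tie / split-zero / ceiling conventions
oracle_wilcoxon <- function(d) {
  r <- rank(abs(d))
  zero_half <- sum(r[d == 0]) / 2
  nz <- which(d != 0)
  w_pos <- sum(r[d > 0]) + zero_half
  w_neg <- sum(r[d < 0]) + zero_half
  stat <- ceiling(min(w_pos, w_neg))
  if (!length(nz)) return(list(statistic = stat, p = 1))
  m <- length(nz)
  signs <- expand.grid(rep(list(c(0, 1)), m))
  w_all <- as.matrix(signs) %*% r[nz] + zero_half
  S <- sum(r)
  p <- min(1, 2 * min(mean(w_all <= stat), mean(w_all >= S - stat)))
  list(statistic = stat, p = p)
}

# random valid-convolution architecture generator for equivalence tests
random_valid_spec <- function(E, T_crop, K) {
  n_blocks <- sample(1:2, 1)
  layers <- list(eegdecode:::layer_conv_time(sample(2:6, 1), sample(2:4, 1)),
                 eegdecode:::layer_conv_spatial(sample(2:4, 1)))
  for (b in seq_len(n_blocks)) {
    layers <- c(layers, list(
      eegdecode:::layer_act(sample(c("elu", "relu", "square"), 1)),
      eegdecode:::layer_pool(sample(2:3, 1), sample(1:3, 1),
                             sample(c("max", "mean"), 1))))
  }
  len <- tryCatch(eegdecode:::temporal_out_len(layers, T_crop),
                  error = function(e) NULL)
  if (is.null(len)) return(NULL)
  layers <- c(layers, list(eegdecode:::layer_conv_class(len, K)))
  structure(list(name = "random", layers = layers,
                 input_shape = c(E, T_crop), n_classes = K,
                 choices = list()),
            class = "arch_spec")
}
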