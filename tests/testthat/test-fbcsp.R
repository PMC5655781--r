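# trials with an exact per-trial covariance: scaled rows of an orthogonal
# design so that X X' / T equals the target diagonal matrix
trials_with_cov <- function(n, diag_cov, T_len = 64) {
  E <- length(diag_cov)
  base <- sqrt(2) * rbind(cos(2 * pi * (1:T_len) * 3 / T_len),
                          sin(2 * pi * (1:T_len) * 3 / T_len))
  arr <- array(0, c(n, E, T_len))
  for (j in seq_len(n)) {
    arr[j, , ] <- diag(sqrt(diag_cov), E) %*% base[rep_len(1:2, E), ] *
      rep(1, T_len)
  }
  arr
}

test_that("csp recovers the closed-form 2x2 diagonal eigenstructure", {
  a <- trials_with_cov(4, c(10, 1))
  b <- trials_with_cov(4, c(1, 10))
  # rows of the base are identical per channel; decorrelate channels
  a[, 2, ] <- a[, 2, ] * rep(c(1, -1), length.out = 64)
  b[, 2, ] <- b[, 2, ] * rep(c(1, -1), length.out = 64)
  m <- csp_fit(a, b, n_filters = 2, shrinkage = 0, trace_norm = FALSE)
  expect_equal(sort(m$eigenvalues), sort(c(10 / 11, 1 / 11)), tolerance = 1e-6)
  # filters align with the coordinate axes up to sign/scale
  W <- abs(m$W / max(abs(m$W)))
  expect_lt(min(apply(W, 2, min)) , 1e-6)
})

test_that("identical class covariances give eigenvalues 1/2 and scaling
           leaves filters invariant", {
  set.seed(3)
  arr <- array(rnorm(6 * 3 * 100), c(6, 3, 100))
  m <- csp_fit(arr, arr, n_filters = 2, shrinkage = 0)
  expect_equal(m$eigenvalues, rep(0.5, 3), tolerance = 1e-8)
  a <- array(rnorm(6 * 3 * 100), c(6, 3, 100))
  b <- array(rnorm(6 * 3 * 100), c(6, 3, 100))
  m1 <- csp_fit(a, b, n_filters = 2, shrinkage = 0, trace_norm = FALSE)
  m2 <- csp_fit(a * 3, b * 3, n_filters = 2, shrinkage = 0,
                trace_norm = FALSE)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
  # filters equal up to scale and sign
  ratio <- m1$W / m2$W
  expect_lt(max(abs(ratio - matrix(ratio[1, ], 3, 2, byrow = TRUE))), 1e-6)
})

test_that("the first filter's training variance ratio equals its eigenvalue", {
  set.seed(8)
  a <- array(rnorm(10 * 4 * 200), c(10, 4, 200)) * 2
  b <- array(rnorm(10 * 4 * 200), c(10, 4, 200))
  m <- csp_fit(a, b, n_filters = 4, shrinkage = 0, trace_norm = FALSE)
  w1 <- m$W[, 1]
  var_of <- function(arr) {
    mean(vapply(seq_len(dim(arr)[1]), function(j) {
      y <- crossprod(w1, arr[j, , ])
      mean(y^2)
    }, 0))
  }
  va <- var_of(a); vb <- var_of(b)
  expect_equal(va / (va + vb), m$eigenvalues[1], tolerance = 1e-6)
})

test_that("log-variance features follow the sinusoid closed form", {
  T_len <- 1000
  A <- 3
  x <- A * sin(2 * pi * 25 * (1:T_len) / 250)
  tr <- array(0, c(1, 2, T_len))
  tr[1, 1, ] <- x
  W <- matrix(c(1, 0), 2, 1)
  f <- log_var_features(list(tr), list(W))
  expect_equal(dim(f), c(1, 1))
  expect_equal(f[1, 1], log(A^2 / 2), tolerance = 0.01)
  # zero signal hits the epsilon guard without error
  f0 <- log_var_features(list(array(0, c(1, 2, 100))), list(W))
  expect_true(is.finite(f0[1, 1]))
  # shape contract: n_bands x n_filters columns
  f2 <- log_var_features(list(tr, tr), list(W, cbind(W, W)))
  expect_equal(ncol(f2), 3)
})

test_that("fbcsp separates an easy two-class band-power dataset", {
  el <- data.frame(name = c("A", "B", "C"), x = c(-0.5, 0.5, 0),
                   y = c(0, 0, 0.5))
  src <- list(list(name = "mu", freq = 11, bandwidth = 5,
                   weights = c(1, 0.2, 0.1)),
              list(name = "mu2", freq = 11, bandwidth = 5,
                   weights = c(0.1, 1, 0.2)))
  cfg <- synth_config(2, 50, 250, c(0, 2), el, src,
                      rbind(c(-0.6, 0.4), c(0.4, -0.6)), snr = 5, seed = 13,
                      class_names = c("left", "right"))
  ds <- generate_dataset(cfg)
  test_idx <- withr::with_seed(1, sample(100, 25))
  train <- subset_trials(ds, setdiff(1:100, test_idx))
  test <- subset_trials(ds, test_idx)
  model <- fbcsp_train(train)
  pr <- fbcsp_predict(model, test)
  expect_gte(accuracy(pr, test), 0.95)
  expect_equal(rowSums(pr$probabilities), rep(1, 25), tolerance = 1e-9)
})

test_that("label-shuffled training stays within the binomial chance band", {
  ds <- default_dataset()
  n <- dim(ds$trials)[1]
  shuf <- ds
  shuf$labels <- withr::with_seed(77, sample(ds$labels))
  test_idx <- withr::with_seed(78, sample(n, 40))
  model <- fbcsp_train(subset_trials(shuf, setdiff(seq_len(n), test_idx)))
  pr <- fbcsp_predict(model, subset_trials(shuf, test_idx))
  acc <- accuracy(pr, subset_trials(shuf, test_idx))
  # 95% binomial band around chance 0.25 at n = 40
  expect_lt(abs(acc - 0.25), 1.96 * sqrt(0.25 * 0.75 / 40) + 1e-9)
})

test_that("single-class input is rejected", {
  ds <- default_dataset()
  one <- subset_trials(ds, which(ds$labels == 0L))
  expect_error(fbcsp_train(one), "2 classes")
})
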