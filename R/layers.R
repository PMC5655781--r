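# Low-level network primitives.
#
# Activations are 4-D arrays (channels C, electrodes E, time T, batch B).
# The electrode axis collapses to 1 after the spatial convolution. All
# convolutions are over time, valid (unpadded) unless a layer says otherwise.
# Every forward returns list(y, cache); every backward consumes its cache and
# returns input and parameter gradients. Broadcasting over the leading
# channel axis (y + b, gamma * x, ...) relies on R's first-dimension
# recycling, which matches the (C, ...) layout.

act_dims <- function(x) {
  d <- dim(x)
  list(C = d[1], E = d[2], T = d[3], B = d[4])
}

# --- temporal convolution (kernel k over time, all input channels) ---------

conv_time_forward <- function(x, W, b, k) {
  d <- act_dims(x)
  T_out <- d$T - k + 1L
  if (T_out < 1L) {
    stop("temporal convolution kernel ", k, " does not fit input of length ",
         d$T, " samples")
  }
  X2 <- array(0, c(d$C, k, d$E, T_out, d$B))
  for (dt in seq_len(k)) {
    X2[, dt, , , ] <- x[, , dt:(T_out + dt - 1L), , drop = FALSE]
  }
  dim(X2) <- c(d$C * k, d$E * T_out * d$B)
  y <- crossprod(W, X2) + b
  dim(y) <- c(ncol(W), d$E, T_out, d$B)
  list(y = y, cache = list(Xm = X2, k = k, d = d, T_out = T_out))
}

conv_time_backward <- function(dY, W, cache) {
  d <- cache$d; k <- cache$k; T_out <- cache$T_out
  C_out <- dim(W)[2]
  dYm <- dY
  dim(dYm) <- c(C_out, d$E * T_out * d$B)
  dW <- tcrossprod(cache$Xm, dYm)
  db <- rowSums(dYm)
  dX2 <- W %*% dYm
  dim(dX2) <- c(d$C, k, d$E, T_out, d$B)
  dX <- array(0, c(d$C, d$E, d$T, d$B))
  for (dt in seq_len(k)) {
    idx <- dt:(T_out + dt - 1L)
    slice <- dX2[, dt, , , , drop = FALSE]
    dim(slice) <- c(d$C, d$E, T_out, d$B)
    dX[, , idx, ] <- dX[, , idx, , drop = FALSE] + slice
  }
  list(dX = dX, dW = dW, db = db)
}

# zero-pad along time ("same" convolutions inside residual blocks)
pad_time <- function(x, lpad, rpad) {
  d <- act_dims(x)
  out <- array(0, c(d$C, d$E, d$T + lpad + rpad, d$B))
  out[, , (lpad + 1L):(lpad + d$T), ] <- x
  out
}

crop_time_grad <- function(dX, lpad, T_orig) {
  dX[, , (lpad + 1L):(lpad + T_orig), , drop = FALSE]
}

# --- spatial convolution (collapses the electrode axis) --------------------

conv_spatial_forward <- function(x, W, b) {
  d <- act_dims(x)
  Xm <- x
  dim(Xm) <- c(d$C * d$E, d$T * d$B)
  y <- crossprod(W, Xm) + b
  dim(y) <- c(ncol(W), 1L, d$T, d$B)
  list(y = y, cache = list(Xm = Xm, d = d))
}

conv_spatial_backward <- function(dY, W, cache) {
  d <- cache$d
  C_out <- dim(W)[2]
  dYm <- dY
  dim(dYm) <- c(C_out, d$T * d$B)
  dW <- tcrossprod(cache$Xm, dYm)
  db <- rowSums(dYm)
  dX <- W %*% dYm
  dim(dX) <- c(d$C, d$E, d$T, d$B)
  list(dX = dX, dW = dW, db = db)
}

# --- pooling over time -----------------------------------------------------
# `offset` selects the stride phase (0-based); the dense multi-crop pass runs
# one phase per stride offset, standard forward passes use offset 0 only.

pool_forward <- function(x, k, stride, mode, offset = 0L) {
  d <- act_dims(x)
  avail <- d$T - k - offset
  if (avail < 0L) return(NULL)  # this phase yields no complete window
  T_out <- avail %/% stride + 1L
  starts <- offset + seq.int(0L, by = stride, length.out = T_out)  # 0-based
  if (mode == "mean") {
    y <- array(0, c(d$C, d$E, T_out, d$B))
    for (dt in seq_len(k)) {
      y <- y + x[, , starts + dt, , drop = FALSE]
    }
    y <- y / k
    cache <- list(k = k, stride = stride, mode = mode, starts = starts, d = d)
  } else {
    y <- x[, , starts + 1L, , drop = FALSE]
    arg <- array(1L, dim(y))
    for (dt in seq_len(k)[-1]) {
      cur <- x[, , starts + dt, , drop = FALSE]
      m <- cur > y
      y[m] <- cur[m]
      arg[m] <- dt
    }
    cache <- list(k = k, stride = stride, mode = mode, starts = starts,
                  d = d, arg = arg)
  }
  list(y = y, cache = cache)
}

pool_backward <- function(dY, cache) {
  d <- cache$d
  dX <- array(0, c(d$C, d$E, d$T, d$B))
  if (cache$mode == "mean") {
    g <- dY / cache$k
    for (dt in seq_len(cache$k)) {
      idx <- cache$starts + dt
      dX[, , idx, ] <- dX[, , idx, , drop = FALSE] + g
    }
  } else {
    for (dt in seq_len(cache$k)) {
      m <- cache$arg == dt
      if (!any(m)) next
      idx <- cache$starts + dt
      tmp <- dX[, , idx, , drop = FALSE]
      tmp[m] <- tmp[m] + dY[m]
      dX[, , idx, ] <- tmp
    }
  }
  dX
}

# --- nonlinearities --------------------------------------------------------

LOG_EPS <- 1e-6

act_forward <- function(x, kind) {
  switch(kind,
    elu = {
      y <- x
      neg <- x <= 0
      y[neg] <- exp(x[neg]) - 1
      list(y = y, cache = list(kind = kind, neg = neg, y = y))
    },
    relu = {
      neg <- x < 0
      y <- x
      y[neg] <- 0
      list(y = y, cache = list(kind = kind, neg = neg))
    },
    square = list(y = x * x, cache = list(kind = kind, x = x)),
    log = {
      xc <- pmax(x, LOG_EPS)
      list(y = log(xc), cache = list(kind = kind, xc = xc, low = x < LOG_EPS))
    },
    sqrt = {
      xc <- pmax(x, LOG_EPS)
      y <- sqrt(xc)
      list(y = y, cache = list(kind = kind, y = y, low = x < LOG_EPS))
    },
    identity = list(y = x, cache = list(kind = kind)),
    stop("unknown activation: ", kind)
  )
}

act_backward <- function(dY, cache) {
  switch(cache$kind,
    elu = {
      dX <- dY
      dX[cache$neg] <- dY[cache$neg] * (cache$y[cache$neg] + 1)
      dX
    },
    relu = {
      dX <- dY
      dX[cache$neg] <- 0
      dX
    },
    square = 2 * cache$x * dY,
    log = {
      dX <- dY / cache$xc
      dX[cache$low] <- 0
      dX
    },
    sqrt = {
      dX <- dY / (2 * cache$y)
      dX[cache$low] <- 0
      dX
    },
    identity = dY
  )
}

# --- batch normalization (per channel, jointly over streams) ---------------
# xs: list of activation arrays sharing the channel count. Statistics pool
# all electrodes, time points, batch elements and streams, as training on
# all crops of a batch would.

BN_EPS <- 1e-5

bn_forward <- function(xs, gamma, beta, running_mean, running_var,
                       training, momentum = 0.1) {
  C <- dim(xs[[1]])[1]
  if (training) {
    n_tot <- 0
    s1 <- numeric(C); s2 <- numeric(C)
    for (x in xs) {
      Xm <- x; dim(Xm) <- c(C, length(x) / C)
      s1 <- s1 + rowSums(Xm)
      s2 <- s2 + rowSums(Xm * Xm)
      n_tot <- n_tot + ncol(Xm)
    }
    m <- s1 / n_tot
    v <- s2 / n_tot - m^2
    running_mean <- (1 - momentum) * running_mean + momentum * m
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    m <- running_mean
    v <- running_var
    n_tot <- NA
  }
  inv_std <- 1 / sqrt(v + BN_EPS)
  xhats <- lapply(xs, function(x) (x - m) * inv_std)
  ys <- lapply(xhats, function(xh) gamma * xh + beta)
  list(ys = ys,
       cache = list(xhats = xhats, inv_std = inv_std, n_tot = n_tot,
                    training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dYs, gamma, cache) {
  C <- length(gamma)
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (i in seq_along(dYs)) {
    dYm <- dYs[[i]]; dim(dYm) <- c(C, length(dYm) / C)
    xhm <- cache$xhats[[i]]; dim(xhm) <- c(C, length(xhm) / C)
    dgamma <- dgamma + rowSums(dYm * xhm)
    dbeta <- dbeta + rowSums(dYm)
  }
  if (!cache$training) {
    # inference statistics are constants
    dXs <- lapply(dYs, function(dY) gamma * cache$inv_std * dY)
    return(list(dXs = dXs, dgamma = dgamma, dbeta = dbeta))
  }
  n <- cache$n_tot
  dXs <- lapply(seq_along(dYs), function(i) {
    gamma * cache$inv_std *
      (dYs[[i]] - dbeta / n - cache$xhats[[i]] * (dgamma / n))
  })
  list(dXs = dXs, dgamma = dgamma, dbeta = dbeta)
}

# --- dropout (inverted scaling) --------------------------------------------

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(y = x, cache = list(mask = NULL)))
  }
  mask <- array(stats::runif(length(x)) >= p, dim(x)) / (1 - p)
  list(y = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# --- softmax / losses ------------------------------------------------------

PROB_EPS <- 1e-10

#' Softmax over class scores
#' @param z numeric vector or matrix (K x n) of pre-softmax scores.
#' @return probabilities, same shape; each prediction sums to 1.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) {
    z <- z - max(z)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Negative log likelihood loss
#'
#' `-log p(label)` for one prediction; for several predictions the losses
#' are summed. Probabilities are clamped at a small epsilon so a zero
#' probability yields a large finite loss.
#'
#' @param probabilities probability vector (length K) or K x n matrix.
#' @param labels 0-based class label(s).
#' @return summed loss (scalar).
#' @export
nll_loss <- function(probabilities, labels) {
  if (is.null(dim(probabilities))) {
    probabilities <- matrix(probabilities, ncol = 1)
  }
  idx <- cbind(labels + 1L, seq_len(ncol(probabilities)))
  sum(-log(pmax(probabilities[idx], PROB_EPS)))
}

#' Tied neighbour-crop loss
#'
#' The cropped-training regularized loss for one crop: the negative log
#' likelihood of the label under `pred_t` plus the cross-entropy between the
#' prediction for the next crop and `pred_t`,
#' `NLL(pred_t, label) + sum_k -log(pred_t[k]) * pred_next[k]`,
#' penalizing prediction discrepancy between neighbouring crops.
#'
#' @param pred_t probability vector for crop t.
#' @param pred_next probability vector for crop t + 1.
#' @param label 0-based class label.
#' @return scalar loss.
#' @export
tied_sample_loss <- function(pred_t, pred_next, label) {
  stopifnot(length(pred_t) == length(pred_next))
  nll_loss(pred_t, label) + sum(-log(pmax(pred_t, PROB_EPS)) * pred_next)
}
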