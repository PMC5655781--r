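# Network engine: parameter initialization, forward/backward over
# stride-offset streams, and the dense multi-crop forward pass.
#
# A "stream" is list(x = activations (C,E,T,B), start, step): element t
# (0-based) of the stream corresponds to a window whose first input sample
# is `start + t * step`. A standard forward pass is a single stream
# (start 0, step 1) that keeps only stride phase 0 at every strided layer;
# the dense multi-crop pass (`dense = TRUE`) splits every strided layer into
# one stream per stride offset so that one prediction per input sample
# survives, and interleaves only after the final layer.

glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

init_layer_params <- function(layer, C_in, E_in) {
  kind <- layer$kind
  if (kind %in% c("conv_time", "conv_class")) {
    W <- glorot(C_in * layer$k, layer$n_filters,
                c(C_in * layer$k, layer$n_filters))
    list(W = W, b = numeric(layer$n_filters))
  } else if (kind == "conv_spatial") {
    W <- glorot(C_in * E_in, layer$n_filters,
                c(C_in * E_in, layer$n_filters))
    list(W = W, b = numeric(layer$n_filters))
  } else if (kind == "conv_combined") {
    W <- glorot(E_in * layer$k, layer$n_filters,
                c(E_in * layer$k, layer$n_filters))
    list(W = W, b = numeric(layer$n_filters))
  } else if (kind == "batchnorm") {
    list(gamma = rep(1, C_in), beta = numeric(C_in),
         running_mean = numeric(C_in), running_var = rep(1, C_in))
  } else if (kind == "resblock") {
    C_out <- layer$n_filters
    list(
      conv1 = list(W = glorot(C_in * layer$k, C_out,
                              c(C_in * layer$k, C_out)),
                   b = numeric(C_out)),
      bn1 = list(gamma = rep(1, C_out), beta = numeric(C_out),
                 running_mean = numeric(C_out), running_var = rep(1, C_out)),
      conv2 = list(W = glorot(C_out * layer$k, C_out,
                              c(C_out * layer$k, C_out)),
                   b = numeric(C_out)),
      bn2 = list(gamma = rep(1, C_out), beta = numeric(C_out),
                 running_mean = numeric(C_out), running_var = rep(1, C_out))
    )
  } else if (kind == "branch") {
    list(branches = lapply(layer$branches, function(chain) {
      init_chain_params(chain, C_in, E_in)$params
    }))
  } else {
    NULL  # act, pool, dropout carry no parameters
  }
}

# track (C, E) through the chain while initializing
chain_shape_step <- function(layer, C_in, E_in) {
  switch(layer$kind,
    conv_time = , conv_class = c(layer$n_filters, E_in),
    conv_spatial = c(layer$n_filters, 1L),
    conv_combined = c(layer$n_filters, 1L),
    resblock = c(layer$n_filters, E_in),
    branch = c(sum(vapply(layer$branches, function(chain) {
      shp <- c(C_in, E_in)
      for (l in chain) shp <- chain_shape_step(l, shp[1], shp[2])
      shp[1]
    }, 0L)), E_in),
    c(C_in, E_in)
  )
}

init_chain_params <- function(chain, C_in, E_in) {
  params <- vector("list", length(chain))
  for (i in seq_along(chain)) {
    params[i] <- list(init_layer_params(chain[[i]], C_in, E_in))
    shp <- chain_shape_step(chain[[i]], C_in, E_in)
    C_in <- shp[1]; E_in <- shp[2]
  }
  list(params = params, C_out = C_in, E_out = E_in)
}

#' Instantiate a network from an architecture specification
#'
#' Allocates all weights (uniform Glorot initialization, seeded) and batch
#' normalization statistics for the layer chain of `spec`.
#'
#' @param spec an `arch_spec` (see [build_deep()] and friends).
#' @param seed integer seed for the weight initialization.
#' @return an object of class `eeg_network`.
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  params <- withr::with_seed(seed,
    init_chain_params(spec$layers, 1L,
                      unname(as.integer(spec$input_shape[1])))$params)
  structure(list(spec = spec, params = params, init_seed = seed),
            class = "eeg_network")
}

#' @export
print.eeg_network <- function(x, ...) {
  cat("<eeg_network> ", x$spec$name, ": ", length(x$spec$layers),
      " top-level layers, ", param_count(x), " parameters, input ",
      x$spec$input_shape[1], " electrodes x ", x$spec$input_shape[2],
      " samples, ", x$spec$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a network or architecture spec
#' @param x an `eeg_network` or `arch_spec`.
#' @return integer count (batchnorm running statistics excluded).
#' @export
param_count <- function(x) {
  if (inherits(x, "arch_spec")) x <- init_network(x, seed = 1L)
  count <- function(p) {
    if (is.list(p)) {
      p <- p[setdiff(names(p), c("running_mean", "running_var"))]
      return(sum(vapply(p, count, 0)))
    }
    length(p)
  }
  sum(vapply(x$params, function(p) if (is.null(p)) 0 else count(p), 0))
}

# ---------------------------------------------------------------------------
# forward

conv_stream <- function(stream, layer, p) {
  x <- stream$x
  if (layer$kind == "conv_combined") {
    # (1, E, T, B) and (E, 1, T, B) share a memory layout
    d <- dim(x)
    dim(x) <- c(d[2], 1L, d[3], d[4])
    r <- conv_time_forward(x, p$W, p$b, layer$k)
    r$cache$combined <- TRUE
    stream$x <- r$y
  } else if (layer$kind == "conv_spatial") {
    r <- conv_spatial_forward(x, p$W, p$b)
    stream$x <- r$y
  } else {
    padded <- identical(layer$padding, "same")
    if (padded) {
      lpad <- (layer$k - 1L) %/% 2L
      x <- pad_time(x, lpad, layer$k - 1L - lpad)
    }
    r <- conv_time_forward(x, p$W, p$b, layer$k)
    if (padded) r$cache$lpad <- lpad
    stream$x <- r$y
  }
  list(stream = stream, cache = r$cache)
}

conv_stream_backward <- function(dY, layer, p, cache) {
  if (layer$kind == "conv_spatial") {
    r <- conv_spatial_backward(dY, p$W, cache)
    return(r)
  }
  r <- conv_time_backward(dY, p$W, cache)
  if (isTRUE(cache$combined)) {
    d <- dim(r$dX)
    dim(r$dX) <- c(1L, d[1], d[3], d[4])
  } else if (!is.null(cache$lpad)) {
    r$dX <- crop_time_grad(r$dX, cache$lpad, cache$d$T - layer$k + 1L)
  }
  r
}

resblock_forward <- function(streams, layer, p, training) {
  caches <- vector("list", length(streams))
  h1 <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    x <- pad_time(streams[[i]]$x, (layer$k - 1L) %/% 2L,
                  layer$k - 1L - (layer$k - 1L) %/% 2L)
    r <- conv_time_forward(x, p$conv1$W, p$conv1$b, layer$k)
    caches[[i]] <- list(conv1 = r$cache)
    h1[[i]] <- r$y
  }
  bn1 <- bn_forward(h1, p$bn1$gamma, p$bn1$beta, p$bn1$running_mean,
                    p$bn1$running_var, training)
  h2 <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    a <- act_forward(bn1$ys[[i]], "elu")
    caches[[i]]$act1 <- a$cache
    x <- pad_time(a$y, (layer$k - 1L) %/% 2L,
                  layer$k - 1L - (layer$k - 1L) %/% 2L)
    r <- conv_time_forward(x, p$conv2$W, p$conv2$b, layer$k)
    caches[[i]]$conv2 <- r$cache
    h2[[i]] <- r$y
  }
  bn2 <- bn_forward(h2, p$bn2$gamma, p$bn2$beta, p$bn2$running_mean,
                    p$bn2$running_var, training)
  for (i in seq_along(streams)) {
    xin <- streams[[i]]$x
    C_in <- dim(xin)[1]; C_out <- layer$n_filters
    y <- bn2$ys[[i]]
    if (C_out > C_in) {
      # identity shortcut option A: extra channels padded with zeros
      y[seq_len(C_in), , , ] <- y[seq_len(C_in), , , , drop = FALSE] + xin
    } else {
      y <- y + xin
    }
    a <- act_forward(y, "elu")
    caches[[i]]$act_out <- a$cache
    caches[[i]]$C_in <- C_in
    streams[[i]]$x <- a$y
  }
  list(streams = streams, caches = caches, bn1 = bn1, bn2 = bn2)
}

resblock_backward <- function(dYs, layer, p, rb_cache) {
  n <- length(dYs)
  dh2 <- vector("list", n)
  dshort <- vector("list", n)
  for (i in seq_len(n)) {
    g <- act_backward(dYs[[i]], rb_cache$caches[[i]]$act_out)
    C_in <- rb_cache$caches[[i]]$C_in
    dshort[[i]] <- if (layer$n_filters > C_in) {
      g[seq_len(C_in), , , , drop = FALSE]
    } else g
    dh2[[i]] <- g
  }
  b2 <- bn_backward(dh2, p$bn2$gamma, rb_cache$bn2$cache)
  dgrad <- list(conv1 = list(W = 0, b = 0), bn1 = list(gamma = 0, beta = 0),
                conv2 = list(W = 0, b = 0),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  da1 <- vector("list", n)
  for (i in seq_len(n)) {
    r <- conv_time_backward(b2$dXs[[i]], p$conv2$W,
                            rb_cache$caches[[i]]$conv2)
    dgrad$conv2$W <- dgrad$conv2$W + r$dW
    dgrad$conv2$b <- dgrad$conv2$b + r$db
    lpad <- (layer$k - 1L) %/% 2L
    da1[[i]] <- act_backward(
      crop_time_grad(r$dX, lpad, rb_cache$caches[[i]]$conv1$T_out),
      rb_cache$caches[[i]]$act1)
  }
  b1 <- bn_backward(da1, p$bn1$gamma, rb_cache$bn1$cache)
  dgrad$bn1$gamma <- b1$dgamma; dgrad$bn1$beta <- b1$dbeta
  dXs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- conv_time_backward(b1$dXs[[i]], p$conv1$W,
                            rb_cache$caches[[i]]$conv1)
    dgrad$conv1$W <- dgrad$conv1$W + r$dW
    dgrad$conv1$b <- dgrad$conv1$b + r$db
    lpad <- (layer$k - 1L) %/% 2L
    T_in <- rb_cache$caches[[i]]$conv1$d$T - (layer$k - 1L)
    dX <- crop_time_grad(r$dX, lpad, T_in)
    C_in <- rb_cache$caches[[i]]$C_in
    dXs[[i]] <- dX + dshort[[i]]
  }
  list(dXs = dXs, dparam = dgrad)
}

forward_chain <- function(chain, params, streams, training, dense) {
  caches <- vector("list", length(chain))
  for (li in seq_along(chain)) {
    layer <- chain[[li]]
    p <- params[[li]]
    kind <- layer$kind
    if (kind %in% c("conv_time", "conv_class", "conv_spatial",
                    "conv_combined")) {
      if (dense && identical(layer$padding, "same")) {
        stop("the dense multi-crop forward pass requires valid (unpadded) ",
             "convolutions; layer ", li, " uses 'same' padding, which would ",
             "change the per-crop predictions")
      }
      cc <- vector("list", length(streams))
      keep <- rep(TRUE, length(streams))
      in_dims <- lapply(streams, function(s) dim(s$x))
      for (i in seq_along(streams)) {
        too_short <- !is.null(layer[["k"]]) &&
          !identical(layer$padding, "same") &&
          dim(streams[[i]]$x)[3] < layer[["k"]]
        if (too_short && dense) {
          # this stride phase cannot host a complete crop; drop it
          keep[i] <- FALSE
          next
        }
        r <- conv_stream(streams[[i]], layer, p)
        streams[[i]] <- r$stream
        cc[[i]] <- r$cache
      }
      if (!any(keep)) {
        stop("layer ", li, " (", kind, ", kernel ", layer$k,
             ") does not fit any stream; input too short")
      }
      caches[[li]] <- list(per_stream = cc[keep], keep = keep,
                           in_dims = in_dims)
      streams <- streams[keep]
    } else if (kind == "act") {
      cc <- vector("list", length(streams))
      for (i in seq_along(streams)) {
        r <- act_forward(streams[[i]]$x, layer$activation)
        streams[[i]]$x <- r$y
        cc[[i]] <- r$cache
      }
      caches[[li]] <- cc
    } else if (kind == "dropout") {
      cc <- vector("list", length(streams))
      for (i in seq_along(streams)) {
        r <- dropout_forward(streams[[i]]$x, layer$p, training)
        streams[[i]]$x <- r$y
        cc[[i]] <- r$cache
      }
      caches[[li]] <- cc
    } else if (kind == "batchnorm") {
      xs <- lapply(streams, `[[`, "x")
      r <- bn_forward(xs, p$gamma, p$beta, p$running_mean, p$running_var,
                      training)
      for (i in seq_along(streams)) streams[[i]]$x <- r$ys[[i]]
      params[[li]]$running_mean <- r$running_mean
      params[[li]]$running_var <- r$running_var
      caches[[li]] <- r$cache
    } else if (kind == "pool") {
      offsets <- if (dense && layer$stride > 1L) {
        seq_len(layer$stride) - 1L
      } else 0L
      new_streams <- list()
      cc <- list()
      split_map <- list()  # per new stream: (parent index, pool cache)
      for (i in seq_along(streams)) {
        for (off in offsets) {
          r <- pool_forward(streams[[i]]$x, layer$k, layer$stride,
                            layer$pool_mode, off)
          if (is.null(r)) next
          ns <- list(x = r$y,
                     start = streams[[i]]$start + off * streams[[i]]$step,
                     step = streams[[i]]$step * layer$stride)
          new_streams[[length(new_streams) + 1L]] <- ns
          split_map[[length(split_map) + 1L]] <-
            list(parent = i, cache = r$cache)
        }
      }
      if (!length(new_streams)) {
        stop("pooling layer ", li, " (window ", layer$k,
             ") does not fit its input; input too short for this ",
             "architecture")
      }
      caches[[li]] <- list(split_map = split_map,
                           n_parents = length(streams),
                           parent_dims = lapply(streams,
                                                function(s) dim(s$x)))
      streams <- new_streams
    } else if (kind == "resblock") {
      if (dense) {
        stop("the dense multi-crop forward pass requires valid (unpadded) ",
             "convolutions; residual blocks use 'same' padding, which would ",
             "change the per-crop predictions")
      }
      r <- resblock_forward(streams, layer, p, training)
      streams <- r$streams
      caches[[li]] <- r
      params[[li]]$bn1$running_mean <- r$bn1$running_mean
      params[[li]]$bn1$running_var <- r$bn1$running_var
      params[[li]]$bn2$running_mean <- r$bn2$running_mean
      params[[li]]$bn2$running_var <- r$bn2$running_var
    } else if (kind == "branch") {
      outs <- vector("list", length(layer$branches))
      bcaches <- vector("list", length(layer$branches))
      for (bi in seq_along(layer$branches)) {
        r <- forward_chain(layer$branches[[bi]], p$branches[[bi]], streams,
                           training, dense)
        outs[[bi]] <- r$streams
        bcaches[[bi]] <- r$caches
        params[[li]]$branches[[bi]] <- r$params
      }
      n_out <- length(outs[[1]])
      merged <- vector("list", n_out)
      widths <- vector("list", n_out)
      for (i in seq_len(n_out)) {
        xs <- lapply(outs, function(o) o[[i]]$x)
        widths[[i]] <- vapply(xs, function(x) dim(x)[1], 0L)
        d <- dim(xs[[1]])
        big <- array(0, c(sum(widths[[i]]), d[2], d[3], d[4]))
        at <- 0L
        for (x in xs) {
          big[(at + 1L):(at + dim(x)[1]), , , ] <- x
          at <- at + dim(x)[1]
        }
        merged[[i]] <- outs[[1]][[i]]
        merged[[i]]$x <- big
      }
      caches[[li]] <- list(bcaches = bcaches, widths = widths)
      streams <- merged
    } else {
      stop("unknown layer kind: ", kind)
    }
  }
  list(streams = streams, caches = caches, params = params)
}

backward_chain <- function(chain, params, caches, dstreams) {
  dparams <- vector("list", length(chain))
  for (li in rev(seq_along(chain))) {
    layer <- chain[[li]]
    p <- params[[li]]
    kind <- layer$kind
    if (kind %in% c("conv_time", "conv_class", "conv_spatial",
                    "conv_combined")) {
      dW <- 0; db <- 0
      cc <- caches[[li]]
      for (i in seq_along(dstreams)) {
        r <- conv_stream_backward(dstreams[[i]], layer, p,
                                  cc$per_stream[[i]])
        dstreams[[i]] <- r$dX
        dW <- dW + r$dW; db <- db + r$db
      }
      if (!all(cc$keep)) {
        # reinsert zero gradients for streams dropped on the way down
        full <- vector("list", length(cc$keep))
        full[cc$keep] <- dstreams
        for (i in which(!cc$keep)) full[[i]] <- array(0, cc$in_dims[[i]])
        dstreams <- full
      }
      dparams[[li]] <- list(W = dW, b = db)
    } else if (kind == "act") {
      for (i in seq_along(dstreams)) {
        dstreams[[i]] <- act_backward(dstreams[[i]], caches[[li]][[i]])
      }
    } else if (kind == "dropout") {
      for (i in seq_along(dstreams)) {
        dstreams[[i]] <- dropout_backward(dstreams[[i]], caches[[li]][[i]])
      }
    } else if (kind == "batchnorm") {
      r <- bn_backward(dstreams, p$gamma, caches[[li]])
      dstreams <- r$dXs
      dparams[[li]] <- list(gamma = r$dgamma, beta = r$dbeta,
                            running_mean = NULL, running_var = NULL)
    } else if (kind == "pool") {
      sm <- caches[[li]]$split_map
      parent_grads <- vector("list", caches[[li]]$n_parents)
      for (i in seq_along(dstreams)) {
        g <- pool_backward(dstreams[[i]], sm[[i]]$cache)
        pi <- sm[[i]]$parent
        parent_grads[[pi]] <- if (is.null(parent_grads[[pi]])) g else
          parent_grads[[pi]] + g
      }
      for (i in seq_along(parent_grads)) {
        if (is.null(parent_grads[[i]])) {
          parent_grads[[i]] <- array(0, caches[[li]]$parent_dims[[i]])
        }
      }
      dstreams <- parent_grads
    } else if (kind == "resblock") {
      r <- resblock_backward(dstreams, layer, p, caches[[li]])
      dstreams <- r$dXs
      dparams[[li]] <- r$dparam
    } else if (kind == "branch") {
      widths <- caches[[li]]$widths
      dinput <- NULL
      dbranch_params <- vector("list", length(layer$branches))
      for (bi in seq_along(layer$branches)) {
        dsub <- vector("list", length(dstreams))
        for (i in seq_along(dstreams)) {
          w <- widths[[i]]
          from <- sum(w[seq_len(bi - 1L)]) + 1L
          dsub[[i]] <- dstreams[[i]][from:(from + w[bi] - 1L), , , ,
                                     drop = FALSE]
        }
        r <- backward_chain(layer$branches[[bi]], p$branches[[bi]],
                            caches[[li]]$bcaches[[bi]], dsub)
        dbranch_params[[bi]] <- r$dparams
        dinput <- if (is.null(dinput)) r$dstreams else
          mapply(`+`, dinput, r$dstreams, SIMPLIFY = FALSE)
      }
      dparams[[li]] <- list(branches = dbranch_params)
      dstreams <- dinput
    }
  }
  list(dparams = dparams, dstreams = dstreams)
}

# ---------------------------------------------------------------------------
# user-facing forward passes

trials_to_stream <- function(trials) {
  # (B, E, T) -> activation (1, E, T, B)
  d <- dim(trials)
  x <- aperm(trials, c(2, 3, 1))
  dim(x) <- c(1L, d[2], d[3], d[1])
  list(list(x = x, start = 0L, step = 1L))
}

collect_predictions <- function(streams) {
  pieces <- lapply(streams, function(s) {
    d <- dim(s$x)  # (K, 1, T, B)
    pos <- s$start + (seq_len(d[3]) - 1L) * s$step
    z <- s$x
    dim(z) <- c(d[1], d[3], d[4])
    list(pos = pos, z = z)
  })
  pos_all <- unlist(lapply(pieces, `[[`, "pos"))
  ord <- order(pos_all)
  K <- dim(pieces[[1]]$z)[1]
  B <- dim(pieces[[1]]$z)[3]
  z_all <- array(0, c(K, length(pos_all), B))
  at <- 0L
  for (pc in pieces) {
    n <- length(pc$pos)
    z_all[, (at + 1L):(at + n), ] <- pc$z
    at <- at + n
  }
  list(scores = z_all[, ord, , drop = FALSE], positions = pos_all[ord],
       order = ord)
}

# scatter per-position score gradients (K, n_positions, B), ordered by crop
# start, back into the per-stream layout produced by forward_chain
scatter_dscores <- function(streams, pred, dscores) {
  inv <- pred$order
  dz_concat <- array(0, dim(dscores))
  dz_concat[, inv, ] <- dscores
  out <- vector("list", length(streams))
  at <- 0L
  for (i in seq_along(streams)) {
    d <- dim(streams[[i]]$x)  # (K, 1, T, B)
    g <- dz_concat[, (at + 1L):(at + d[3]), , drop = FALSE]
    dim(g) <- d
    out[[i]] <- g
    at <- at + d[3]
  }
  out
}

#' Forward pass of a network
#'
#' Computes pre-softmax class scores. With `dense = TRUE` the input may be
#' longer than the architecture's nominal input length and one prediction is
#' produced per possible crop start (the dense multi-crop pass: stride
#' offsets are kept in separate streams and interleaved only after the final
#' layer, giving outputs identical to running every crop separately).
#'
#' @param model an `eeg_network`.
#' @param trials array (B, E, T) (or E x T matrix for one trial).
#' @param dense produce one prediction per crop start.
#' @param training use batch statistics, apply dropout (internal use).
#' @return list with `scores` (K x n_positions x B), `probabilities` (same
#'   shape, softmax over K), and `positions` (0-based crop starts).
#' @export
network_forward <- function(model, trials, dense = FALSE, training = FALSE) {
  if (length(dim(trials)) == 2) {
    trials <- array(trials, c(1L, dim(trials)))
  }
  streams <- trials_to_stream(trials)
  fw <- forward_chain(model$spec$layers, model$params, streams,
                      training = training, dense = dense)
  pred <- collect_predictions(fw$streams)
  if (dense) {
    # only complete crops: pipelines with strided pooling discard trailing
    # samples and could otherwise emit predictions for truncated crops
    max_start <- dim(trials)[3] - model$spec$input_shape[2]
    keep <- pred$positions <= max_start
    pred$scores <- pred$scores[, keep, , drop = FALSE]
    pred$positions <- pred$positions[keep]
  }
  K <- dim(pred$scores)[1]
  probs <- apply(pred$scores, c(2, 3), softmax)
  dim(probs) <- dim(pred$scores)
  list(scores = pred$scores, probabilities = probs,
       positions = pred$positions)
}
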