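# Declarative architecture construction: deep / shallow / hybrid / residual
# ConvNets plus sizing and receptive-field arithmetic.

layer_conv_time <- function(k, n_filters, padding = "valid") {
  list(kind = "conv_time", k = as.integer(k), n_filters = as.integer(n_filters),
       stride = 1L, padding = padding)
}
layer_conv_spatial <- function(n_filters) {
  list(kind = "conv_spatial", n_filters = as.integer(n_filters), stride = 1L)
}
layer_conv_combined <- function(k, n_filters) {
  list(kind = "conv_combined", k = as.integer(k),
       n_filters = as.integer(n_filters), stride = 1L, padding = "valid")
}
layer_conv_class <- function(k, n_classes) {
  list(kind = "conv_class", k = as.integer(k), n_filters = as.integer(n_classes),
       stride = 1L, padding = "valid")
}
layer_bn <- function() list(kind = "batchnorm", stride = 1L)
layer_act <- function(activation) {
  list(kind = "act", activation = activation, stride = 1L)
}
layer_pool <- function(k, stride, mode) {
  list(kind = "pool", k = as.integer(k), stride = as.integer(stride),
       pool_mode = mode)
}
layer_dropout <- function(p = 0.5) list(kind = "dropout", p = p, stride = 1L)
# a convolution with stride s is expressed as the stride-1 convolution
# followed by this subsampling layer (a width-1 pooling window)
layer_subsample <- function(stride) layer_pool(1, stride, "mean")
layer_resblock <- function(k, n_filters) {
  list(kind = "resblock", k = as.integer(k), n_filters = as.integer(n_filters),
       stride = 1L, padding = "same")
}

#' Temporal output length of a layer chain
#'
#' Propagates the time-axis length through convolutions (valid or same) and
#' pooling layers; errors (naming the offending layer) if any layer no
#' longer fits.
#'
#' @param layers list of layer specs (e.g. `spec$layers`).
#' @param input_length input length in samples.
#' @return output length in samples.
#' @export
temporal_out_len <- function(layers, input_length) {
  len <- input_length
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind %in% c("conv_time", "conv_combined", "conv_class")) {
      if (!identical(l$padding, "same")) len <- len - l$k + 1L
    } else if (l$kind == "pool") {
      len <- (len - l$k) %/% l$stride + 1L
    } else if (l$kind == "branch") {
      lens <- vapply(l$branches, temporal_out_len, 0,
                     input_length = len)
      if (length(unique(lens)) > 1) {
        stop("branches of layer ", i, " disagree on output length")
      }
      len <- lens[1]
    }
    if (len < 1) {
      stop("layer ", i, " (", l$kind,
           if (!is.null(l[["k"]])) paste0(", kernel ", l[["k"]]) else "",
           ") does not fit: input too short")
    }
  }
  len
}

default_choices <- function() {
  list(split_first_layer = TRUE, batchnorm = TRUE, dropout = TRUE,
       activation = "elu", pool_mode = "max", factorized = FALSE,
       tied_loss = FALSE)
}

merge_choices <- function(choices) {
  utils::modifyList(default_choices(), as.list(choices))
}

new_arch_spec <- function(name, layers, E, input_length, K, choices) {
  structure(list(name = name, layers = layers,
                 input_shape = unname(c(as.integer(E),
                                        as.integer(input_length))),
                 n_classes = unname(as.integer(K)), choices = choices),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec> ", x$name, ": input ", x$input_shape[1], " x ",
      x$input_shape[2], ", ", x$n_classes, " classes, final kernel ",
      final_kernel_length(x), "\n", sep = "")
  invisible(x)
}

#' Temporal kernel length of the final classification layer
#' @param spec an `arch_spec`.
#' @return kernel length in samples.
#' @export
final_kernel_length <- function(spec) {
  cls <- Filter(function(l) l$kind == "conv_class", spec$layers)
  if (!length(cls)) {
    # hybrid: classification follows the branch concat
    return(spec$final_kernel)
  }
  cls[[length(cls)]]$k
}

#' Deep ConvNet architecture
#'
#' Four convolution-max-pooling blocks with a special first block (temporal
#' convolution, kernel 10, then a spatial convolution over all electrodes),
#' followed by a dense softmax classification layer implemented as a
#' convolution whose kernel spans the remaining temporal length. Batch
#' normalization is applied to convolution outputs before the nonlinearity;
#' dropout (p = 0.5) is applied to the inputs of all convolutional layers
#' after the first block; pooling windows are 3 samples with stride 3.
#'
#' Design-choice toggles (`choices`): `split_first_layer` (FALSE fuses the
#' first block into one E x 10 convolution), `batchnorm`, `dropout`,
#' `activation` ("elu"/"relu"/...), `pool_mode` ("max"/"mean"),
#' `factorized` (two kernel-6 temporal convolutions per conv layer instead
#' of one kernel-10).
#'
#' @param E number of electrodes.
#' @param input_length input length in samples (1125 for a -0.5..4 s trial
#'   at 250 Hz; ~500 for cropped training).
#' @param K number of classes.
#' @param choices named list overriding the defaults above.
#' @param n_filters per-block filter counts (length 5: temporal, spatial,
#'   blocks 2-4).
#' @param k temporal kernel length (default 10).
#' @return an `arch_spec`.
#' @export
build_deep <- function(E, input_length, K, choices = list(),
                       n_filters = c(25, 25, 50, 100, 200), k = 10) {
  ch <- merge_choices(choices)
  conv_stack <- function(kk, nf) {
    if (ch$factorized) {
      # two kernel-6 convolutions approximate one kernel-10 (and are only
      # used for the standard blocks, as in the evaluated variant)
      list(layer_conv_time(6, nf), layer_conv_time(6, nf))
    } else {
      list(layer_conv_time(kk, nf))
    }
  }
  layers <- list()
  if (ch$split_first_layer) {
    layers <- c(layers, list(layer_conv_time(k, n_filters[1]),
                             layer_conv_spatial(n_filters[2])))
  } else {
    layers <- c(layers, list(layer_conv_combined(k, n_filters[2])))
  }
  if (ch$batchnorm) layers <- c(layers, list(layer_bn()))
  layers <- c(layers, list(layer_act(ch$activation),
                           layer_pool(3, 3, ch$pool_mode)))
  for (b in 3:5) {
    if (ch$dropout) layers <- c(layers, list(layer_dropout(0.5)))
    layers <- c(layers, conv_stack(k, n_filters[b]))
    if (ch$batchnorm) layers <- c(layers, list(layer_bn()))
    layers <- c(layers, list(layer_act(ch$activation),
                             layer_pool(3, 3, ch$pool_mode)))
  }
  remaining <- temporal_out_len(layers, input_length)
  if (ch$dropout) layers <- c(layers, list(layer_dropout(0.5)))
  layers <- c(layers, list(layer_conv_class(remaining, K)))
  new_arch_spec("deep", layers, E, input_length, K, ch)
}

#' Shallow ConvNet architecture
#'
#' Temporal convolution (kernel 25), spatial convolution, squaring
#' nonlinearity, mean pooling (window 75, stride 15) and a logarithmic
#' activation — the band-power pipeline of FBCSP embedded in one trainable
#' network — followed by a dense softmax classification layer.
#'
#' `choices`: as [build_deep()]; additionally `activation` defaults to
#' "square" + log here and `post_pool_activation` may be set to "sqrt" to
#' test L2-pooling instead of the logarithm.
#'
#' @inheritParams build_deep
#' @param n_filters filter counts (temporal, spatial).
#' @return an `arch_spec`.
#' @export
build_shallow <- function(E, input_length, K, choices = list(),
                          n_filters = c(40, 40)) {
  ch <- merge_choices(utils::modifyList(
    list(activation = "square", pool_mode = "mean",
         post_pool_activation = "log"), as.list(choices)))
  layers <- list()
  if (ch$split_first_layer) {
    layers <- c(layers, list(layer_conv_time(25, n_filters[1]),
                             layer_conv_spatial(n_filters[2])))
  } else {
    layers <- c(layers, list(layer_conv_combined(25, n_filters[2])))
  }
  if (ch$batchnorm) layers <- c(layers, list(layer_bn()))
  layers <- c(layers, list(
    layer_act(ch$activation),
    layer_pool(75, 15, ch$pool_mode),
    layer_act(ch$post_pool_activation)
  ))
  remaining <- temporal_out_len(layers, input_length)
  if (ch$dropout) layers <- c(layers, list(layer_dropout(0.5)))
  layers <- c(layers, list(layer_conv_class(remaining, K)))
  new_arch_spec("shallow", layers, E, input_length, K, ch)
}

#' Hybrid ConvNet architecture
#'
#' The deep and shallow networks with their K-filter softmax classification
#' layers replaced by 60- and 40-filter ELU layers; the resulting 100
#' feature maps are concatenated and feed a new softmax classification
#' layer. Trained from scratch (no pretrained branch parameters).
#'
#' @inheritParams build_deep
#' @param deep_features,shallow_features ELU feature maps per branch
#'   (default 60 and 40).
#' @return an `arch_spec`.
#' @export
build_hybrid <- function(E, input_length, K, choices = list(),
                         deep_features = 60, shallow_features = 40) {
  dp <- build_deep(E, input_length, K, choices)
  sh <- build_shallow(E, input_length, K, choices)
  swap_head <- function(layers, n_feat) {
    i <- length(layers)
    stopifnot(layers[[i]]$kind == "conv_class")
    layers[[i]] <- layer_conv_time(layers[[i]]$k, n_feat)
    c(layers, list(layer_act("elu")))
  }
  branch_layer <- list(kind = "branch", stride = 1L,
                       branches = list(swap_head(dp$layers, deep_features),
                                       swap_head(sh$layers, shallow_features)))
  layers <- list(branch_layer, layer_conv_class(1, K))
  spec <- new_arch_spec("hybrid", layers, E, input_length, K,
                        merge_choices(choices))
  spec$n_feature_maps <- deep_features + shallow_features
  spec$final_kernel <- 1L
  spec
}

#' Residual ConvNet architecture
#'
#' Split temporal + spatial entry convolutions (as the deep and shallow
#' networks), batch normalization and ELU, followed by 14 residual blocks
#' (two same-padded temporal convolutions each, identity shortcut with
#' zero-padded channel increases — option A), interspersed max pooling for
#' temporal downsampling, a final mean pooling over the remaining length and
#' a dense softmax classification layer. Width schedule is configurable.
#'
#' @inheritParams build_deep
#' @param n_blocks number of residual blocks (default 14).
#' @param widths channel widths of the three stages.
#' @param k temporal kernel length inside blocks (default 3).
#' @return an `arch_spec`.
#' @export
build_resnet <- function(E, input_length, K, n_blocks = 14,
                         widths = c(24, 48, 96), k = 3) {
  layers <- list(layer_conv_time(10, widths[1]),
                 layer_conv_spatial(widths[1]),
                 layer_bn(), layer_act("elu"))
  stage_of <- function(b) ceiling(b * length(widths) / n_blocks)
  prev_stage <- 1
  for (b in seq_len(n_blocks)) {
    st <- stage_of(b)
    if (st > prev_stage) {
      layers <- c(layers, list(layer_pool(3, 3, "max")))
      prev_stage <- st
    }
    layers <- c(layers, list(layer_resblock(k, widths[st])))
  }
  remaining <- temporal_out_len(layers, input_length)
  layers <- c(layers, list(layer_pool(remaining, 1, "mean"),
                           layer_conv_class(1, K)))
  spec <- new_arch_spec("resnet", layers, E, input_length, K,
                        merge_choices(list(activation = "elu")))
  spec$n_residual_blocks <- n_blocks
  spec
}

#' Receptive field of a layer's units
#'
#' Standard recursion over kernels and strides: starting from
#' (rf, jump) = (1, 1), each layer with kernel k and stride s updates
#' rf <- rf + (k - 1) * jump, jump <- jump * s. The spatial receptive field
#' is 1 electrode before the spatial (or combined) convolution and all E
#' after it.
#'
#' @param spec an `arch_spec`.
#' @param layer_index index into `spec$layers`; the receptive field of that
#'   layer's outputs is returned.
#' @return named vector `c(temporal = samples, spatial = electrodes)`.
#' @export
receptive_field <- function(spec, layer_index) {
  stopifnot(layer_index >= 1, layer_index <= length(spec$layers))
  rf <- 1L; jump <- 1L
  spatial <- 1L
  E <- unname(spec$input_shape[1])
  for (i in seq_len(layer_index)) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv_time", "conv_class")) {
      rf <- rf + (l$k - 1L) * jump
    } else if (l$kind == "conv_combined") {
      rf <- rf + (l$k - 1L) * jump
      spatial <- E
    } else if (l$kind == "conv_spatial") {
      spatial <- E
    } else if (l$kind == "pool") {
      rf <- rf + (l$k - 1L) * jump
      jump <- jump * l$stride
    } else if (l$kind == "resblock") {
      rf <- rf + 2L * (l$k - 1L) * jump
    } else if (l$kind == "branch") {
      stop("receptive_field is defined for the trunk layers, not across ",
           "branch containers")
    }
  }
  c(temporal = rf, spatial = spatial)
}

#' Indices of the conv-pool block outputs of an architecture
#'
#' The default analysis layers for the unit-output correlation maps: the
#' output of each pooling layer (for pooled architectures) or of each
#' residual block.
#'
#' @param spec an `arch_spec`.
#' @return integer vector of layer indices.
#' @export
block_output_layers <- function(spec) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  idx <- which(kinds == "pool")
  if (!length(idx)) idx <- which(kinds == "resblock")
  idx
}
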