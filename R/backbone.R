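# Channels-as-depth CNN -> bidirectional LSTM -> attention -> classifier.
#
# EEG channels play the role of the convolutional depth dimension (like RGB
# planes), so convolutions have kernel (1, k) along time only and the depth
# grows by an algebraic progression chans*k0, chans*(k0+1), ...  Each layer
# halves the time axis (stride 2 with "same"-style zero padding, out =
# ceil(in/2)). After the last convolution the time axis becomes the sequence
# axis of a many-to-one bidirectional LSTM; an attention layer (none,
# learned-score softmax, multi-head, or margin-optimized) pools the LSTM
# outputs before the fully connected head.

#' Algebraic depth progression
#'
#' Layer depths `chans*k0, chans*(k0+1), ..., chans*(k0+n_layers-1)` — an
#' algebraic (not geometric) progression in the channel count.
#'
#' @param chans number of input channels (>= 1).
#' @param n_layers number of convolutional layers.
#' @param k0 starting multiplier (>= 1).
#' @return integer vector of layer depths.
#' @export
depth_progression <- function(chans, n_layers, k0 = 1L) {
  if (chans < 1L || n_layers < 1L || k0 < 1L)
    stop("chans, n_layers and k0 must all be >= 1")
  as.integer(chans) * (as.integer(k0) + seq_len(n_layers) - 1L)
}

#' Backbone configuration
#'
#' @param in_channels EEG channel count (used as convolutional depth in
#'   collapsed mode).
#' @param n_layers number of conv layers.
#' @param depth_start_multiplier starting multiplier k0 of the algebraic
#'   depth progression.
#' @param kernel temporal kernel length k of the (1, k) kernels; 8, 24 and
#'   40 are the studied values but any k >= 1 is accepted.
#' @param spatial_mode `"collapsed"` (channels-as-depth) or `"preserved"`
#'   (channels kept as a spatial axis, the baseline layout).
#' @param depths optional explicit depth sequence overriding the algebraic
#'   progression (used e.g. for the doubling baseline 8, 16, ..., 256).
#' @param lstm_hidden hidden units per LSTM direction.
#' @param activation head activation: `"relu"` or `"abs_tanh"`
#'   (`|x| * tanh(x)`).
#' @param batch_norm apply batch normalization after each convolution.
#' @param attention `"none"`, `"softmax"` (learned-score), `"multi_head"`,
#'   or `"svm_margin"`.
#' @param n_heads heads for multi-head attention.
#' @param input_time model input window length in samples.
#' @param head_hidden hidden units of the classification head.
#' @param C regularization weight of the margin objective.
#' @param lambda_aux weight of the auxiliary hinge loss.
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(in_channels, n_layers = 3L,
                            depth_start_multiplier = 1L, kernel = 24L,
                            spatial_mode = c("collapsed", "preserved"),
                            depths = NULL, lstm_hidden = 32L,
                            activation = c("relu", "abs_tanh"),
                            batch_norm = TRUE,
                            attention = c("none", "softmax", "multi_head",
                                          "svm_margin"),
                            n_heads = 2L, input_time = 180L,
                            head_hidden = 32L, C = 1, lambda_aux = 0.1) {
  spatial_mode <- match.arg(spatial_mode)
  activation <- match.arg(activation)
  attention <- match.arg(attention)
  kernel <- if (length(kernel) == 2L) as.integer(kernel[2L]) else as.integer(kernel)
  if (kernel < 1L) stop("kernel length must be >= 1")
  depths <- if (is.null(depths)) {
    base <- if (spatial_mode == "collapsed") in_channels else 1L
    depth_progression(max(1L, base), n_layers, depth_start_multiplier)
  } else as.integer(depths)
  structure(list(in_channels = as.integer(in_channels),
                 n_layers = length(depths),
                 depth_start_multiplier = as.integer(depth_start_multiplier),
                 kernel = kernel, spatial_mode = spatial_mode, depths = depths,
                 lstm_hidden = as.integer(lstm_hidden), activation = activation,
                 batch_norm = isTRUE(batch_norm), attention = attention,
                 n_heads = as.integer(n_heads), input_time = as.integer(input_time),
                 head_hidden = as.integer(head_hidden), C = C,
                 lambda_aux = lambda_aux),
            class = "backbone_config")
}

#' Layer-by-layer shape arithmetic of the convolutional stack
#'
#' Reproduces the output-dimension bookkeeping of the channels-as-depth
#' design: layer i has depth `depths[i]`; the time axis halves with ceiling
#' each layer starting from `input_time`; the spatial axis is 1 in collapsed
#' mode and `in_channels` in preserved mode. The flattened size is
#' depth x spatial x time.
#'
#' @param cfg a [backbone_config()].
#' @param input_time input window length (defaults to `cfg$input_time`).
#' @return data.frame with columns `layer`, `batch`, `depth`, `spatial`,
#'   `time`, `flattened`.
#' @export
shape_trace <- function(cfg, input_time = cfg$input_time) {
  if (input_time < 2^cfg$n_layers)
    stop("input_time too short for the number of halving layers")
  spatial <- if (cfg$spatial_mode == "collapsed") 1L else cfg$in_channels
  tm <- as.integer(input_time)
  out <- data.frame(layer = seq_len(cfg$n_layers), batch = 1L,
                    depth = cfg$depths, spatial = spatial, time = 0L,
                    flattened = 0L)
  for (i in seq_len(cfg$n_layers)) {
    tm <- as.integer(ceiling(tm / 2))
    if (tm < 1L) stop("time dimension collapsed to zero")
    out$time[i] <- tm
  }
  out$flattened <- out$depth * out$spatial * out$time
  out
}

#' Per-timestep feature dimension entering the LSTM
#'
#' Depth of the final conv layer in collapsed mode; depth x channels in
#' preserved mode (448 vs 16384 for the 64-channel reference configuration).
#'
#' @param cfg a [backbone_config()].
#' @return integer.
#' @export
lstm_input_dim <- function(cfg) {
  d <- cfg$depths[cfg$n_layers]
  if (cfg$spatial_mode == "collapsed") d else d * cfg$in_channels
}

#' The |x| * tanh(x) activation
#'
#' Odd, monotone non-decreasing, asymptotically |x|; dampens small inputs
#' quadratically while behaving linearly for large ones.
#'
#' @param x numeric.
#' @return `abs(x) * tanh(x)`.
#' @export
abs_tanh <- function(x) abs(x) * tanh(x)

#' Build the CNN + BiLSTM (+ attention) classifier
#'
#' Initializes all parameters (seed the RNG beforehand for reproducibility)
#' and returns a model object whose `forward` composes the autodiff graph.
#'
#' @param cfg a [backbone_config()].
#' @return list of class `mi_model` with elements `cfg`, `params`,
#'   `forward(tape, pn, x, y = NULL)`.
#' @export
build_backbone <- function(cfg) {
  stopifnot(inherits(cfg, "backbone_config"))
  st <- shape_trace(cfg)
  collapsed <- cfg$spatial_mode == "collapsed"
  d_in <- if (collapsed) cfg$in_channels else 1L
  params <- list()
  for (i in seq_len(cfg$n_layers)) {
    din_i <- if (i == 1L) d_in else cfg$depths[i - 1L]
    params <- add_params(params, sprintf("conv%d", i),
                         init_conv1d(din_i, cfg$depths[i], cfg$kernel))
    if (cfg$batch_norm)
      params <- add_params(params, sprintf("bn%d", i), init_bn(cfg$depths[i]))
  }
  d_feat <- lstm_input_dim(cfg)
  h <- cfg$lstm_hidden
  params <- add_params(params, "lstm.fw", init_lstm_dir(d_feat, h))
  params <- add_params(params, "lstm.bw", init_lstm_dir(d_feat, h))
  d_ctx <- 2L * h
  params <- switch(cfg$attention,
    none = params,
    softmax = add_params(params, "attn",
                         list(u = glorot(d_ctx, 1L), c = numeric(1L))),
    svm_margin = add_params(params, "attn",
                            list(A = glorot(d_ctx, 1L), b = numeric(1L))),
    multi_head = add_params(params, "attn", init_mha(d_ctx, cfg$n_heads)))
  params <- add_params(params, "head1", init_dense(d_ctx, cfg$head_hidden))
  params <- add_params(params, "head2", init_dense(cfg$head_hidden, 2L))

  n_t <- st$time[cfg$n_layers]
  forward <- function(tape, pn, x, y = NULL) {
    n_b <- dim(x)[1L]
    xin <- if (collapsed) x else {
      x2 <- aperm(x, c(1L, 2L, 3L))          # (B, C, T)
      dim(x2) <- c(n_b * cfg$in_channels, 1L, dim(x)[3L])
      x2
    }
    hconv <- nn_conv_stack(tape, pn, cfg$n_layers, ad_input(tape, xin),
                           stride = 2L, batch_norm = cfg$batch_norm)
    # time becomes the sequence axis: (B, T, features)
    x3 <- if (collapsed) {
      ad_aperm(hconv, c(1L, 3L, 2L))
    } else {
      dn <- cfg$depths[cfg$n_layers]
      r4 <- ad_reshape(hconv, c(n_b, cfg$in_channels, dn, n_t))
      ad_reshape(ad_aperm(r4, c(1L, 4L, 2L, 3L)),
                 c(n_b, n_t, cfg$in_channels * dn))
    }
    lstm <- nn_bilstm3(tape, pn, "lstm", x3, n_b, n_t, h)
    k2 <- lstm$steps2                         # (B*T x 2h)
    attn_w <- NULL; aux <- NULL
    if (cfg$attention == "none") {
      feat <- lstm$final
    } else if (cfg$attention %in% c("softmax", "svm_margin")) {
      at <- if (cfg$attention == "softmax")
        nn_score_attn(tape, pn, "attn", k2, n_b, n_t)
      else
        nn_margin_attn(tape, pn, "attn", k2, n_b, n_t, y = y, C = cfg$C)
      feat <- at$context; attn_w <- at$weights; aux <- at$aux
    } else {                                  # multi_head
      mh <- nn_mha(tape, pn, "attn", k2, n_b, n_t, cfg$n_heads)
      feat <- ad_scale(ad_rowsum_group(mh, rep(seq_len(n_b), n_t), n_b), 1 / n_t)
    }
    logits <- nn_head(tape, pn, feat, cfg$activation)
    list(logits = logits, aux = aux, feat = feat, attn = attn_w)
  }
  structure(list(cfg = cfg, params = params, forward = forward,
                 lambda_aux = cfg$lambda_aux),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<mi_model> %s, attention=%s, %d parameters\n",
              class(x$cfg), x$cfg$attention %||% "-", np))
  invisible(x)
}
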