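# Transformer encoder pathway: fixed-length crops of the epochs are resized
# by linear interpolation, cut into patches, linearly projected with learned
# positional embeddings, and passed through pre-norm encoder blocks
# (LN -> attention -> skip, LN -> MLP -> skip). The attention inside each
# block is either standard multi-head softmax attention or the
# margin-optimized scoring layer.

#' Transformer configuration
#'
#' @param n_channels EEG channels of the input crops.
#' @param crop_len crop length in samples (default 45).
#' @param resize_len length after 1-D linear-interpolation resize
#'   (default 72); must be divisible by `patch_size`.
#' @param patch_size samples per patch (default 8).
#' @param n_blocks encoder blocks.
#' @param n_heads attention heads; must divide `projection_dim`.
#' @param projection_dim token embedding dimension.
#' @param mlp_hidden hidden units of the block MLP.
#' @param use_conv_down if `TRUE`, a channels-as-depth convolutional front
#'   end downsamples the resized crop and its timesteps become the tokens
#'   (patch encoding is bypassed).
#' @param attention_kind `"multi_head"` or `"svm_margin"`.
#' @param head_hidden classifier head hidden units.
#' @param activation head activation (`"relu"` or `"abs_tanh"`).
#' @param conv_layers,conv_kernel front-end stack geometry when
#'   `use_conv_down = TRUE`.
#' @param C,lambda_aux margin-objective parameters (see
#'   [margin_params()]).
#' @return list of class `transformer_config`.
#' @export
transformer_config <- function(n_channels, crop_len = 45L, resize_len = 72L,
                               patch_size = 8L, n_blocks = 1L, n_heads = 2L,
                               projection_dim = 16L, mlp_hidden = 32L,
                               use_conv_down = FALSE,
                               attention_kind = c("multi_head", "svm_margin"),
                               head_hidden = 32L,
                               activation = c("relu", "abs_tanh"),
                               conv_layers = 2L, conv_kernel = 8L,
                               C = 1, lambda_aux = 0.1) {
  attention_kind <- match.arg(attention_kind)
  activation <- match.arg(activation)
  if (resize_len %% patch_size != 0L)
    stop("resize_len must be divisible by patch_size")
  if (projection_dim %% n_heads != 0L)
    stop("n_heads must divide projection_dim")
  structure(list(n_channels = as.integer(n_channels),
                 crop_len = as.integer(crop_len),
                 resize_len = as.integer(resize_len),
                 patch_size = as.integer(patch_size),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 projection_dim = as.integer(projection_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 use_conv_down = isTRUE(use_conv_down),
                 attention_kind = attention_kind,
                 head_hidden = as.integer(head_hidden), activation = activation,
                 conv_layers = as.integer(conv_layers),
                 conv_kernel = as.integer(conv_kernel),
                 C = C, lambda_aux = lambda_aux),
            class = "transformer_config")
}

#' Cut epochs into fixed-length crops
#'
#' Non-overlapping consecutive crops per trial; each crop inherits the trial
#' label; remainder samples are dropped. The crop count per trial is
#' `floor(samples / crop_len)`.
#'
#' @param epochs an `epoch_set`.
#' @param crop_len crop length in samples.
#' @return an `epoch_set` of crops with an extra element `trial_idx`
#'   mapping each crop to its source trial.
#' @export
crop_series <- function(epochs, crop_len = 45L) {
  d <- dim(epochs$data)
  if (crop_len > d[3L]) stop("crop_len exceeds the epoch length")
  ncr <- d[3L] %/% crop_len
  data <- array(0, c(d[1L] * ncr, d[2L], crop_len))
  trial_idx <- integer(d[1L] * ncr)
  for (i in seq_len(d[1L])) {
    for (j in seq_len(ncr)) {
      r <- (i - 1L) * ncr + j
      data[r, , ] <- epochs$data[i, , (j - 1L) * crop_len + seq_len(crop_len)]
      trial_idx[r] <- i
    }
  }
  out <- new_epoch_set(data, rep(epochs$labels, each = ncr), epochs$fs,
                       epochs$subject_id,
                       kept_trial_idx = rep(epochs$kept_trial_idx, each = ncr),
                       channel_names = epochs$channel_names)
  out$trial_idx <- trial_idx
  out
}

# (to x from) linear interpolation matrix mapping `from` samples onto `to`
resize_matrix <- function(from, to) {
  pos <- seq(1, from, length.out = to)
  M <- matrix(0, to, from)
  lo <- pmin(floor(pos), from - 1L)
  w <- pos - lo
  M[cbind(seq_len(to), lo)] <- 1 - w
  M[cbind(seq_len(to), lo + 1L)] <- w
  M
}

#' Resize crops along time by linear interpolation
#'
#' @param x crops array (n x channels x samples).
#' @param resize_len target length.
#' @return array (n x channels x resize_len).
#' @export
resize_crops <- function(x, resize_len = 72L) {
  d <- dim(x)
  if (d[3L] == resize_len) return(x)
  M <- resize_matrix(d[3L], resize_len)
  flat <- matrix(x, d[1L] * d[2L], d[3L])
  array(tcrossprod(flat, M), c(d[1L], d[2L], resize_len))
}

#' Patch-encode resized crops
#'
#' Splits each crop into `resize_len / patch_size` consecutive patches (all
#' channels of `patch_size` samples), projects each flattened patch with a
#' learned linear map and adds a learned positional embedding.
#'
#' @param x array (n x channels x resize_len).
#' @param cfg a [transformer_config()].
#' @param params list with `W` (`channels*patch_size x projection_dim`),
#'   `b`, and `pos` (`n_tokens x projection_dim`); when `NULL`, freshly
#'   initialized parameters are used (seed the RNG for reproducibility).
#' @return list with `tokens` (n x n_tokens x projection_dim) and `params`.
#' @export
patch_encode <- function(x, cfg, params = NULL) {
  d <- dim(x)
  if (d[3L] %% cfg$patch_size != 0L)
    stop("crop length not divisible by patch_size")
  n_tok <- d[3L] %/% cfg$patch_size
  if (is.null(params)) {
    params <- list(W = glorot(d[2L] * cfg$patch_size, cfg$projection_dim),
                   b = numeric(cfg$projection_dim),
                   pos = matrix(stats::rnorm(n_tok * cfg$projection_dim, 0, 0.02),
                                n_tok, cfg$projection_dim))
  }
  pm <- patch_matrix(x, cfg$patch_size)              # (n*n_tok) x (C*patch)
  tok <- pm %*% params$W + rep(params$b, each = nrow(pm))
  tok <- tok + params$pos[rep(seq_len(n_tok), each = d[1L]), ]
  list(tokens = array(tok, c(d[1L], n_tok, cfg$projection_dim)),
       params = params, n_tokens = n_tok)
}

# flatten patches: rows ordered crop-major within token blocks
# (row = n + (tok-1)*N), columns = channel-major then within-patch sample
patch_matrix <- function(x, patch_size) {
  d <- dim(x)
  n_tok <- d[3L] %/% patch_size
  out <- matrix(0, d[1L] * n_tok, d[2L] * patch_size)
  for (t in seq_len(n_tok)) {
    blk <- x[, , (t - 1L) * patch_size + seq_len(patch_size), drop = FALSE]
    out[(t - 1L) * d[1L] + seq_len(d[1L]), ] <- matrix(blk, d[1L],
                                                       d[2L] * patch_size)
  }
  out
}

init_transformer_block <- function(cfg) {
  pd <- cfg$projection_dim
  p <- list()
  p <- add_params(p, "ln1", list(gamma = rep(1, pd), beta = numeric(pd)))
  if (cfg$attention_kind == "multi_head") {
    p <- add_params(p, "attn", init_mha(pd, cfg$n_heads))
  } else {
    p <- add_params(p, "attn", list(A = glorot(pd, 1L), b = numeric(1L),
                                    Wv = glorot(pd, pd), Wo = glorot(pd, pd),
                                    bo = numeric(pd)))
  }
  p <- add_params(p, "ln2", list(gamma = rep(1, pd), beta = numeric(pd)))
  p <- add_params(p, "mlp1", init_dense(pd, cfg$mlp_hidden))
  p <- add_params(p, "mlp2", init_dense(cfg$mlp_hidden, pd))
  p
}

# expand per-trial rows back to per-token rows (inverse of ad_rowsum_group)
ad_expand_rows <- function(a, group) {
  A <- ad_value(a)
  ad_node(a$tape, A[group, , drop = FALSE], a$id, function(g)
    list(rowsum(g, group = factor(group, levels = seq_len(nrow(A))))))
}

# one encoder block on token matrix x2 ((B*T) x pd).
# out = t2 + MLP(LN2(t2)),  t2 = x + Attn(LN1(x))
nn_transformer_block <- function(tape, pn, prefix, x2, n_b, n_t, cfg,
                                 y = NULL) {
  p <- function(s) pn[[paste0(prefix, ".", s)]]
  ln1 <- ad_layernorm_rows(x2, p("ln1.gamma"), p("ln1.beta"))
  aux <- NULL; attn_w <- NULL
  if (cfg$attention_kind == "multi_head") {
    att <- nn_mha(tape, pn, paste0(prefix, ".attn"), ln1, n_b, n_t, cfg$n_heads)
  } else {
    ma <- nn_margin_attn(tape, pn, paste0(prefix, ".attn"), ln1, n_b, n_t,
                         y = y, C = cfg$C)
    aux <- ma$aux; attn_w <- ma$weights
    v2 <- ad_matmul(ln1, p("attn.Wv"))
    wflat <- ad_reshape(ma$weights, c(n_b * n_t))
    grp <- rep(seq_len(n_b), n_t)
    ctx <- ad_rowsum_group(ad_mul_rows(v2, wflat), grp, n_b)
    att <- ad_add(ad_matmul(ad_expand_rows(ctx, grp), p("attn.Wo")),
                  p("attn.bo"))
  }
  t2 <- ad_add(x2, att)
  ln2 <- ad_layernorm_rows(t2, p("ln2.gamma"), p("ln2.beta"))
  mlp <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(ln2, p("mlp1.W")),
                                         p("mlp1.b"))), p("mlp2.W")),
                p("mlp2.b"))
  list(tokens = ad_add(t2, mlp), aux = aux, attn = attn_w)
}

#' Build the transformer encoder classifier
#'
#' Patch-encodes the (already resized) input crops, applies `n_blocks`
#' encoder blocks, mean-pools the tokens and classifies with a small dense
#' head. With `use_conv_down = TRUE` a channels-as-depth conv stack runs
#' first and its timesteps are the tokens.
#'
#' @param cfg a [transformer_config()].
#' @return an `mi_model` (same interface as [build_backbone()]); its
#'   forward expects inputs of length `resize_len` (use [resize_crops()]).
#' @export
build_transformer <- function(cfg) {
  stopifnot(inherits(cfg, "transformer_config"))
  pd <- cfg$projection_dim
  params <- list()
  if (cfg$use_conv_down) {
    conv_cfg <- backbone_config(cfg$n_channels, n_layers = cfg$conv_layers,
                                kernel = cfg$conv_kernel,
                                input_time = cfg$resize_len)
    for (i in seq_len(conv_cfg$n_layers)) {
      din_i <- if (i == 1L) cfg$n_channels else conv_cfg$depths[i - 1L]
      params <- add_params(params, sprintf("conv%d", i),
                           init_conv1d(din_i, conv_cfg$depths[i],
                                       conv_cfg$kernel))
      params <- add_params(params, sprintf("bn%d", i),
                           init_bn(conv_cfg$depths[i]))
    }
    n_tok <- shape_trace(conv_cfg)$time[conv_cfg$n_layers]
    d_tok <- conv_cfg$depths[conv_cfg$n_layers]
    params <- add_params(params, "patch",
                         list(W = glorot(d_tok, pd), b = numeric(pd),
                              pos = matrix(stats::rnorm(n_tok * pd, 0, 0.02),
                                           n_tok, pd)))
  } else {
    conv_cfg <- NULL
    n_tok <- cfg$resize_len %/% cfg$patch_size
    params <- add_params(params, "patch",
                         list(W = glorot(cfg$n_channels * cfg$patch_size, pd),
                              b = numeric(pd),
                              pos = matrix(stats::rnorm(n_tok * pd, 0, 0.02),
                                           n_tok, pd)))
  }
  for (bl in seq_len(cfg$n_blocks)) {
    bp <- init_transformer_block(cfg)
    names(bp) <- paste0(sprintf("block%d", bl), ".", names(bp))
    params <- c(params, bp)
  }
  params <- add_params(params, "head1", init_dense(pd, cfg$head_hidden))
  params <- add_params(params, "head2", init_dense(cfg$head_hidden, 2L))

  forward <- function(tape, pn, x, y = NULL) {
    n_b <- dim(x)[1L]
    if (cfg$use_conv_down) {
      hc <- nn_conv_stack(tape, pn, conv_cfg$n_layers, ad_input(tape, x),
                          stride = 2L, batch_norm = TRUE)
      xs <- lapply(seq_len(n_tok), function(t) ad_slice_time(hc, t))
      tok <- ad_rbind(xs)                                  # (B*T x d_tok)
    } else {
      tok <- ad_input(tape, patch_matrix(x, cfg$patch_size))
    }
    tok <- ad_add(ad_matmul(tok, pn[["patch.W"]]), pn[["patch.b"]])
    pos <- ad_value(pn[["patch.pos"]])[rep(seq_len(n_tok), each = n_b), ,
                                       drop = FALSE]
    # positional embedding broadcast over the batch
    tok <- ad_add(tok, ad_node(tape, pos, pn[["patch.pos"]]$id, function(g)
      list(rowsum(g, group = factor(rep(seq_len(n_tok), each = n_b),
                                    levels = seq_len(n_tok))))))
    aux_total <- NULL; attn_w <- NULL
    for (bl in seq_len(cfg$n_blocks)) {
      blk <- nn_transformer_block(tape, pn, sprintf("block%d", bl), tok,
                                  n_b, n_tok, cfg, y = y)
      tok <- blk$tokens
      if (!is.null(blk$aux))
        aux_total <- if (is.null(aux_total)) blk$aux else
          ad_add(aux_total, blk$aux)
      if (!is.null(blk$attn)) attn_w <- blk$attn
    }
    feat <- ad_scale(ad_rowsum_group(tok, rep(seq_len(n_b), n_tok), n_b),
                     1 / n_tok)
    logits <- nn_head(tape, pn, feat, cfg$activation)
    list(logits = logits, aux = aux_total, feat = feat, attn = attn_w)
  }
  structure(list(cfg = cfg, params = params, forward = forward,
                 lambda_aux = cfg$lambda_aux),
            class = "mi_model")
}

#' Train with AdamW and metric-based early stopping
#'
#' Thin wrapper around [train_model()] exposing the optimizer
#' configuration as a list: decoupled-weight-decay Adam, per-epoch
#' validation metric tracking (best initialized to -infinity), stop after
#' `patience` non-improving epochs, restore the best checkpoint.
#'
#' @param model an `mi_model`.
#' @param data list with `x`, `y`, `val_x`, `val_y`.
#' @param optimizer_cfg list with any of `lr`, `weight_decay`, `epochs`,
#'   `batch_size`, `patience`.
#' @param seed RNG seed for shuffling.
#' @return list with `model` (best checkpoint restored) and `history`.
#' @export
train_with_early_stopping <- function(model, data,
                                      optimizer_cfg = list(), seed = 1L) {
  oc <- utils::modifyList(list(lr = 1e-3, weight_decay = 1e-2, epochs = 30L,
                               batch_size = 64L, patience = 10L), optimizer_cfg)
  m <- train_model(model, data$x, data$y, data$val_x, data$val_y,
                   epochs = oc$epochs, batch_size = oc$batch_size,
                   lr = oc$lr, weight_decay = oc$weight_decay,
                   patience = oc$patience, seed = seed)
  list(model = m, history = attr(m, "history"),
       best_epoch = attr(m, "best_epoch"))
}
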