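# Layer builders on top of the autodiff engine. Parameters live in a flat
# named list of plain arrays; builders take the matching list of lifted tape
# nodes (`pn`) and compose the forward graph.

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_dense <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

init_conv1d <- function(d_in, d_out, k) {
  lim <- sqrt(6 / (d_in * k + d_out * k))
  list(W = array(stats::runif(d_out * d_in * k, -lim, lim), c(d_out, d_in, k)),
       b = numeric(d_out))
}

init_bn <- function(d) list(gamma = rep(1, d), beta = numeric(d))

init_lstm_dir <- function(d_in, hidden) {
  b <- numeric(4L * hidden)
  b[hidden + seq_len(hidden)] <- 1           # forget-gate bias
  list(W = glorot(d_in, 4L * hidden), U = glorot(hidden, 4L * hidden), b = b)
}

# prefix params with a name, flattening into the destination list
add_params <- function(dst, prefix, p) {
  names(p) <- paste0(prefix, ".", names(p))
  c(dst, p)
}

lift_params <- function(tape, params) lapply(params, function(p) ad_input(tape, p))

# conv -> (batch norm) -> ReLU, repeated; x: (B, Din, T) node
nn_conv_stack <- function(tape, pn, n_layers, x, stride = 2L, batch_norm = TRUE) {
  h <- x
  for (i in seq_len(n_layers)) {
    h <- ad_conv1d(h, pn[[sprintf("conv%d.W", i)]], pn[[sprintf("conv%d.b", i)]],
                   stride = stride)
    d <- dim(ad_value(h))
    if (batch_norm) {
      h2 <- ad_reshape(ad_aperm(h, c(1L, 3L, 2L)), c(d[1L] * d[3L], d[2L]))
      h2 <- ad_batchnorm_cols(h2, pn[[sprintf("bn%d.gamma", i)]],
                              pn[[sprintf("bn%d.beta", i)]])
      h <- ad_aperm(ad_reshape(h2, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
    }
    h <- ad_relu(h)
  }
  h
}

init_mha <- function(dim, n_heads) {
  stopifnot(dim %% n_heads == 0L)
  list(Wq = glorot(dim, dim), Wk = glorot(dim, dim), Wv = glorot(dim, dim),
       Wo = glorot(dim, dim), bo = numeric(dim))
}

# multi-head softmax self-attention over tokens.
# x2: (B*T x dim) node, rows ordered b + (t-1)*B.  Returns (B*T x dim).
nn_mha <- function(tape, pn, prefix, x2, n_b, n_t, n_heads) {
  dim_ <- ncol(ad_value(x2))
  dh <- dim_ %/% n_heads
  Q <- ad_matmul(x2, pn[[paste0(prefix, ".Wq")]])
  K <- ad_matmul(x2, pn[[paste0(prefix, ".Wk")]])
  V <- ad_matmul(x2, pn[[paste0(prefix, ".Wv")]])
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    q3 <- ad_reshape(ad_cols(Q, cols), c(n_b, n_t, dh))
    k3 <- ad_reshape(ad_cols(K, cols), c(n_b, n_t, dh))
    v3 <- ad_reshape(ad_cols(V, cols), c(n_b, n_t, dh))
    sc <- ad_scale(ad_bmm(q3, k3, tB = TRUE), 1 / sqrt(dh))   # (B, T, T)
    att <- ad_reshape(ad_softmax_rows(ad_reshape(sc, c(n_b * n_t, n_t))),
                      c(n_b, n_t, n_t))
    ctx <- ad_bmm(att, v3)                                    # (B, T, dh)
    heads[[h]] <- ad_reshape(ctx, c(n_b * n_t, dh))
  }
  ad_add(ad_matmul(ad_concat_cols(heads), pn[[paste0(prefix, ".Wo")]]),
         pn[[paste0(prefix, ".bo")]])
}

# margin-score attention pooling over timesteps.
# k2: (B*T x d) node of key/feature vectors (rows b + (t-1)*B); the same
# matrix serves as the values. Scores s = K A + b are softmax-normalized per
# trial; returns pooled context (B x d), the weights (B x T) node, and the
# auxiliary hinge objective on the pooled features when labels are given.
nn_margin_attn <- function(tape, pn, prefix, k2, n_b, n_t, y = NULL, C = 1) {
  nm <- function(s) if (nzchar(prefix)) paste0(prefix, ".", s) else s
  s <- ad_add(ad_matmul(k2, pn[[nm("A")]]), pn[[nm("b")]])  # (B*T x 1)
  w <- ad_softmax_rows(ad_reshape(s, c(n_b, n_t)))        # (B x T)
  wflat <- ad_reshape(w, c(n_b * n_t))
  grp <- rep(seq_len(n_b), n_t)
  ctx <- ad_rowsum_group(ad_mul_rows(k2, wflat), grp, n_b)  # (B x d)
  aux <- NULL
  if (!is.null(y)) {
    mar <- ad_add(ad_matmul(ctx, pn[[nm("A")]]), pn[[nm("b")]])
    aux <- ad_add(ad_scale(ad_sum_sq(pn[[nm("A")]]), 0.5),
                  ad_scale(ad_hinge_sum(mar, y), C))
  }
  list(context = ctx, weights = w, aux = aux)
}

# learned-score softmax attention pooling (same form as nn_margin_attn but
# without the margin objective): the conventional attention baseline.
nn_score_attn <- function(tape, pn, prefix, k2, n_b, n_t) {
  s <- ad_add(ad_matmul(k2, pn[[paste0(prefix, ".u")]]),
              pn[[paste0(prefix, ".c")]])
  w <- ad_softmax_rows(ad_reshape(s, c(n_b, n_t)))
  wflat <- ad_reshape(w, c(n_b * n_t))
  grp <- rep(seq_len(n_b), n_t)
  ctx <- ad_rowsum_group(ad_mul_rows(k2, wflat), grp, n_b)
  list(context = ctx, weights = w, aux = NULL)
}

# classification head: dense -> activation -> dense(2)
nn_head <- function(tape, pn, feat, activation = "relu") {
  h <- ad_add(ad_matmul(feat, pn[["head1.W"]]), pn[["head1.b"]])
  h <- if (activation == "abs_tanh") ad_abs_tanh(h) else ad_relu(h)
  ad_add(ad_matmul(h, pn[["head2.W"]]), pn[["head2.b"]])
}
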