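# Fused LSTM: one tape node per direction with hand-derived
# backpropagation-through-time, instead of ~30 graph nodes per timestep.
# Gate order in the packed weight matrices: input, forget, cell, output.

# x: (B, T, d) node; W: (d, 4h); U: (h, 4h); b: (4h).
# Returns the hidden-state sequence as a (B, T, h) node; `reverse = TRUE`
# processes timesteps right-to-left (states stored at original positions).
ad_lstm_dir <- function(x, W, U, b, reverse = FALSE) {
  tape <- x$tape
  W <- ad_lift(tape, W); U <- ad_lift(tape, U); b <- ad_lift(tape, b)
  X <- ad_value(x); Wv <- ad_value(W); Uv <- ad_value(U); bv <- as.vector(ad_value(b))
  db <- dim(X)[1L]; n_t <- dim(X)[2L]; d <- dim(X)[3L]
  h <- ncol(Uv) %/% 4L
  ii <- seq_len(h); fi <- h + ii; gi <- 2L * h + ii; oi <- 3L * h + ii
  ts <- if (reverse) rev(seq_len(n_t)) else seq_len(n_t)
  H <- array(0, c(db, n_t, h))
  Ig <- Fg <- Gg <- Og <- Tc <- Hprev <- Cprev <- array(0, c(db, n_t, h))
  h_prev <- matrix(0, db, h); c_prev <- matrix(0, db, h)
  for (t in ts) {
    z <- X[, t, ] %*% Wv + h_prev %*% Uv + rep(bv, each = db)
    gI <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    gF <- 1 / (1 + exp(-z[, fi, drop = FALSE]))
    gG <- tanh(z[, gi, drop = FALSE])
    gO <- 1 / (1 + exp(-z[, oi, drop = FALSE]))
    Hprev[, t, ] <- h_prev; Cprev[, t, ] <- c_prev
    cc <- gF * c_prev + gI * gG
    tc <- tanh(cc)
    hh <- gO * tc
    Ig[, t, ] <- gI; Fg[, t, ] <- gF; Gg[, t, ] <- gG; Og[, t, ] <- gO
    Tc[, t, ] <- tc
    H[, t, ] <- hh
    h_prev <- hh; c_prev <- cc
  }
  ad_node(tape, H, c(x$id, W$id, U$id, b$id), function(gH) {
    dX <- array(0, c(db, n_t, d))
    dW <- matrix(0, d, 4L * h); dU <- matrix(0, h, 4L * h)
    dbv <- numeric(4L * h)
    dh_next <- matrix(0, db, h); dc_next <- matrix(0, db, h)
    dz <- matrix(0, db, 4L * h)
    for (t in rev(ts)) {
      dh <- matrix(gH[, t, ], db, h) + dh_next
      gI <- matrix(Ig[, t, ], db, h); gF <- matrix(Fg[, t, ], db, h)
      gG <- matrix(Gg[, t, ], db, h); gO <- matrix(Og[, t, ], db, h)
      tc <- matrix(Tc[, t, ], db, h)
      dc <- dh * gO * (1 - tc * tc) + dc_next
      dz[, ii] <- dc * gG * gI * (1 - gI)
      dz[, fi] <- dc * matrix(Cprev[, t, ], db, h) * gF * (1 - gF)
      dz[, gi] <- dc * gI * (1 - gG * gG)
      dz[, oi] <- dh * tc * gO * (1 - gO)
      xt <- matrix(X[, t, ], db, d)
      hp <- matrix(Hprev[, t, ], db, h)
      dW <- dW + crossprod(xt, dz)
      dU <- dU + crossprod(hp, dz)
      dbv <- dbv + colSums(dz)
      dX[, t, ] <- dz %*% t(Wv)
      dh_next <- dz %*% t(Uv)
      dc_next <- dc * gF
    }
    list(dX, dW, dU, dbv)
  })
}

# bidirectional LSTM over a (B, T, d) input node; returns the per-timestep
# outputs flattened to (B*T x 2h) (rows b + (t-1)*B) plus the concatenated
# final states (B x 2h).
nn_bilstm3 <- function(tape, pn, prefix, x3, n_b, n_t, hidden) {
  fw <- ad_lstm_dir(x3, pn[[paste0(prefix, ".fw.W")]],
                    pn[[paste0(prefix, ".fw.U")]],
                    pn[[paste0(prefix, ".fw.b")]])
  bw <- ad_lstm_dir(x3, pn[[paste0(prefix, ".bw.W")]],
                    pn[[paste0(prefix, ".bw.U")]],
                    pn[[paste0(prefix, ".bw.b")]], reverse = TRUE)
  f2 <- ad_reshape(fw, c(n_b * n_t, hidden))
  b2 <- ad_reshape(bw, c(n_b * n_t, hidden))
  steps2 <- ad_concat_cols(list(f2, b2))
  fin <- ad_concat_cols(list(ad_rows(f2, (n_t - 1L) * n_b + seq_len(n_b)),
                             ad_rows(b2, seq_len(n_b))))
  list(steps2 = steps2, final = fin)
}
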