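# Minimal tape-based reverse-mode autodiff over base-R arrays.
#
# Every operation pushes a node onto a tape: the node stores the computed
# value, the ids of its parents and a vector-Jacobian-product closure.
# ad_backward walks the tape in reverse, accumulating gradients. Ops are
# coarse (whole-matrix BLAS calls), so the R-level overhead per node is
# negligible next to the linear algebra.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an empty autodiff tape
#'
#' @return An environment of class `ad_tape` holding node values, parent ids
#'   and backward closures.
#' @keywords internal
tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$vals <- vector("list", 256L)
  e$parents <- vector("list", 256L)
  e$vjps <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_node <- function(tape, value, parents = integer(0), vjp = NULL) {
  i <- tape$n + 1L
  if (i > length(tape$vals)) { # grow geometrically
    length(tape$vals) <- 2L * i
    length(tape$parents) <- 2L * i
    length(tape$vjps) <- 2L * i
  }
  tape$n <- i
  tape$vals[[i]] <- value
  tape$parents[[i]] <- parents
  if (!is.null(vjp)) tape$vjps[[i]] <- vjp
  structure(list(tape = tape, id = i), class = "ad")
}

is_ad <- function(x) inherits(x, "ad")

#' Value stored at an autodiff node
#' @keywords internal
ad_value <- function(x) x$tape$vals[[x$id]]

#' Create a leaf node (input or constant) on a tape
#' @keywords internal
ad_input <- function(tape, value) ad_node(tape, value)

ad_lift <- function(tape, x) if (is_ad(x)) x else ad_input(tape, x)

#' Reverse pass: gradients of a scalar node with respect to all tape nodes
#'
#' @param loss an `ad` node holding a scalar.
#' @return list indexed by node id; `NULL` where the node does not influence
#'   `loss`.
#' @keywords internal
ad_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq.int(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    vjp <- tape$vjps[[i]]
    if (is.null(vjp)) next
    pg <- vjp(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

# ---- elementwise and linear-algebra ops -------------------------------------

ad_matmul <- function(a, b) {
  tape <- (if (is_ad(a)) a else b)$tape
  a <- ad_lift(tape, a); b <- ad_lift(tape, b)
  A <- ad_value(a); B <- ad_value(b)
  ad_node(tape, A %*% B, c(a$id, b$id),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

# a + b where b may be: same-shape array, a length-ncol vector (row-broadcast
# bias), or a scalar.
ad_add <- function(a, b) {
  tape <- (if (is_ad(a)) a else b)$tape
  a <- ad_lift(tape, a); b <- ad_lift(tape, b)
  A <- ad_value(a); B <- ad_value(b)
  vec_b <- is.null(dim(B)) || length(dim(B)) == 1L
  if (is.matrix(A) && vec_b && length(B) == ncol(A) && length(B) > 1L) {
    val <- A + rep(as.vector(B), each = nrow(A))
    ad_node(tape, val, c(a$id, b$id),
            function(g) list(g, colSums(g)))
  } else if (vec_b && length(B) == 1L) {
    ad_node(tape, A + as.numeric(B), c(a$id, b$id),
            function(g) list(g, sum(g)))
  } else {
    stopifnot(identical(dim(A), dim(B)) || length(A) == length(B))
    ad_node(tape, A + B, c(a$id, b$id), function(g) list(g, g))
  }
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_mul <- function(a, b) {
  tape <- (if (is_ad(a)) a else b)$tape
  a <- ad_lift(tape, a); b <- ad_lift(tape, b)
  A <- ad_value(a); B <- ad_value(b)
  stopifnot(length(A) == length(B))
  ad_node(tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

# multiply each row-indexed element of matrix `a` (n x d) by vector `v`
# (length n), i.e. sweep over rows.
ad_mul_rows <- function(a, v) {
  tape <- a$tape
  v <- ad_lift(tape, v)
  A <- ad_value(a); V <- as.vector(ad_value(v))
  stopifnot(nrow(A) == length(V))
  ad_node(tape, A * V, c(a$id, v$id),
          function(g) list(g * V, rowSums(g * A)))
}

ad_scale <- function(a, s) {
  A <- ad_value(a)
  ad_node(a$tape, A * s, a$id, function(g) list(g * s))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  Y <- A; Y[Y < 0] <- 0
  ad_node(a$tape, Y, a$id, function(g) list(g * (A > 0)))
}

ad_sigmoid <- function(a) {
  S <- 1 / (1 + exp(-ad_value(a)))
  ad_node(a$tape, S, a$id, function(g) list(g * S * (1 - S)))
}

ad_tanh <- function(a) {
  T_ <- tanh(ad_value(a))
  ad_node(a$tape, T_, a$id, function(g) list(g * (1 - T_ * T_)))
}

# |x| * tanh(x); derivative |tanh(x)| + |x| * sech^2(x) >= 0 (monotone).
ad_abs_tanh <- function(a) {
  A <- ad_value(a)
  th <- tanh(A)
  ad_node(a$tape, abs(A) * th, a$id,
          function(g) list(g * (abs(th) + abs(A) * (1 - th * th))))
}

ad_softmax_rows <- function(a) {
  A <- ad_value(a)
  m <- A - apply(A, 1L, max)
  e <- exp(m)
  S <- e / rowSums(e)
  ad_node(a$tape, S, a$id,
          function(g) list(S * (g - rowSums(g * S))))
}

ad_sum <- function(a) {
  A <- ad_value(a)
  d <- dim(A)
  ad_node(a$tape, sum(A), a$id,
          function(g) list(if (is.null(d)) rep(g, length(A)) else array(g, d)))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

ad_sum_sq <- function(a) {
  A <- ad_value(a)
  ad_node(a$tape, sum(A * A), a$id, function(g) list(2 * g * A))
}

# ---- shape ops --------------------------------------------------------------

ad_reshape <- function(a, d) {
  A <- ad_value(a)
  d0 <- dim(A)
  Y <- A; dim(Y) <- d
  ad_node(a$tape, Y, a$id, function(g) { dim(g) <- d0 %||% length(A); list(g) })
}

ad_aperm <- function(a, perm) {
  A <- ad_value(a)
  inv <- order(perm)
  ad_node(a$tape, aperm(A, perm), a$id, function(g) list(aperm(g, inv)))
}

ad_cols <- function(a, idx) {
  A <- ad_value(a)
  ad_node(a$tape, A[, idx, drop = FALSE], a$id, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[, idx] <- g
    list(G)
  })
}

ad_rows <- function(a, idx) {
  A <- ad_value(a)
  ad_node(a$tape, A[idx, , drop = FALSE], a$id, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[idx, ] <- g
    list(G)
  })
}

ad_concat_cols <- function(xs) {
  tape <- xs[[1L]]$tape
  vals <- lapply(xs, ad_value)
  ncs <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncs)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tape, do.call(cbind, vals), vapply(xs, function(x) x$id, 1L),
          function(g) lapply(seq_along(xs),
                             function(j) g[, starts[j]:ends[j], drop = FALSE]))
}

# stack a list of (B x d) matrices into a (B*T x d) matrix, row index
# b + (t-1)*B  (column-major over (batch, time)).
ad_rbind <- function(xs) {
  tape <- xs[[1L]]$tape
  vals <- lapply(xs, ad_value)
  nr <- nrow(vals[[1L]])
  ad_node(tape, do.call(rbind, vals), vapply(xs, function(x) x$id, 1L),
          function(g) lapply(seq_along(xs), function(j) {
            g[(j - 1L) * nr + seq_len(nr), , drop = FALSE]
          }))
}

# slice time index t from a (B, D, T) array -> (B, D) matrix
ad_slice_time <- function(a, t) {
  A <- ad_value(a)
  d <- dim(A)
  ad_node(a$tape, A[, , t], a$id, function(g) {
    G <- array(0, d)
    G[, , t] <- g
    list(G)
  })
}

# group-sum rows of (N x d) matrix by integer `group` in 1..ngroups
ad_rowsum_group <- function(a, group, ngroups) {
  A <- ad_value(a)
  val <- rowsum(A, group = factor(group, levels = seq_len(ngroups)))
  dimnames(val) <- NULL
  ad_node(a$tape, val, a$id,
          function(g) list(g[group, , drop = FALSE]))
}

# batched matrix multiply over the first index of 3-D arrays
# a: (B, n, m); b: (B, m, p)  (or (B, p, m) with tB = TRUE) -> (B, n, p)
ad_bmm <- function(a, b, tB = FALSE) {
  tape <- a$tape
  A <- ad_value(a); B <- ad_value(b)
  nb <- dim(A)[1L]
  n <- dim(A)[2L]
  p <- if (tB) dim(B)[2L] else dim(B)[3L]
  Y <- array(0, c(nb, n, p))
  for (i in seq_len(nb)) {
    Bi <- matrix(B[i, , ], dim(B)[2L], dim(B)[3L])
    Ai <- matrix(A[i, , ], n, dim(A)[3L])
    Y[i, , ] <- if (tB) tcrossprod(Ai, Bi) else Ai %*% Bi
  }
  ad_node(tape, Y, c(a$id, b$id), function(g) {
    gA <- array(0, dim(A)); gB <- array(0, dim(B))
    for (i in seq_len(nb)) {
      Gi <- matrix(g[i, , ], n, p)
      Bi <- matrix(B[i, , ], dim(B)[2L], dim(B)[3L])
      Ai <- matrix(A[i, , ], n, dim(A)[3L])
      if (tB) {
        gA[i, , ] <- Gi %*% Bi
        gB[i, , ] <- crossprod(Gi, Ai)
      } else {
        gA[i, , ] <- tcrossprod(Gi, Bi)
        gB[i, , ] <- crossprod(Ai, Gi)
      }
    }
    list(gA, gB)
  })
}

# ---- normalization ----------------------------------------------------------

# batch norm over the rows of an (N x D) matrix (per-column statistics),
# training-mode statistics.
ad_batchnorm_cols <- function(a, gamma, beta, eps = 1e-5) {
  tape <- a$tape
  gamma <- ad_lift(tape, gamma); beta <- ad_lift(tape, beta)
  A <- ad_value(a); G <- as.vector(ad_value(gamma)); Bt <- as.vector(ad_value(beta))
  n <- nrow(A)
  mu <- colMeans(A)
  xc <- A - rep(mu, each = n)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  Y <- xhat * rep(G, each = n) + rep(Bt, each = n)
  ad_node(tape, Y, c(a$id, gamma$id, beta$id), function(g) {
    dxhat <- g * rep(G, each = n)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
      rep(istd, each = n)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# layer norm over each row of an (N x D) matrix
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  tape <- a$tape
  gamma <- ad_lift(tape, gamma); beta <- ad_lift(tape, beta)
  A <- ad_value(a); G <- as.vector(ad_value(gamma)); Bt <- as.vector(ad_value(beta))
  d <- ncol(A); n <- nrow(A)
  mu <- rowMeans(A)
  xc <- A - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- xhat * rep(G, each = n) + rep(Bt, each = n)
  ad_node(tape, Y, c(a$id, gamma$id, beta$id), function(g) {
    dxhat <- g * rep(G, each = n)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * istd
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# ---- losses -----------------------------------------------------------------

# mean cross-entropy of logits (N x K) against integer class index (1..K)
ad_cross_entropy <- function(logits, yidx) {
  L <- ad_value(logits)
  n <- nrow(L)
  m <- L - apply(L, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), yidx)]
  val <- -mean(log(pmax(picked, 1e-300)))
  ad_node(logits$tape, val, logits$id, function(g) {
    G <- p
    G[cbind(seq_len(n), yidx)] <- G[cbind(seq_len(n), yidx)] - 1
    list(g * G / n)
  })
}

# sum of hinge terms max(0, 1 - y*s); subgradient 0 at the kink.
# scores: (N x 1) node; y: numeric vector in {-1, +1}
ad_hinge_sum <- function(scores, y) {
  S <- as.vector(ad_value(scores))
  h <- pmax(0, 1 - y * S)
  act <- (1 - y * S) > 0
  ad_node(scores$tape, sum(h), scores$id,
          function(g) list(matrix(g * (-y) * act, ncol = 1L)))
}

# ---- convolution ------------------------------------------------------------

# "same"-style padding so that out = ceil(T / stride)
conv1d_geometry <- function(n_time, k, stride) {
  out <- as.integer(ceiling(n_time / stride))
  total <- max(0L, (out - 1L) * stride + k - n_time)
  list(out = out, left = total %/% 2L, right = total - total %/% 2L)
}

# 1-D convolution along time with stride, zero padding chosen so that the
# output length is ceil(T/stride).  x: (B, Din, T); w: (Dout, Din, k);
# b: length Dout.  Returns (B, Dout, To).
ad_conv1d <- function(x, w, b, stride = 2L) {
  tape <- x$tape
  w <- ad_lift(tape, w); b <- ad_lift(tape, b)
  X <- ad_value(x); W <- ad_value(w); Bv <- as.vector(ad_value(b))
  db <- dim(X)[1L]; din <- dim(X)[2L]; n_time <- dim(X)[3L]
  dout <- dim(W)[1L]; k <- dim(W)[3L]
  geo <- conv1d_geometry(n_time, k, stride)
  to <- geo$out
  tp <- n_time + geo$left + geo$right
  Xp <- array(0, c(db, din, tp))
  Xp[, , geo$left + seq_len(n_time)] <- X
  starts <- (seq_len(to) - 1L) * stride + 1L
  Xc <- matrix(0, db * to, din * k)
  for (j in seq_len(k)) {
    blk <- Xp[, , starts + j - 1L, drop = FALSE]          # (B, Din, To)
    Xc[, (j - 1L) * din + seq_len(din)] <-
      matrix(aperm(blk, c(1L, 3L, 2L)), db * to, din)
  }
  Wm <- matrix(W, dout, din * k)                          # col = d + (j-1)*Din
  Yc <- tcrossprod(Xc, Wm) + rep(Bv, each = db * to)      # (B*To, Dout)
  Y <- aperm(array(Yc, c(db, to, dout)), c(1L, 3L, 2L))   # (B, Dout, To)
  ad_node(tape, Y, c(x$id, w$id, b$id), function(g) {
    gYc <- matrix(aperm(g, c(1L, 3L, 2L)), db * to, dout)
    gW <- crossprod(gYc, Xc)                              # (Dout, Din*k)
    dim(gW) <- c(dout, din, k)
    gb <- colSums(gYc)
    gXc <- gYc %*% Wm                                     # (B*To, Din*k)
    gXp <- array(0, c(db, din, tp))
    for (j in seq_len(k)) {
      blk <- array(gXc[, (j - 1L) * din + seq_len(din)], c(db, to, din))
      gXp[, , starts + j - 1L] <- gXp[, , starts + j - 1L, drop = FALSE] +
        aperm(blk, c(1L, 3L, 2L))
    }
    list(gXp[, , geo$left + seq_len(n_time), drop = FALSE], gW, gb)
  })
}
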