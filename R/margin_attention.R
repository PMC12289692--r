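# Margin-optimized attention: attention scores are an affine function
# s_j = A . phi(x_j) + b whose parameters are trained under the soft-margin
# SVM objective, via the differentiable hinge surrogate
#   L_SVM = 1/2 ||A||^2 + C * sum_i max(0, 1 - y_i (A . phi(x_i) + b)).
# The optimized scores replace softmax similarity scores and modulate the
# value vectors; labels enter only through the auxiliary loss, never the
# scoring path, so the layer is usable at inference without labels.

#' Parameters of the margin-optimized attention layer
#'
#' @param A numeric weight vector over the feature space.
#' @param b scalar bias.
#' @param C regularization weight (> 0): trade-off between margin width and
#'   hinge violations.
#' @param lambda_aux weight of the auxiliary hinge loss in the training
#'   objective (>= 0).
#' @return list of class `margin_params`.
#' @export
margin_params <- function(A, b = 0, C = 1, lambda_aux = 0.1) {
  if (C <= 0) stop("C must be positive")
  if (lambda_aux < 0) stop("lambda_aux must be non-negative")
  structure(list(A = as.numeric(A), b = as.numeric(b)[1L], C = C,
                 lambda_aux = lambda_aux),
            class = "margin_params")
}

check_labels <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  as.numeric(y)
}

#' Scaled dot-product softmax attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` — the conventional
#' similarity-based scoring that the margin-optimized layer replaces.
#'
#' @param Q queries, `n_q x d_k`.
#' @param K keys, `n x d_k`.
#' @param V values, `n x d_v`.
#' @return list with `weights` (`n_q x n`, rows on the simplex) and
#'   `context` (`n_q x d_v`).
#' @export
softmax_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d_k <- ncol(K)
  if (d_k < 1L) stop("key dimension must be positive")
  if (ncol(Q) != d_k) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  S <- Q %*% t(K) / sqrt(d_k)
  S <- S - apply(S, 1L, max)
  W <- exp(S)
  W <- W / rowSums(W)
  list(weights = W, context = W %*% V)
}

#' Hinge surrogate of the soft-margin objective
#'
#' Exact evaluation of
#' `1/2 ||A||^2 + C * sum_i max(0, 1 - y_i (A . phi_i + b))`,
#' together with the per-sample margins and hinge terms (the slack
#' surrogates).
#'
#' @param params a [margin_params()].
#' @param phi feature matrix, `n x d`.
#' @param y labels in \{-1, +1\}, length `n`.
#' @return list with `loss`, `margins`, `hinge_terms`.
#' @export
hinge_objective <- function(params, phi, y) {
  phi <- as.matrix(phi)
  y <- check_labels(y)
  if (ncol(phi) != length(params$A)) stop("dimension mismatch between A and phi")
  margins <- y * (as.vector(phi %*% params$A) + params$b)
  hinge <- pmax(0, 1 - margins)
  list(loss = 0.5 * sum(params$A^2) + params$C * sum(hinge),
       margins = margins, hinge_terms = hinge)
}

#' Analytic (sub)gradient of the hinge surrogate
#'
#' Subgradient 0 is chosen at the hinge kink, matching the `max(0, .)`
#' autodiff convention.
#'
#' @inheritParams hinge_objective
#' @return list with `A` (length d) and `b` (scalar).
#' @export
hinge_gradient <- function(params, phi, y) {
  phi <- as.matrix(phi)
  y <- check_labels(y)
  margins <- y * (as.vector(phi %*% params$A) + params$b)
  act <- (1 - margins) > 0
  gA <- params$A - params$C * colSums(phi[act, , drop = FALSE] * y[act])
  gb <- -params$C * sum(y[act])
  list(A = as.numeric(gA), b = gb)
}

#' Minimize the hinge surrogate by gradient descent
#'
#' Full-batch Adam on the convex surrogate with a step-decayed learning
#' rate, followed (by default) by a numerical polish: BFGS on a softplus
#' smoothing of the hinge whose temperature is driven towards zero, warm
#' started from the Adam iterate. The polish removes the residual
#' oscillation of first-order steps around the hinge kinks; no
#' quadratic-programming solver is involved at any point.
#'
#' @param phi feature matrix `n x d`.
#' @param y labels in \{-1, +1\}.
#' @param C regularization weight.
#' @param iters Adam iterations.
#' @param lr initial learning rate.
#' @param init optional [margin_params()] starting point.
#' @param polish run the smoothed-objective refinement (default `TRUE`).
#' @return the optimized [margin_params()], with attribute `history`
#'   (loss trace, every 50 Adam iterations).
#' @export
fit_margin_params <- function(phi, y, C = 1, iters = 2000L, lr = 0.1,
                              init = NULL, polish = TRUE) {
  phi <- as.matrix(phi)
  y <- check_labels(y)
  d <- ncol(phi)
  p <- init %||% margin_params(numeric(d), 0, C = C)
  p$C <- C
  th <- c(p$A, p$b)
  m <- v <- numeric(d + 1L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- numeric(0)
  best <- th; best_loss <- Inf
  for (t in seq_len(iters)) {
    pp <- margin_params(th[seq_len(d)], th[d + 1L], C = C)
    g <- hinge_gradient(pp, phi, y)
    gv <- c(g$A, g$b)
    m <- b1 * m + (1 - b1) * gv
    v <- b2 * v + (1 - b2) * gv * gv
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    step <- lr * 0.5^((t - 1) %/% (iters / 8))   # halve lr 8 times
    th <- th - step * mh / (sqrt(vh) + eps)
    if (t %% 50 == 0 || t == iters) {
      l <- hinge_objective(pp, phi, y)$loss
      hist <- c(hist, l)
      if (l < best_loss) { best_loss <- l; best <- c(pp$A, pp$b) }
    }
  }
  if (polish) {
    # softplus_tau(1 - m) -> hinge as tau -> 0; each stage is smooth, so
    # BFGS converges tightly; warm starts keep the homotopy cheap.
    smooth_obj <- function(tau) {
      list(fn = function(th) {
        mar <- y * (as.vector(phi %*% th[seq_len(d)]) + th[d + 1L])
        z <- (1 - mar) / tau
        sp <- tau * ifelse(z > 30, z, log1p(exp(z)))
        0.5 * sum(th[seq_len(d)]^2) + C * sum(sp)
      }, gr = function(th) {
        mar <- y * (as.vector(phi %*% th[seq_len(d)]) + th[d + 1L])
        sig <- 1 / (1 + exp(-(1 - mar) / tau))
        gA <- th[seq_len(d)] - C * colSums(phi * (y * sig))
        c(gA, -C * sum(y * sig))
      })
    }
    for (tau in 10^seq(-1, -6)) {
      ob <- smooth_obj(tau)
      opt <- stats::optim(best, ob$fn, ob$gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      best <- opt$par
    }
    l <- hinge_objective(margin_params(best[seq_len(d)], best[d + 1L], C = C),
                         phi, y)$loss
    hist <- c(hist, l)
  }
  pf <- margin_params(best[seq_len(d)], best[d + 1L], C = C,
                      lambda_aux = p$lambda_aux)
  attr(pf, "history") <- hist
  pf
}

#' Margin scores of feature vectors
#'
#' `score_j = A . phi_j + b`; label-free, usable at inference time.
#'
#' @param params a [margin_params()].
#' @param phi feature matrix `n x d`.
#' @return numeric vector of length `n`.
#' @export
margin_scores <- function(params, phi) {
  phi <- as.matrix(phi)
  if (ncol(phi) != length(params$A)) stop("dimension mismatch between A and phi")
  as.vector(phi %*% params$A) + params$b
}

normalize_scores <- function(s, normalization) {
  if (normalization == "softmax") {
    e <- exp(s - max(s))
    e / sum(e)
  } else {                      # clip-at-zero and renormalize
    w <- pmax(s, 0)
    if (sum(w) <= 0) rep(1 / length(s), length(s)) else w / sum(w)
  }
}

#' Margin-optimized attention forward pass
#'
#' Keys serve as the feature representations phi; margin scores over the key
#' positions are normalized to a distribution (softmax of margins by
#' default) and modulate the values. In training mode (labels supplied) the
#' auxiliary loss is the hinge surrogate evaluated on the attention-pooled
#' feature with the trial label; at inference it is exactly 0.
#'
#' @param inp list with `Q` (`n_q x d_k`), `K` (`n x d_k`), `V` (`n x d_v`).
#'   `Q` only sets the number of output rows: margin scores are per-key, so
#'   every query row receives the same weight distribution.
#' @param params a [margin_params()] with `A` of length `d_k`.
#' @param labels optional scalar trial label in \{-1, +1\} (or length-1
#'   vector); anything else is an error.
#' @param normalization `"softmax"` or `"clip"`.
#' @return list with `weights` (`n_q x n`), `context` (`n_q x d_v`),
#'   `aux_loss`.
#' @export
margin_attention_forward <- function(inp, params, labels = NULL,
                                     normalization = c("softmax", "clip")) {
  normalization <- match.arg(normalization)
  K <- as.matrix(inp$K); V <- as.matrix(inp$V)
  n_q <- if (!is.null(inp$Q)) nrow(as.matrix(inp$Q)) else 1L
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  s <- margin_scores(params, K)
  w <- normalize_scores(s, normalization)
  weights <- matrix(w, n_q, length(w), byrow = TRUE)
  context <- weights %*% V
  aux <- 0
  if (!is.null(labels)) {
    if (length(labels) != 1L)
      stop("labels must be a single trial label in {-1, +1}")
    check_labels(labels)
    phi_pool <- matrix(w, 1L) %*% K        # attention-pooled feature
    aux <- hinge_objective(params, phi_pool, labels)$loss
  }
  list(weights = weights, context = context, aux_loss = aux)
}

#' Combined training loss
#'
#' `ce_loss + lambda_aux * aux_loss` — cross-entropy plus the weighted
#' auxiliary hinge surrogate.
#'
#' @param ce_loss scalar cross-entropy loss.
#' @param aux_loss scalar auxiliary hinge loss.
#' @param lambda_aux non-negative weight.
#' @return scalar.
#' @export
total_loss <- function(ce_loss, aux_loss, lambda_aux) {
  if (lambda_aux < 0) stop("lambda_aux must be non-negative")
  ce_loss + lambda_aux * aux_loss
}
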