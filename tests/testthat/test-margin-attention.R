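# The margin-optimized attention layer: exact hinge evaluation, gradient
# correctness, convergence of the surrogate minimizer to the quadratic-
# programming optimum, and the attention forward contract.

test_that("softmax attention satisfies its closed-form cases", {
  # single key: weight exactly 1 and context = V
  out <- softmax_attention(matrix(1, 1, 2), matrix(c(3, -1), 1, 2),
                           matrix(c(5, 7), 1, 2))
  expect_equal(out$weights, matrix(1, 1, 1))
  expect_equal(out$context, matrix(c(5, 7), 1, 2))
  # equal dot products: uniform weights
  K <- matrix(1, 4, 2)
  out <- softmax_attention(matrix(c(1, 1), 1, 2), K, matrix(rnorm(8), 4, 2))
  expect_equal(as.vector(out$weights), rep(0.25, 4))
  # two keys with logits (1, 0) at d_k = 1: weights (e, 1)/(e + 1)
  out <- softmax_attention(matrix(1, 1, 1), matrix(c(1, 0), 2, 1),
                           matrix(c(10, 20), 2, 1))
  expect_equal(as.vector(out$weights),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # rows always on the simplex
  out <- softmax_attention(matrix(rnorm(6), 3, 2), matrix(rnorm(10), 5, 2),
                           matrix(rnorm(15), 5, 3))
  expect_true(all(out$weights >= 0))
  expect_equal(rowSums(out$weights), rep(1, 3))
  expect_error(softmax_attention(matrix(1, 1, 2), matrix(1, 2, 2),
                                 matrix(1, 3, 1)), "same number of rows")
})

test_that("hinge objective reproduces hand-computed values", {
  # zero parameters: every hinge term is 1
  p0 <- margin_params(c(0, 0), 0)
  r0 <- hinge_objective(p0, matrix(rnorm(8), 4, 2), c(-1, 1, -1, 1))
  expect_equal(r0$loss, 4)
  expect_equal(r0$hinge_terms, rep(1, 4))
  # satisfied margins: loss is the regularizer alone
  p1 <- margin_params(1, 0)
  r1 <- hinge_objective(p1, matrix(c(2, -2), 2, 1), c(1, -1))
  expect_equal(r1$margins, c(2, 2))
  expect_equal(r1$loss, 0.5)
  expect_equal(r1$hinge_terms, c(0, 0))
  expect_error(hinge_objective(p1, matrix(c(2, -2), 2, 1), c(1, 0)),
               "labels")
})

test_that("analytic hinge gradients match central finite differences", {
  set.seed(21)
  for (rep in 1:8) {
    inst <- random_hinge_instance()
    th0 <- rnorm(inst$d + 1L)
    p <- margin_params(th0[seq_len(inst$d)], th0[inst$d + 1L], C = 0.7)
    g <- hinge_gradient(p, inst$phi, inst$y)
    fn <- function(th) hinge_objective(
      margin_params(th[seq_len(inst$d)], th[inst$d + 1L], C = 0.7),
      inst$phi, inst$y)$loss
    ng <- num_grad(fn, th0, eps = 1e-6)
    expect_lt(max(abs(c(g$A, g$b) - ng)) / max(abs(ng)), 1e-5)
  }
})

test_that("the gradient-descent minimum matches the interior-point QP optimum", {
  skip_if_not_installed("kernlab")
  set.seed(42)
  diffs <- replicate(20, {
    inst <- random_hinge_instance()
    C <- sample(c(0.3, 1, 3), 1L)
    fit <- fit_margin_params(inst$phi, inst$y, C = C)
    abs(hinge_objective(fit, inst$phi, inst$y)$loss -
          qp_hinge_optimum(inst$phi, inst$y, C))
  })
  expect_lt(max(diffs), 1e-4)
})

test_that("the hinge surrogate is convex in (A, b)", {
  set.seed(31)
  for (rep in 1:20) {
    inst <- random_hinge_instance()
    th1 <- rnorm(inst$d + 1L, sd = 2)
    th2 <- rnorm(inst$d + 1L, sd = 2)
    lam <- runif(1)
    thm <- lam * th1 + (1 - lam) * th2
    f <- function(th) hinge_objective(
      margin_params(th[seq_len(inst$d)], th[inst$d + 1L]), inst$phi, inst$y)$loss
    expect_lte(f(thm), lam * f(th1) + (1 - lam) * f(th2) + 1e-10)
  }
})

test_that("optimized total slack is non-increasing in C", {
  set.seed(33)
  inst <- random_hinge_instance(n = 16L, d = 2L)
  slack <- vapply(c(0.1, 0.3, 1, 3, 10, 30), function(C) {
    fit <- fit_margin_params(inst$phi, inst$y, C = C)
    sum(hinge_objective(fit, inst$phi, inst$y)$hinge_terms)
  }, 1)
  expect_true(all(diff(slack) <= 1e-6))
})

test_that("margin scores are affine, label-free and permutation-equivariant", {
  p <- margin_params(c(2, -1), 0.5)
  phi <- matrix(rnorm(10), 5, 2)
  s <- margin_scores(p, phi)
  expect_equal(s, as.vector(phi %*% c(2, -1)) + 0.5)
  expect_equal(margin_scores(margin_params(c(0, 0), 0), phi), rep(0, 5))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(margin_scores(p, phi[perm, ]), s[perm])
})

test_that("on a separable instance the optimized scores sign-match the labels", {
  set.seed(35)
  w <- c(1, 1) / sqrt(2)
  phi <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2) + 1.5 * matrix(w, 10, 2, byrow = TRUE),
               matrix(rnorm(20, 0, 0.2), 10, 2) - 1.5 * matrix(w, 10, 2, byrow = TRUE))
  y <- rep(c(1, -1), each = 10L)
  fit <- fit_margin_params(phi, y, C = 10)
  expect_equal(sign(margin_scores(fit, phi)), y)
})

test_that("optimized weights align with a planted separating direction", {
  # separable 2-D features whose closest points (planted support vectors at
  # +-w) make the planted normal exactly the max-margin direction; at large
  # C the optimizer must recover it within 10 degrees, across 10 seeds
  angles <- vapply(1:10, function(sd) {
    set.seed(400 + sd)
    theta <- runif(1, 0, 2 * pi)
    w <- c(cos(theta), sin(theta))
    wp <- c(-w[2L], w[1L])
    n_bg <- 30L
    u <- runif(n_bg, 1.3, 3)                 # along-margin distances > 1
    o <- runif(n_bg, -1, 1)                  # orthogonal jitter
    yb <- rep(c(1, -1), length.out = n_bg)
    phi <- rbind(w, -w, outer(yb * u, w) + outer(o, wp))
    y <- c(1, -1, yb)
    fit <- fit_margin_params(phi, y, C = 100)
    a <- fit$A / sqrt(sum(fit$A^2))
    acos(pmin(1, abs(sum(a * w)))) * 180 / pi
  }, 1)
  expect_lt(max(angles), 10)
})

test_that("attention forward: normalization, trivial cases, inference aux", {
  set.seed(37)
  K <- matrix(rnorm(12), 6, 2)
  V <- matrix(rnorm(18), 6, 3)
  inp <- list(Q = matrix(0, 2, 2), K = K, V = V)
  # zero parameters: uniform weights, context = mean of V
  p0 <- margin_params(c(0, 0), 0)
  out0 <- margin_attention_forward(inp, p0)
  expect_equal(out0$weights, matrix(1 / 6, 2, 6))
  expect_equal(out0$context[1L, ], colMeans(V))
  expect_identical(out0$aux_loss, 0)             # inference mode: exactly 0
  # training mode: aux equals the hinge objective on the pooled feature
  p <- margin_params(c(1, -0.5), 0.2, C = 2)
  out <- margin_attention_forward(inp, p, labels = 1)
  w <- out$weights[1L, ]
  expect_equal(rowSums(out$weights), c(1, 1))
  pooled <- matrix(w, 1) %*% K
  expect_equal(out$aux_loss, hinge_objective(p, pooled, 1)$loss)
  expect_error(margin_attention_forward(inp, p, labels = c(1, -1)), "single")
  # clip normalization also lands on the simplex
  outc <- margin_attention_forward(inp, p, normalization = "clip")
  expect_true(all(outc$weights >= 0))
  expect_equal(rowSums(outc$weights), c(1, 1))
})

test_that("total loss combines cross-entropy and the auxiliary hinge", {
  expect_equal(total_loss(1.0, 2.0, 0.5), 2.0)
  expect_equal(total_loss(0.3, 99, 0), 0.3)
  expect_error(total_loss(1, 1, -0.1), "non-negative")
})

test_that("hinge training of attention plus features raises Fisher separation", {
  # the auxiliary hinge backpropagates into the feature projection as well
  # as the attention scores (as in the full model, where it is part of the
  # computational graph); on two-cluster key sequences the pooled contexts
  # separate further on average across seeds
  ad <- function(name) get(name, envir = asNamespace("marginattn"))
  gains <- vapply(1:10, function(sd) {
    set.seed(500 + sd)
    n_b <- 40L; n_t <- 6L; d <- 4L
    y <- rep(c(-1, 1), each = n_b / 2L)
    dir <- rnorm(d); dir <- dir / sqrt(sum(dir^2))
    k2 <- matrix(rnorm(n_b * n_t * d, 0, 1), n_b * n_t, d) +
      outer(rep(y, n_t), dir)
    params <- list(A = matrix(rnorm(d, 0, 0.1), d, 1L), b = 0,
                   P = diag(d) + matrix(rnorm(d * d, 0, 0.05), d, d))
    sep_of <- function(params) {
      tape <- ad("tape_new")()
      pn <- ad("lift_params")(tape, params)
      phi <- ad("ad_matmul")(ad("ad_input")(tape, k2), pn$P)
      at <- ad("nn_margin_attn")(tape, pn, "", phi, n_b, n_t, y = NULL)
      class_separation(ad("ad_value")(at$context), y)
    }
    s0 <- sep_of(params)
    opt <- ad("adamw_new")(params)
    for (it in 1:400) {
      tape <- ad("tape_new")()
      pn <- ad("lift_params")(tape, params)
      phi <- ad("ad_matmul")(ad("ad_input")(tape, k2), pn$P)
      at <- ad("nn_margin_attn")(tape, pn, "", phi, n_b, n_t, y = y, C = 1)
      grads_all <- ad("ad_backward")(at$aux)
      grads <- lapply(pn, function(nd) grads_all[[nd$id]])
      st <- ad("adamw_step")(opt, params, grads, lr = 0.03, weight_decay = 0)
      opt <- st$opt; params <- st$params
    }
    sep_of(params) - s0
  }, 1)
  expect_gt(mean(gains), 0)
  expect_gte(sum(gains > 0), 7L)
})
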