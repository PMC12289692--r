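# Depth progression, shape arithmetic, forward-shape agreement, the
# abs(x)*tanh(x) activation, and a learning smoke test on synthetic data.

test_that("algebraic depth progression matches the studied configurations", {
  expect_equal(depth_progression(64, 6, 2), c(128L, 192L, 256L, 320L, 384L, 448L))
  expect_equal(depth_progression(3, 5, 1), c(3L, 6L, 9L, 12L, 15L))
  expect_equal(depth_progression(1, 1, 1), 1L)
  expect_equal(depth_progression(22, 5, 1), c(22L, 44L, 66L, 88L, 110L))
  expect_error(depth_progression(0, 3, 1), ">= 1")
})

test_that("shape trace halves time with ceiling and multiplies out flattened sizes", {
  cfg <- backbone_config(8, n_layers = 3L, kernel = 8L, input_time = 50L)
  st <- shape_trace(cfg)
  expect_equal(st$time, c(25L, 13L, 7L))
  expect_equal(st$depth, c(8L, 16L, 24L))
  expect_equal(st$flattened, st$depth * st$time)
  # single layer: ceil(10/2) = 5
  cfg1 <- backbone_config(2, n_layers = 1L, kernel = 8L, input_time = 10L)
  expect_equal(shape_trace(cfg1)$time, 5L)
  expect_error(shape_trace(backbone_config(2, n_layers = 4L, kernel = 8L,
                                           input_time = 8L)), "too short")
})

test_that("forward tensor shapes agree with shape_trace for all kernels and modes", {
  set.seed(61)
  x <- array(rnorm(4 * 6 * 40), c(4, 6, 40))
  for (k in c(8L, 24L, 40L)) {
    for (mode in c("collapsed", "preserved")) {
      cfg <- backbone_config(6, n_layers = 2L, kernel = k, spatial_mode = mode,
                             lstm_hidden = 6L, input_time = 40L, head_hidden = 6L)
      st <- shape_trace(cfg)
      m <- build_backbone(cfg)
      tape <- marginattn:::tape_new()
      pn <- marginattn:::lift_params(tape, m$params)
      hc <- marginattn:::nn_conv_stack(tape, pn, cfg$n_layers,
                                       marginattn:::ad_input(tape, if (mode == "collapsed") x else {
                                         x2 <- x; dim(x2) <- c(4 * 6, 1, 40); x2
                                       }), 2L, cfg$batch_norm)
      d <- dim(marginattn:::ad_value(hc))
      expect_equal(d[2L], st$depth[2L])
      expect_equal(d[3L], st$time[2L])
      fw <- m$forward(tape, pn, x)
      expect_equal(dim(marginattn:::ad_value(fw$logits)), c(4L, 2L))
      expect_true(all(is.finite(marginattn:::ad_value(fw$logits))))
    }
  }
})

test_that("LSTM input dimension is depth (collapsed) or depth x channels (preserved)", {
  cc <- backbone_config(64, n_layers = 6L, depth_start_multiplier = 2L,
                        input_time = 180L)
  cp <- backbone_config(64, spatial_mode = "preserved", depths = 8 * 2^(0:5),
                        input_time = 180L)
  expect_equal(lstm_input_dim(cc), 448L)
  expect_equal(lstm_input_dim(cp), 16384L)
})

test_that("flattened size is non-increasing across layers in the collapsed reference", {
  st <- shape_trace(backbone_config(64, n_layers = 6L,
                                    depth_start_multiplier = 2L,
                                    input_time = 180L))
  expect_true(all(diff(st$flattened) <= 0))
})

test_that("abs_tanh is odd, monotone, and matches tanh at the unit point", {
  expect_equal(abs_tanh(0), 0)
  expect_equal(abs_tanh(1), tanh(1))
  g <- seq(-5, 5, by = 0.01)
  expect_equal(abs_tanh(-g), -abs_tanh(g))
  expect_true(all(diff(abs_tanh(g)) >= 0))
  # derivative |tanh| + |x| sech^2 is non-negative on a grid
  d <- abs(tanh(g)) + abs(g) * (1 - tanh(g)^2)
  expect_true(all(d >= 0))
})

test_that("a forward pass of zeros yields finite logits", {
  set.seed(62)
  cfg <- backbone_config(4, n_layers = 2L, kernel = 8L, lstm_hidden = 6L,
                         input_time = 32L, attention = "svm_margin",
                         head_hidden = 6L)
  m <- build_backbone(cfg)
  tape <- marginattn:::tape_new()
  pn <- marginattn:::lift_params(tape, m$params)
  fw <- m$forward(tape, pn, array(0, c(3, 4, 32)))
  expect_true(all(is.finite(marginattn:::ad_value(fw$logits))))
  expect_equal(dim(marginattn:::ad_value(fw$logits)), c(3L, 2L))
})

test_that("whole-model analytic gradients match finite differences", {
  set.seed(63)
  cfg <- backbone_config(3, n_layers = 2L, kernel = 5L, lstm_hidden = 4L,
                         input_time = 16L, attention = "svm_margin",
                         head_hidden = 4L)
  m <- build_backbone(cfg)
  x <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  y <- c(-1, 1, 1, -1)
  lossval <- function(params) {
    tape <- marginattn:::tape_new()
    pn <- marginattn:::lift_params(tape, params)
    ml <- marginattn:::model_loss(list(cfg = cfg, forward = m$forward,
                                       lambda_aux = 0.1, params = params),
                                  x, y, pn, tape)
    marginattn:::ad_value(ml$loss)
  }
  tape <- marginattn:::tape_new()
  pn <- marginattn:::lift_params(tape, m$params)
  ml <- marginattn:::model_loss(m, x, y, pn, tape)
  ga <- marginattn:::ad_backward(ml$loss)
  worst <- 0
  for (k in names(m$params)) {
    g <- ga[[pn[[k]]$id]]
    pick <- sample(length(m$params[[k]]), min(3L, length(m$params[[k]])))
    for (i in pick) {
      eps <- 1e-5
      pp <- m$params; pp[[k]][i] <- pp[[k]][i] + eps
      pm <- m$params; pm[[k]][i] <- pm[[k]][i] - eps
      nd <- (lossval(pp) - lossval(pm)) / (2 * eps)
      worst <- max(worst, abs(g[i] - nd) / max(1e-6, abs(nd), abs(g[i])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the backbone learns within-subject motor imagery above 85 percent", {
  cfg_s <- synth_config(n_subjects = 8L, n_trials_per_subject = 200L,
                        erd_factor = 0.3, seed = 11L)
  rec <- generate_recording(cfg_s, 1L)
  ep <- prepare_input(preprocess_recording(rec)$epochs, 180L)
  sp <- split_spec(ep$labels, c(0.70, 0.15, 0.15), seed = 1L)
  set.seed(3)
  cfg <- backbone_config(dim(ep$data)[2L], n_layers = 3L, kernel = 24L,
                         lstm_hidden = 24L, input_time = 180L,
                         attention = "svm_margin")
  m <- build_backbone(cfg)
  m <- train_model(m, ep$data[sp$train, , , drop = FALSE], ep$labels[sp$train],
                   ep$data[sp$validation, , , drop = FALSE],
                   ep$labels[sp$validation],
                   epochs = 15L, batch_size = 64L, lr = 2e-3, patience = 5L,
                   seed = 1L)
  expect_gt(max(attr(m, "history")$val_acc), 0.85)
})

test_that("softmax-normalized margin attention with zero auxiliary weight still converges", {
  ep <- small_epochs()
  sp <- split_spec(ep$labels, c(0.70, 0.30, 0), seed = 2L)
  set.seed(5)
  cfg <- backbone_config(dim(ep$data)[2L], n_layers = 3L, kernel = 8L,
                         lstm_hidden = 12L, input_time = 180L,
                         attention = "svm_margin", lambda_aux = 0)
  m <- build_backbone(cfg)
  m <- train_model(m, ep$data[sp$train, , , drop = FALSE], ep$labels[sp$train],
                   ep$data[sp$validation, , , drop = FALSE],
                   ep$labels[sp$validation], epochs = 8L, batch_size = 32L,
                   lr = 2e-3, patience = 8L, seed = 1L)
  h <- attr(m, "history")
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
  expect_gt(max(h$val_acc), 0.7)
})
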