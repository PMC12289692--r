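# LOSO folds, metrics, Fisher separation, one-way ANOVA, and heatmap export.

test_that("LOSO folds cover every subject exactly once and never leak", {
  folds <- loso_folds(c(3, 1, 2))
  expect_length(folds, 3L)
  expect_equal(vapply(folds, function(f) f$test_subject, 1), c(1, 2, 3))
  for (f in folds) {
    expect_length(f$train_subjects, 2L)
    expect_false(f$test_subject %in% f$train_subjects)
  }
  expect_error(loso_folds(1L), "at least 2")
  # fuzz: random subject lists
  set.seed(81)
  for (rep in 1:20) {
    ids <- sample(100L, sample(2:12, 1L))
    folds <- loso_folds(ids)
    tests <- vapply(folds, function(f) f$test_subject, 1)
    expect_setequal(tests, ids)
    expect_equal(anyDuplicated(tests), 0L)
    for (f in folds) {
      expect_setequal(c(f$test_subject, f$train_subjects), ids)
      expect_length(intersect(f$test_subject, f$train_subjects), 0L)
    }
  }
})

test_that("classification metrics match direct formula evaluation", {
  # perfect prediction
  m <- classification_metrics(c(-1, 1, 1, -1), c(-1, 1, 1, -1))
  expect_equal(c(m$accuracy, m$f1, m$sensitivity), c(1, 1, 1))
  # TP=3 FN=1 FP=1 TN=5
  y_true <- c(rep(1, 4), rep(-1, 6))
  y_pred <- c(1, 1, 1, -1, 1, rep(-1, 5))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  # all-positive predictor on balanced data
  m <- classification_metrics(rep(c(1, -1), 5), rep(1, 10))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$accuracy, 0.5)
  # degenerate denominators warn (sensitivity, precision, F1) and return 0
  w <- capture_warnings(m0 <- classification_metrics(rep(-1, 4), rep(-1, 4)))
  expect_length(w, 3L)
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(m0$sensitivity, 0)
  # accuracy from the confusion matrix equals mean-correct
  expect_equal(sum(diag(m0$confusion)) / sum(m0$confusion), 1)
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
  expect_error(classification_metrics(c(1, 0), c(1, 1)), "labels")
})

test_that("Fisher separation matches closed forms and is rotation invariant", {
  # 1-D classes with means +-1, variance 1 each: J = 4 / 2
  set.seed(82)
  n <- 4000L
  xp <- rnorm(n, 1); xm <- rnorm(n, -1)
  feats <- matrix(c(xp, xm), ncol = 1L)
  y <- rep(c(1, -1), each = n)
  expect_equal(class_separation(feats, y), 2, tolerance = 0.1)
  # identical class means: 0
  f0 <- matrix(c(1, 1, 2, 2), 4, 2)
  expect_equal(class_separation(f0, c(1, -1, 1, -1)), 0)
  # invariance under a common rotation
  f2 <- matrix(rnorm(200), 100, 2)
  f2[1:50, 1] <- f2[1:50, 1] + 3
  y2 <- rep(c(1, -1), each = 50)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(class_separation(f2 %*% R, y2), class_separation(f2, y2),
               tolerance = 1e-12)
  expect_error(class_separation(f2, rep(1, 100)), "both classes")
})

test_that("one-way ANOVA matches a direct sum-of-squares computation", {
  groups <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  res <- one_way_anova(groups)
  # independent oracle: explicit SS_between / SS_within
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1L
  dfw <- length(all_v) - length(groups)
  f_oracle <- (ssb / dfb) / (ssw / dfw)
  expect_equal(res$F, f_oracle, tolerance = 1e-6)
  expect_equal(res$p, stats::pf(f_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-9)
  # degenerate: identical constants -> NaN with a warning
  expect_warning(r0 <- one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_true(is.nan(r0$F))
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 2)), ">= 2 values")
})

test_that("ANOVA p-values are uniform under random group assignment", {
  set.seed(83)
  vals <- rnorm(15)
  ps <- replicate(200, {
    g <- sample(rep(1:3, each = 5))
    one_way_anova(split(vals, g))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("attention heatmaps render; one-hot weights light a single band", {
  skip_if_not_installed("png")
  dir <- withr::local_tempdir()
  # uniform weights: constant-colour payload
  wu <- matrix(1 / 8, 12, 8)
  fu <- file.path(dir, "uniform.png")
  attention_heatmap(wu, fu)
  expect_true(file.exists(fu) && file.size(fu) > 0)
  crop <- function(path) {
    img <- png::readPNG(path)
    h <- dim(img)[1L]; w <- dim(img)[2L]
    img[round(h * 0.15):round(h * 0.82), round(w * 0.12):round(w * 0.76), 1:3]
  }
  cu <- crop(fu)
  # constant-colour payload: every channel is flat inside the panel
  expect_lt(max(apply(cu, 3L, stats::sd)), 1e-6)
  # one-hot on the last key: bright band on the right side of the panel
  w1 <- matrix(0, 12, 8); w1[, 8] <- 1
  f1 <- file.path(dir, "onehot_right.png")
  attention_heatmap(w1, f1)
  c1 <- crop(f1)
  expect_gt(max(apply(c1, 3L, stats::sd)), 0.05)
  lum <- apply(c1, 2L, mean)
  nl <- length(lum)
  expect_gt(mean(lum[round(nl * 0.9):nl]), mean(lum[1:round(nl * 0.1)]) + 0.2)
  # and on the first key: bright band on the left
  w2 <- matrix(0, 12, 8); w2[, 1] <- 1
  f2 <- file.path(dir, "onehot_left.png")
  attention_heatmap(w2, f2)
  c2 <- crop(f2)
  lum2 <- apply(c2, 2L, mean)
  expect_gt(mean(lum2[1:round(nl * 0.1)]), mean(lum2[round(nl * 0.9):nl]) + 0.2)
  expect_error(attention_heatmap(matrix(1, 2, 3), tempfile()), "sum to 1")
})

test_that("pooled epochs preserve labels and subject assignment", {
  cfg <- synth_config(n_subjects = 2L, n_trials_per_subject = 10L, seed = 84L)
  eps <- prepare_dataset(generate_dataset(cfg))
  pool <- pool_epochs(eps)
  expect_equal(dim(pool$x)[1L], length(pool$y))
  expect_equal(length(pool$y), length(pool$subject))
  expect_setequal(unique(pool$subject), c(1L, 2L))
  n1 <- sum(pool$subject == 1L)
  expect_equal(pool$x[seq_len(n1), , ], eps[[1L]]$data)
  expect_equal(pool$y[pool$subject == 2L], eps[[2L]]$labels)
})

test_that("split_spec is stratified and partitions all trials", {
  y <- rep(c(-1, 1), each = 50)
  sp <- split_spec(y, c(0.70, 0.15, 0.15), seed = 4L)
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_along(y))
  expect_equal(sum(y[sp$train] == 1), 35L)
  expect_equal(sum(y[sp$validation] == 1), 8L, tolerance = 1)
  expect_error(split_spec(y, c(0.5, 0.5, 0.5)), "sum to 1")
})
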