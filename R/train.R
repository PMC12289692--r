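# Training loop: AdamW (decoupled weight decay) with metric-based early
# stopping. The best validation checkpoint is tracked (initialized to
# -infinity for maximized metrics) and restored at the end.

adamw_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

# decoupled weight decay on weight matrices/kernels only (names ending .W*,
# attention projections), not biases or normalization gains
adamw_step <- function(opt, params, grads, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  decay_mask <- grepl("\\.(W[a-z]?|U|A|u)$", names(params))
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    mh <- opt$m[[k]] / (1 - beta1^opt$t)
    vh <- opt$v[[k]] / (1 - beta2^opt$t)
    upd <- mh / (sqrt(vh) + eps)
    if (decay_mask[match(k, names(params))])
      upd <- upd + weight_decay * params[[k]]
    params[[k]] <- params[[k]] - lr * upd
  }
  list(opt = opt, params = params)
}

model_loss <- function(model, x, y, pn, tape) {
  fw <- model$forward(tape, pn, x, y)
  yidx <- ifelse(y > 0, 2L, 1L)
  ce <- ad_cross_entropy(fw$logits, yidx)
  loss <- ce
  if (!is.null(fw$aux) && model$lambda_aux > 0)
    loss <- ad_add(ce, ad_scale(fw$aux, model$lambda_aux / length(y)))
  list(loss = loss, ce = ce, fw = fw)
}

#' Forward pass without gradients
#'
#' @param model an `mi_model`.
#' @param x input array (trials x channels x samples).
#' @param batch_size evaluation batch size.
#' @return list with `logits` (n x 2), `pred` labels in \{-1, +1\} (ties
#'   broken toward the negative class), `feat` pooled feature matrix, and
#'   `attn` attention weights (n x timesteps) when the model has a scoring
#'   attention layer.
#' @export
predict_model <- function(model, x, batch_size = 512L) {
  n <- dim(x)[1L]
  logits <- NULL; feat <- NULL; attn <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    tape <- tape_new()
    pn <- lift_params(tape, model$params)
    fw <- model$forward(tape, pn, x[idx, , , drop = FALSE], y = NULL)
    logits <- rbind(logits, ad_value(fw$logits))
    feat <- rbind(feat, ad_value(fw$feat))
    if (!is.null(fw$attn)) attn <- rbind(attn, ad_value(fw$attn))
  }
  pred <- ifelse(logits[, 2L] > logits[, 1L], 1, -1)  # tie -> negative class
  list(logits = logits, pred = pred, feat = feat, attn = attn)
}

#' Train a model with AdamW and early stopping
#'
#' Minimizes cross-entropy plus `lambda_aux / batch` times the auxiliary
#' hinge objective (for margin attention). Tracks validation accuracy each
#' epoch; stops after `patience` epochs without improvement and restores the
#' best parameters. With `patience = 0` training stops at the first
#' non-improving epoch.
#'
#' @param model an `mi_model` from [build_backbone()] or
#'   [build_transformer()].
#' @param x,y training inputs (n x channels x time) and labels in
#'   \{-1, +1\}.
#' @param val_x,val_y validation split (required for early stopping).
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param patience epochs without validation improvement tolerated; `Inf`
#'   disables early stopping.
#' @param seed RNG seed for shuffling (parameter init is seeded at build
#'   time).
#' @param verbose print per-epoch progress.
#' @return the trained model, with `history` (data.frame epoch/train_loss/
#'   val_acc) and `best_epoch` attached.
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL,
                        epochs = 20L, batch_size = 64L, lr = 2e-3,
                        weight_decay = 1e-2, patience = 5L, seed = 1L,
                        verbose = FALSE) {
  if (!is.null(val_x) && dim(val_x)[1L] == 0L) stop("empty validation set")
  set.seed(seed)
  n <- dim(x)[1L]
  opt <- adamw_new(model$params)
  best_metric <- -Inf                     # maximized metric, init -infinity
  best_params <- model$params
  best_epoch <- 0L
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      tape <- tape_new()
      pn <- lift_params(tape, model$params)
      ml <- model_loss(model, x[idx, , , drop = FALSE], y[idx], pn, tape)
      grads_all <- ad_backward(ml$loss)
      grads <- lapply(pn, function(node) grads_all[[node$id]])
      st <- adamw_step(opt, model$params, grads, lr, weight_decay)
      opt <- st$opt; model$params <- st$params
      tot <- tot + ad_value(ml$loss); nb <- nb + 1L
    }
    val_acc <- NA_real_
    if (!is.null(val_x)) {
      pr <- predict_model(model, val_x)
      val_acc <- mean(pr$pred == val_y)
      if (val_acc > best_metric) {
        best_metric <- val_acc; best_params <- model$params
        best_epoch <- ep; bad <- 0L
      } else {
        bad <- bad + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / nb,
                                   val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val_acc %.3f", ep, tot / nb, val_acc))
    if (!is.null(val_x) && bad > patience) break
  }
  if (!is.null(val_x)) model$params <- best_params
  attr(model, "history") <- hist
  attr(model, "best_epoch") <- best_epoch
  model
}

#' Stratified train/validation/test split
#'
#' Splits trial indices by label so that class balance is preserved in each
#' part.
#'
#' @param y labels in \{-1, +1\}.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_spec <- function(y, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  tr <- va <- te <- integer(0)
  for (lb in unique(y)) {
    idx <- sample(which(y == lb))
    n <- length(idx)
    n_tr <- round(fractions[1L] * n)
    n_va <- min(round(fractions[2L] * n), n - n_tr)
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    if (n_tr + n_va < n) te <- c(te, idx[(n_tr + n_va + 1L):n])
  }
  list(train = sort(tr), validation = sort(va), test = sort(te))
}
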