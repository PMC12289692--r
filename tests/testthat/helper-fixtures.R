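# Shared fixtures (built once per test run) and numerical helpers.

fixture_env <- new.env()

# one-subject preprocessed epochs on the 180-sample model window
small_epochs <- function() {
  if (is.null(fixture_env$ep)) {
    cfg <- synth_config(n_subjects = 1L, n_trials_per_subject = 60L,
                        erd_factor = 0.4, seed = 101L)
    pp <- preprocess_recording(generate_recording(cfg, 1L))
    fixture_env$ep <- prepare_input(pp$epochs, 180L)
  }
  fixture_env$ep
}

# central finite differences of a scalar function of an array
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative error between an autodiff gradient and finite differences
grad_rel_err <- function(f_ad, x) {
  tape <- marginattn:::tape_new()
  xn <- marginattn:::ad_input(tape, x)
  loss <- f_ad(tape, xn)
  gr <- marginattn:::ad_backward(loss)[[xn$id]]
  fn <- function(xx) {
    t2 <- marginattn:::tape_new()
    as.numeric(marginattn:::ad_value(f_ad(t2, marginattn:::ad_input(t2, xx))))
  }
  ng <- num_grad(fn, x)
  max(abs(gr - ng)) / max(1e-8, max(abs(ng)))
}

# raw single-channel recording around a given waveform
wave_recording <- function(x, fs, onset = 1L, label = 1) {
  structure(list(data = matrix(x, nrow = 1L), fs = fs, channel_names = "C1",
                 events = data.frame(onset = onset, label = label),
                 subject_id = 1L),
            class = "raw_recording")
}

# steady-state gain of a single-pass filter at frequency f (least-squares
# fit of a sine/cosine pair on the final stretch of a long filtered sine)
single_pass_gain <- function(f, fs = 250, spec = filter_spec(zero_phase = FALSE),
                             dur = 20) {
  tt <- seq(0, dur, by = 1 / fs)
  rec <- wave_recording(sin(2 * pi * f * tt), fs)
  out <- highpass_filter(rec, spec)
  tail_idx <- (length(tt) - 2 * fs):length(tt)
  y <- out$data[1L, tail_idx]
  x <- tt[tail_idx]
  co <- stats::coef(stats::lm(y ~ sin(2 * pi * f * x) + cos(2 * pi * f * x) - 1))
  sqrt(sum(co^2))
}

# closed-form high-pass Butterworth magnitude response
butter_hp_gain <- function(f, fc = 4, n = 4) (f / fc)^n / sqrt(1 + (f / fc)^(2 * n))

# SVM dual solved by an interior-point QP (kernlab::ipop); by strong
# duality the optimal primal objective equals sum(alpha) - 0.5 ||w||^2.
qp_hinge_optimum <- function(phi, y, C) {
  n <- nrow(phi)
  H <- (y %*% t(y)) * tcrossprod(phi)
  sv <- kernlab::ipop(c = matrix(rep(-1, n)), H = H + diag(1e-8, n),
                      A = matrix(y, 1L), b = 0,
                      l = matrix(rep(0, n)), u = matrix(rep(C, n)), r = 0,
                      sigf = 8, maxiter = 400, margin = 0.05)
  a <- kernlab::primal(sv)
  w <- colSums(a * y * phi)
  sum(a) - 0.5 * sum(w^2)
}

# random small hinge instance with both classes present
random_hinge_instance <- function(n = NULL, d = NULL) {
  n <- n %||% sample(6:20, 1L)
  d <- d %||% sample(2:4, 1L)
  phi <- matrix(stats::rnorm(n * d), n, d)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2L) y[1L] <- -y[1L]
  list(phi = phi, y = y, n = n, d = d)
}
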