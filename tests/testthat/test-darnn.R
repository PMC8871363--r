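test_that("window construction is causal and counts L - T windows", {
  tr <- make_toy_traces(n = 3, L = 1001)
  w <- make_windows(tr, target = 2, T = 50)
  expect_equal(dim(w$X), c(951, 50, 3))
  expect_equal(length(w$label), 951)

  # no leakage: window b holds exactly columns b..b+T-1, label is column b+T
  for (b in c(1, 400, 951)) {
    for (j in 1:3) {
      expect_equal(w$X[b, , j], unname(tr$X[j, b:(b + 49)]))
    }
    expect_equal(unname(w$label[b]), unname(tr$X[2, b + 50]))
  }
  expect_equal(w$yhist, w$X[, , 2])

  expect_error(make_windows(tr, 1, 1001), "smaller")
  raw <- expression_traces(1:10, matrix(rnorm(20), 2))
  expect_error(make_windows(raw, 1, 3), "standardized")
})

test_that("a toy window set matches brute-force slicing", {
  X <- matrix(c(1, 2, 3, 4, 5,
                10, 20, 30, 40, 50), 2, byrow = TRUE)
  sc <- standard_scale(expression_traces(1:5, X))
  w <- make_windows(sc, target = 1, T = 2)
  expect_equal(dim(w$X)[1], 3)
  for (b in 1:3) {
    expect_equal(w$X[b, , 1], unname(sc$X[1, b:(b + 1)]))
    expect_equal(w$X[b, , 2], unname(sc$X[2, b:(b + 1)]))
    expect_equal(unname(w$label[b]), unname(sc$X[1, b + 2]))
  }
})

test_that("analytic gradients agree with finite differences", {
  cfg <- darnn_config(T = 4, encoder_hidden = 3, decoder_hidden = 3,
                      seed = 11)
  set.seed(5)
  B <- 3; T <- 4; n <- 3
  X <- array(rnorm(B * T * n), dim = c(B, T, n))
  yh <- matrix(rnorm(B * T), B, T)
  lb <- rnorm(B)
  params <- darnn_init(n, cfg)
  loss_fn <- function(p) mean((darnn_forward(p, X, yh, cfg)$yhat - lb)^2)
  fwd <- darnn_forward(params, X, yh, cfg, keep = "cache")
  gr <- darnn_backward(params, fwd, 2 * (fwd$yhat - lb) / B, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    idx <- if (length(p) > 5) {
      set.seed(match(nm, names(params)))
      sample(length(p), 5)
    } else seq_along(p)
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- gr[[nm]][i]
      scale <- abs(num) + abs(ana)
      if (scale > 1e-7) {
        expect_lt(abs(num - ana) / scale, 1e-4,
                  label = sprintf("gradient of %s[%d]", nm, i))
      }
    }
  }
})

test_that("input attention is a softmax at every encoder step", {
  cfg <- small_cfg()
  tr <- make_toy_traces(n = 4, L = 60)
  w <- make_windows(tr, 1, cfg$T)
  params <- darnn_init(4, cfg)
  fwd <- darnn_forward(params, w$X, w$yhist, cfg, keep = "alpha")
  expect_true(all(fwd$alphas >= 0))
  sums <- apply(fwd$alphas, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
})

test_that("training reduces the loss on a clean signal and is deterministic", {
  tr <- make_toy_traces(n = 2, L = 200, noise = 0)
  cfg <- darnn_config(T = 8, encoder_hidden = 12, decoder_hidden = 12,
                      batch_size = 64, epochs = 25, learning_rate = 2e-3,
                      seed = 7)
  w <- make_windows(tr, 1, cfg$T)
  m1 <- train_target_model(w, cfg)
  expect_lt(tail(m1$training_loss, 1), 0.3 * m1$training_loss[1])
  # near-monotone decrease: allow small (5%) upticks
  d <- diff(m1$training_loss)
  expect_true(all(d < 0.05 * head(m1$training_loss, -1)))

  m2 <- train_target_model(w, cfg)
  expect_identical(m1$params, m2$params)

  cfg2 <- cfg; cfg2$seed <- 8
  m3 <- train_target_model(w, cfg2)
  expect_false(identical(m1$params, m3$params))
})

test_that("parallel training yields one independent model per gene", {
  tr <- make_toy_traces(n = 3, L = 80)
  cfg <- small_cfg(epochs = 2)
  models <- train_parallel(tr, cfg)
  expect_length(models, 3)
  expect_equal(vapply(models, `[[`, 0L, "target"), 1:3)
  # independent parameter values (different derived seeds, different targets)
  expect_false(identical(models[[1]]$params, models[[2]]$params))
})

test_that("stub predictors isolate the RMSE contract", {
  tr <- make_toy_traces(n = 3, L = 120)
  T <- 10
  perfect <- perfect_ensemble(tr, T)
  rt <- rmse_table(perfect, tr)
  expect_equal(rt$rmse, rep(0, 3))
  expect_equal(attr(rt, "mean"), 0)

  zero <- stub_ensemble(tr, T, function(i) function(Xb, yb, t) rep(0, length(t)))
  rt0 <- rmse_table(zero, tr)
  # on standardized traces a constant-zero forecast scores about RMSE 1
  expect_true(all(abs(rt0$rmse - 1) < 0.05))
})

test_that("autonomous forecasting fixes its seed window and fixed points", {
  tr <- make_toy_traces(n = 2, L = 100)
  T <- 10
  perfect <- perfect_ensemble(tr, T)
  out <- predict_autonomous(perfect, tr)
  expect_equal(out$X, tr$X, tolerance = 1e-12)
  expect_equal(out$X[, 1:T], tr$X[, 1:T])

  diverge <- stub_ensemble(tr, T, function(i) function(Xb, yb, t) rep(2e3, length(t)))
  expect_error(predict_autonomous(diverge, tr), "diverged")
})

test_that("a trained model forecasts a noiseless oscillation autonomously", {
  tr <- make_toy_traces(n = 2, L = 250, noise = 0)
  cfg <- darnn_config(T = 10, encoder_hidden = 16, decoder_hidden = 16,
                      batch_size = 64, epochs = 40, learning_rate = 2e-3,
                      seed = 2)
  models <- train_parallel(tr, cfg)
  out <- predict_autonomous(models, tr)
  err <- sqrt(mean((out$X[, 11:250] - tr$X[, 11:250])^2))
  expect_lt(err, 0.35)
})

test_that("attention aggregation matches the explicit mean and row-sums to 1", {
  tr <- make_toy_traces(n = 3, L = 70)
  cfg <- small_cfg(epochs = 2)
  models <- train_parallel(tr, cfg)
  A <- extract_input_attention(models, tr)
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(A >= 0))

  # oracle: average the per-step attention window by window
  w <- make_windows(tr, 1, cfg$T)
  acc <- numeric(3)
  for (b in seq_len(dim(w$X)[1])) {
    fwd <- darnn_forward(models[[1]]$params, w$X[b, , , drop = FALSE],
                         w$yhist[b, , drop = FALSE], models[[1]]$config,
                         keep = "alpha")
    acc <- acc + apply(fwd$alphas[1, , ], 2, mean)
  }
  expect_equal(unname(A[1, ]), acc / dim(w$X)[1], tolerance = 1e-10)

  # single driving series: the softmax over one gene is identically 1
  tr1 <- make_toy_traces(n = 1, L = 60)
  m1 <- train_parallel(tr1, small_cfg(epochs = 1))
  expect_equal(unname(extract_input_attention(m1, tr1)), matrix(1, 1, 1),
               ignore_attr = TRUE)
})

test_that("gene-set mismatches are rejected", {
  tr <- make_toy_traces(n = 3, L = 70)
  cfg <- small_cfg(epochs = 1)
  models <- train_parallel(tr, cfg)
  other <- make_toy_traces(n = 4, L = 70)
  expect_error(extract_input_attention(models, other), "mismatch")
  w_bad <- make_windows(tr, 1, 4)
  expect_error(predict_one_step(models[[1]], w_bad), "mismatch")
})

test_that("one-step accuracy is insensitive to the window length", {
  # the forecast quality should vary by far less than 2x across windows
  tr <- make_toy_traces(n = 2, L = 260, noise = 0.02, seed = 5)
  rmses <- vapply(c(5, 10, 20), function(T) {
    cfg <- darnn_config(T = T, encoder_hidden = 8, decoder_hidden = 8,
                        batch_size = 128, epochs = 15, seed = 3)
    w <- make_windows(tr, 1, T)
    m <- train_target_model(w, cfg)
    sqrt(mean((predict_one_step(m, w) - w$label)^2))
  }, 0)
  expect_lt(max(rmses) / min(rmses), 2)
})
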