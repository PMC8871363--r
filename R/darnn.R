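#' Configuration of the dual-attention forecaster
#'
#' The forecaster is an encoder-decoder recurrent network with two softmax
#' attention stages: *input attention* reweights the N driving gene series
#' at every encoder step (from the previous encoder state and each series'
#' full window), and *temporal attention* reweights the T encoder hidden
#' states at every decoder step.  The decoder additionally consumes the
#' target gene's own history, and a final affine layer emits the one-step
#' prediction.  Training minimizes the mean squared error by mini-batch
#' gradient descent with the Adam optimizer.
#'
#' @param T window length in samples (study default 50).
#' @param encoder_hidden,decoder_hidden LSTM state sizes.
#' @param batch_size mini-batch size (study default 128).
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param seed master seed for initialization and batch shuffling.
#' @param train_fraction fraction of windows used for training (1 = all;
#'   the study trains on every window of the single provided trace).
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param patience epochs without loss improvement before early stop.
#' @return A list of class `darnn_config`.
#' @export
darnn_config <- function(T = 50L, encoder_hidden = 64L, decoder_hidden = 64L,
                         batch_size = 128L, epochs = 100L,
                         learning_rate = 1e-3, seed = 1L,
                         train_fraction = 1, grad_clip = 1, patience = 10L) {
  stopifnot(T >= 2, batch_size >= 1, epochs >= 1, learning_rate > 0,
            train_fraction > 0, train_fraction <= 1)
  structure(list(T = as.integer(T), encoder_hidden = as.integer(encoder_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 grad_clip = grad_clip, patience = as.integer(patience)),
            class = "darnn_config")
}

#' Build the supervised window set for one target gene
#'
#' For every time index `t` past the window, the driving inputs are all N
#' gene series over the previous `T` samples, the decoder history is the
#' target gene over the same window, and the label is the target at `t`
#' (strictly later than every input sample, so no leakage is possible).
#'
#' @param traces standardized [expression_traces()].
#' @param target target gene index (1-based).
#' @param T window length; must be smaller than the number of timepoints.
#' @return A list of class `darnn_windows` with the input array
#'   `X` (windows x T x genes), target history `yhist`, labels, and indexing
#'   metadata.  `L - T` windows are produced for a trace of length `L`.
#' @export
make_windows <- function(traces, target, T) {
  stopifnot(inherits(traces, "expression_traces"))
  if (!traces$scaled) stop("traces must be standardized first")
  Xg <- traces$X
  n <- nrow(Xg)
  L <- ncol(Xg)
  T <- as.integer(T)
  if (T >= L) stop("window length T must be smaller than the trace length")
  stopifnot(target >= 1, target <= n)
  B <- L - T
  # window b covers columns b..b+T-1, label at column b+T
  idx <- outer(seq_len(B) - 1L, seq_len(T), `+`)
  X <- array(0, dim = c(B, T, n))
  for (j in seq_len(n)) {
    X[, , j] <- matrix(Xg[j, idx], B, T)   # lagged embedding of gene j
  }
  structure(list(X = X, yhist = matrix(X[, , target], B, T),
                 label = Xg[target, T + seq_len(B)],
                 label_index = T + seq_len(B),
                 target = as.integer(target), T = T, n = n,
                 gene_ids = traces$gene_ids),
            class = "darnn_windows")
}

softmax_rows <- function(e) {
  e <- e - apply(e, 1, max)
  ex <- exp(e)
  ex / rowSums(ex)
}

# Parameter initialization: uniform(-1/sqrt(fan_in), +) per matrix, forget
# bias 1 on both LSTMs.
darnn_init <- function(n, cfg) {
  T <- cfg$T; m <- cfg$encoder_hidden; p <- cfg$decoder_hidden
  u <- function(nr, nc) {
    r <- 1 / sqrt(nc)
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  uv <- function(len, fan) runif(len, -1 / sqrt(fan), 1 / sqrt(fan))
  with_seed(cfg$seed, {
    params <- list(
      We = u(T, 2 * m), Ue = u(T, T), ve = uv(T, T),
      Wenc = u(4 * m, n + m), benc = rep(0, 4 * m),
      Wd = u(m, 2 * p), Ud = u(m, m), vd = uv(m, m),
      Wdec = u(4 * p, 1 + p), bdec = rep(0, 4 * p),
      wt = u(1, 1 + m), bt = 0,
      Wy = u(p, p + m), bw = rep(0, p), vy = uv(p, p), bv = 0
    )
    params$benc[m + seq_len(m)] <- 1
    params$bdec[p + seq_len(p)] <- 1
    params
  })
}

# Forward pass over a batch of windows.
#  X: (B, T, n) driving inputs; yhist: (B, T) target history.
#  keep = "none"  -> prediction only
#  keep = "cache" -> everything needed for the backward pass
#  keep = "alpha" -> per-step input-attention weights only
darnn_forward <- function(params, X, yhist, cfg, keep = "none") {
  B <- dim(X)[1]; T <- dim(X)[2]; n <- dim(X)[3]
  m <- cfg$encoder_hidden; p <- cfg$decoder_hidden
  want_cache <- keep == "cache"
  want_alpha <- keep != "none"
  sig <- function(z) 1 / (1 + exp(-z))
  gi <- seq_len; # readability only

  # --- encoder with input attention ---
  # stacked windows: row (k-1)*B + b holds gene k's window of sample b
  Xstack <- matrix(aperm(X, c(1, 3, 2)), B * n, T)
  P <- Xstack %*% t(params$Ue)
  repB <- rep(seq_len(B), times = n)
  h <- matrix(0, B, m); s <- matrix(0, B, m)
  H <- array(0, dim = c(B, T, m))
  alphas <- if (want_alpha) array(0, dim = c(B, T, n)) else NULL
  ecache <- if (want_cache) vector("list", T) else NULL
  i_i <- gi(m); i_f <- m + gi(m); i_o <- 2 * m + gi(m); i_g <- 3 * m + gi(m)
  for (t in seq_len(T)) {
    h_prev <- h; s_prev <- s
    q <- cbind(h, s) %*% t(params$We)              # B x T
    M <- tanh(P + q[repB, , drop = FALSE])         # (B n) x T
    e <- matrix(M %*% params$ve, B, n)
    alpha <- softmax_rows(e)
    xt <- matrix(X[, t, ], B, n)
    xtil <- alpha * xt
    z <- cbind(xtil, h) %*% t(params$Wenc)
    z <- sweep(z, 2, params$benc, `+`)
    ii <- sig(z[, i_i, drop = FALSE]); ff <- sig(z[, i_f, drop = FALSE])
    oo <- sig(z[, i_o, drop = FALSE]); gg <- tanh(z[, i_g, drop = FALSE])
    s <- ff * s_prev + ii * gg
    ts_ <- tanh(s)
    h <- oo * ts_
    H[, t, ] <- h
    if (want_alpha) alphas[, t, ] <- alpha
    if (want_cache) {
      ecache[[t]] <- list(M = M, alpha = alpha, xt = xt, xtil = xtil,
                          ii = ii, ff = ff, oo = oo, gg = gg,
                          h_prev = h_prev, s_prev = s_prev, s = s, ts = ts_)
    }
  }

  # --- decoder with temporal attention ---
  Hmat <- matrix(H, B * T, m)                      # row (i-1)*B + b = H[b,i,]
  UH <- Hmat %*% t(params$Ud)
  repBT <- rep(seq_len(B), times = T)
  d <- matrix(0, B, p); sd_ <- matrix(0, B, p)
  dcache <- if (want_cache) vector("list", T) else NULL
  j_i <- gi(p); j_f <- p + gi(p); j_o <- 2 * p + gi(p); j_g <- 3 * p + gi(p)
  ct <- matrix(0, B, m)
  for (t in seq_len(T)) {
    d_prev <- d; sd_prev <- sd_
    qd <- cbind(d, sd_) %*% t(params$Wd)           # B x m
    Md <- tanh(UH + qd[repBT, , drop = FALSE])     # (B T) x m
    l <- matrix(Md %*% params$vd, B, T)
    beta <- softmax_rows(l)
    ct <- matrix(0, B, m)
    for (i in seq_len(T)) ct <- ct + beta[, i] * matrix(H[, i, ], B, m)
    yt <- yhist[, t]
    ytil <- drop(cbind(yt, ct) %*% t(params$wt)) + params$bt
    z <- cbind(ytil, d) %*% t(params$Wdec)
    z <- sweep(z, 2, params$bdec, `+`)
    ii <- sig(z[, j_i, drop = FALSE]); ff <- sig(z[, j_f, drop = FALSE])
    oo <- sig(z[, j_o, drop = FALSE]); gg <- tanh(z[, j_g, drop = FALSE])
    sd_ <- ff * sd_prev + ii * gg
    tsd <- tanh(sd_)
    d <- oo * tsd
    if (want_cache) {
      dcache[[t]] <- list(Md = Md, beta = beta, ct = ct, yt = yt, ytil = ytil,
                          ii = ii, ff = ff, oo = oo, gg = gg,
                          d_prev = d_prev, sd_prev = sd_prev, sd = sd_,
                          tsd = tsd)
    }
  }

  u <- cbind(d, ct) %*% t(params$Wy)
  u <- sweep(u, 2, params$bw, `+`)
  yhat <- drop(u %*% params$vy) + params$bv

  out <- list(yhat = yhat)
  if (want_alpha) out$alphas <- alphas
  if (want_cache) {
    out$cache <- list(Xstack = Xstack, P = P, repB = repB, H = H,
                      Hmat = Hmat, UH = UH, repBT = repBT,
                      enc = ecache, dec = dcache, u = u,
                      d_T = d, c_T = ct, B = B, T = T, n = n)
  }
  out
}

# Compiled fused pass.  `darnn_forward()`/`darnn_backward()` above are the
# reference implementation; this wrapper calls the Armadillo translation,
# which the tests hold equal to the reference to near machine precision.
darnn_pass <- function(params, X, yhist, label = NULL, grad = FALSE,
                       alpha = FALSE) {
  out <- darnn_pass_cpp(params, X, yhist,
                        if (is.null(label)) numeric(dim(X)[1]) else label,
                        grad, alpha)
  out$yhat <- drop(out$yhat)
  if (alpha) out$alphas <- aperm(out$alphas, c(1, 3, 2))  # to (B, T, genes)
  out
}

# Backward pass: analytic gradients of the batch-mean squared error.
# Verified against central finite differences in the test suite.
darnn_backward <- function(params, fwd, dyhat, cfg) {
  cache <- fwd$cache
  B <- cache$B; T <- cache$T; n <- cache$n
  m <- cfg$encoder_hidden; p <- cfg$decoder_hidden
  g <- lapply(params, function(x) if (is.matrix(x)) {
    matrix(0, nrow(x), ncol(x))
  } else {
    numeric(length(x))
  })

  # output layer
  dvy <- drop(t(cache$u) %*% dyhat)
  dbv <- sum(dyhat)
  du <- dyhat %o% params$vy
  g$Wy <- t(du) %*% cbind(cache$d_T, cache$c_T)
  g$bw <- colSums(du)
  g$vy <- dvy; g$bv <- dbv
  ddc <- du %*% params$Wy
  dd <- ddc[, seq_len(p), drop = FALSE]
  dcT_out <- ddc[, p + seq_len(m), drop = FALSE]
  dsd <- matrix(0, B, p)

  dH <- array(0, dim = c(B, T, m))
  dUH <- matrix(0, B * T, m)

  # decoder, reversed
  for (t in rev(seq_len(T))) {
    dc <- cache$dec[[t]]
    # LSTM cell
    do_ <- dd * dc$tsd
    dsd_tot <- dsd + dd * dc$oo * (1 - dc$tsd^2)
    dii <- dsd_tot * dc$gg
    dff <- dsd_tot * dc$sd_prev
    dgg <- dsd_tot * dc$ii
    dsd <- dsd_tot * dc$ff
    dz <- cbind(dii * dc$ii * (1 - dc$ii), dff * dc$ff * (1 - dc$ff),
                do_ * dc$oo * (1 - dc$oo), dgg * (1 - dc$gg^2))
    g$Wdec <- g$Wdec + t(dz) %*% cbind(dc$ytil, dc$d_prev)
    g$bdec <- g$bdec + colSums(dz)
    dinp <- dz %*% params$Wdec
    dytil <- dinp[, 1]
    dd <- dinp[, 1 + seq_len(p), drop = FALSE]
    # ytil = [y_t, c_t] wt^T + bt
    g$wt <- g$wt + matrix(colSums(dytil * cbind(dc$yt, dc$ct)), 1)
    g$bt <- g$bt + sum(dytil)
    dct <- dytil %o% drop(params$wt)[1 + seq_len(m)]
    if (t == T) dct <- dct + dcT_out
    # context: c_t = sum_i beta_i H_i
    dbeta <- matrix(0, B, T)
    for (i in seq_len(T)) {
      Hi <- matrix(cache$H[, i, ], B, m)
      dbeta[, i] <- rowSums(dct * Hi)
      dH[, i, ] <- dH[, i, ] + dc$beta[, i] * dct
    }
    dl <- dc$beta * (dbeta - rowSums(dbeta * dc$beta))
    dlvec <- as.vector(dl)
    dMd <- dlvec %o% params$vd
    g$vd <- g$vd + drop(t(dc$Md) %*% dlvec)
    dAd <- dMd * (1 - dc$Md^2)
    dqd <- rowsum(dAd, cache$repBT)
    dUH <- dUH + dAd
    g$Wd <- g$Wd + t(dqd) %*% cbind(dc$d_prev, dc$sd_prev)
    dds <- dqd %*% params$Wd
    dd <- dd + dds[, seq_len(p), drop = FALSE]
    dsd <- dsd + dds[, p + seq_len(p), drop = FALSE]
  }
  g$Ud <- t(dUH) %*% cache$Hmat
  dHmat <- dUH %*% params$Ud
  dH <- dH + array(dHmat, dim = c(B, T, m))

  # encoder, reversed
  dh <- matrix(0, B, m); ds <- matrix(0, B, m)
  dP <- matrix(0, nrow(cache$P), ncol(cache$P))
  for (t in rev(seq_len(T))) {
    ec <- cache$enc[[t]]
    dh_tot <- dh + matrix(dH[, t, ], B, m)
    do_ <- dh_tot * ec$ts
    ds_tot <- ds + dh_tot * ec$oo * (1 - ec$ts^2)
    dii <- ds_tot * ec$gg
    dff <- ds_tot * ec$s_prev
    dgg <- ds_tot * ec$ii
    ds <- ds_tot * ec$ff
    dz <- cbind(dii * ec$ii * (1 - ec$ii), dff * ec$ff * (1 - ec$ff),
                do_ * ec$oo * (1 - ec$oo), dgg * (1 - ec$gg^2))
    g$Wenc <- g$Wenc + t(dz) %*% cbind(ec$xtil, ec$h_prev)
    g$benc <- g$benc + colSums(dz)
    dinp <- dz %*% params$Wenc
    dxtil <- dinp[, seq_len(n), drop = FALSE]
    dh <- dinp[, n + seq_len(m), drop = FALSE]
    # attention softmax
    dalpha <- dxtil * ec$xt
    de <- ec$alpha * (dalpha - rowSums(dalpha * ec$alpha))
    devec <- as.vector(de)
    dM <- devec %o% params$ve
    g$ve <- g$ve + drop(t(ec$M) %*% devec)
    dA <- dM * (1 - ec$M^2)
    dq <- rowsum(dA, cache$repB)
    dP <- dP + dA
    g$We <- g$We + t(dq) %*% cbind(ec$h_prev, ec$s_prev)
    dhs <- dq %*% params$We
    dh <- dh + dhs[, seq_len(m), drop = FALSE]
    ds <- ds + dhs[, m + seq_len(m), drop = FALSE]
  }
  g$Ue <- t(dP) %*% cache$Xstack
  g
}

grad_global_norm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), 0)))

#' Train the forecaster for one target gene
#'
#' Mini-batch Adam on the mean-squared one-step error.  Gradients are
#' clipped at a global norm and training stops early when the epoch loss
#' stops improving.  Deterministic given the configuration seed.
#'
#' @param windows a [make_windows()] set.
#' @param config a [darnn_config()]; its `T` must match the windows.
#' @return An object of class `darnn_model` holding the trained parameters,
#'   the configuration and the per-epoch loss history.
#' @export
train_target_model <- function(windows, config) {
  stopifnot(inherits(windows, "darnn_windows"), inherits(config, "darnn_config"))
  if (windows$T != config$T) stop("window length of data and config differ")
  n <- windows$n
  B_all <- dim(windows$X)[1]
  if (B_all < 1) stop("no training windows")
  params <- darnn_init(n, config)
  mstate <- lapply(params, function(x) x * 0)
  vstate <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_hist <- numeric(0)
  best <- Inf; stall <- 0L

  idx_all <- seq_len(B_all)
  if (config$train_fraction < 1) {
    keep <- with_seed(derive_seed(config$seed, 999),
                      sample(idx_all, max(1, round(config$train_fraction * B_all))))
    idx_all <- sort(keep)
  }

  with_seed(derive_seed(config$seed, 7), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(idx_all)
      starts <- seq(1, length(ord), by = config$batch_size)
      ep_loss <- 0
      for (st in starts) {
        take <- ord[st:min(st + config$batch_size - 1L, length(ord))]
        Xb <- windows$X[take, , , drop = FALSE]
        yb <- windows$yhist[take, , drop = FALSE]
        lb <- windows$label[take]
        pass <- darnn_pass(params, Xb, yb, label = lb, grad = TRUE)
        loss <- pass$loss
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", ep))
        }
        ep_loss <- ep_loss + loss * length(take)
        gr <- pass$grads
        if (config$grad_clip > 0) {
          gn <- grad_global_norm(gr)
          if (gn > config$grad_clip) {
            gr <- lapply(gr, function(x) x * config$grad_clip / gn)
          }
        }
        step <- step + 1
        corr <- config$learning_rate *
          sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr[[nm]]
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr[[nm]]^2
          params[[nm]] <- params[[nm]] -
            corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
        }
      }
      ep_loss <- ep_loss / length(ord)
      loss_hist <- c(loss_hist, ep_loss)
      if (ep_loss < best - 1e-8) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  structure(list(target = windows$target, params = params, config = config,
                 n = n, gene_ids = windows$gene_ids,
                 training_loss = loss_hist),
            class = "darnn_model")
}

#' @export
print.darnn_model <- function(x, ...) {
  cat(sprintf("<darnn_model> target gene %d (%s), %d genes, T=%d, final loss %.4g\n",
              x$target, x$gene_ids[x$target], x$n, x$config$T,
              tail(x$training_loss, 1)))
  invisible(x)
}

#' Train one forecaster per gene (parallel scheme)
#'
#' Trains N independent models, the i-th predicting the i-th gene from the
#' windows of all genes.  Per-gene seeds are derived from the master seed.
#'
#' @param traces standardized [expression_traces()].
#' @param config a [darnn_config()].
#' @param verbose print per-gene progress.
#' @return A list of class `darnn_ensemble` of N `darnn_model`s.
#' @export
train_parallel <- function(traces, config, verbose = FALSE) {
  stopifnot(inherits(traces, "expression_traces"))
  n <- nrow(traces$X)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    w <- make_windows(traces, i, config$T)
    t0 <- Sys.time()
    models[[i]] <- tryCatch(
      train_target_model(w, cfg_i),
      error = function(e) stop(sprintf("target gene %d: %s", i, conditionMessage(e)))
    )
    if (verbose) {
      message(sprintf("trained target %d/%d (%.1fs, loss %.4g)", i, n,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      tail(models[[i]]$training_loss, 1)))
    }
  }
  structure(models, class = "darnn_ensemble")
}

# Single prediction entry point.  A model may carry `predict_fun(Xb, yb, t)`
# (with `t` the label indices) in place of trained parameters -- used by
# stub predictors in the test suite to isolate contracts.
model_predict <- function(model, Xb, yb, t) {
  if (!is.null(model$predict_fun)) {
    return(model$predict_fun(Xb, yb, t))
  }
  if (is.null(model$params)) stop("model is not trained")
  darnn_pass(model$params, Xb, yb)$yhat
}

# Forward a window set through a model in memory-bounded chunks.
predict_windows <- function(model, windows, chunk = 512L, keep = "none") {
  B <- dim(windows$X)[1]
  preds <- numeric(B)
  alpha_sum <- NULL
  n_alpha <- 0
  for (st in seq(1, B, by = chunk)) {
    take <- st:min(st + chunk - 1L, B)
    if (keep == "none") {
      preds[take] <- model_predict(model, windows$X[take, , , drop = FALSE],
                                   windows$yhist[take, , drop = FALSE],
                                   windows$label_index[take])
      next
    }
    fwd <- darnn_pass(model$params, windows$X[take, , , drop = FALSE],
                      windows$yhist[take, , drop = FALSE],
                      alpha = keep == "alpha")
    preds[take] <- fwd$yhat
    if (keep == "alpha") {
      # mean over encoder steps and windows of the chunk
      contrib <- apply(fwd$alphas, 3, sum)
      alpha_sum <- if (is.null(alpha_sum)) contrib else alpha_sum + contrib
      n_alpha <- n_alpha + length(take) * dim(fwd$alphas)[2]
    }
  }
  out <- list(yhat = preds)
  if (keep == "alpha") out$alpha_mean <- alpha_sum / n_alpha
  out
}

#' One-step predictions and the per-gene RMSE table
#'
#' `predict_one_step()` runs a trained model over a window set and returns
#' the one-step predictions.  `rmse_table()` evaluates every model of an
#' ensemble on all windows of the trace (standardized scale) and reports the
#' per-gene root-mean-square error together with its mean and standard
#' deviation across genes -- the standard accuracy summary of the benchmark.
#'
#' @param model a `darnn_model`.
#' @param windows a [make_windows()] set with the model's window length.
#' @return `predict_one_step()`: numeric vector of predictions.
#' @export
predict_one_step <- function(model, windows) {
  stopifnot(inherits(model, "darnn_model"), inherits(windows, "darnn_windows"))
  if (windows$T != model$config$T) stop("window length mismatch")
  predict_windows(model, windows)$yhat
}

#' @rdname predict_one_step
#' @param models a `darnn_ensemble`.
#' @param traces standardized [expression_traces()].
#' @return `rmse_table()`: data frame of per-gene RMSE with attributes
#'   `mean` and `sd`.
#' @export
rmse_table <- function(models, traces) {
  stopifnot(inherits(models, "darnn_ensemble"))
  rmse <- vapply(seq_along(models), function(i) {
    w <- make_windows(traces, models[[i]]$target, models[[i]]$config$T)
    sqrt(mean((predict_one_step(models[[i]], w) - w$label)^2))
  }, 0)
  out <- data.frame(gene = traces$gene_ids[vapply(models, `[[`, 0L, "target")],
                    rmse = rmse)
  attr(out, "mean") <- mean(rmse)
  attr(out, "sd") <- sd(rmse)
  out
}

#' Free-running (autonomous) forecast of all genes
#'
#' All N models advance jointly one step at a time: the first `T` samples
#' are taken from the data, each step's N predictions are appended and
#' become inputs for the next step, so after `T` steps the forecast feeds
#' exclusively on its own output.
#'
#' @param models a `darnn_ensemble` (one model per gene, same gene set).
#' @param traces standardized [expression_traces()].
#' @param start index of the first sample of the seed window (default 1).
#' @return Predicted [expression_traces()] aligned to the input grid; the
#'   first `T` samples (from `start`) equal the input.
#' @export
predict_autonomous <- function(models, traces, start = 1L) {
  stopifnot(inherits(models, "darnn_ensemble"),
            inherits(traces, "expression_traces"), traces$scaled)
  n <- length(models)
  if (n != nrow(traces$X)) stop("ensemble/gene-set mismatch")
  T <- models[[1]]$config$T
  L <- ncol(traces$X)
  if (start + T - 1 >= L) stop("start + T must leave room for prediction")
  pred <- traces$X
  for (t in (start + T):L) {
    win <- pred[, (t - T):(t - 1), drop = FALSE]   # n x T
    Xb <- array(t(win), dim = c(1, T, n))
    for (i in seq_len(n)) {
      yb <- matrix(win[models[[i]]$target, ], 1, T)
      val <- model_predict(models[[i]], Xb, yb, t)
      if (!is.finite(val) || abs(val) > 1e3) {
        stop(sprintf("autonomous forecast diverged (gene %d, step %d)", i, t))
      }
      pred[models[[i]]$target, t] <- val
    }
  }
  expression_traces(traces$times, pred, traces$gene_ids, scaled = TRUE,
                    scaler = traces$scaler)
}

#' Aggregate the learned input attention into a gene-by-gene matrix
#'
#' Row i holds the input-attention weights of the model trained on target
#' gene i, averaged over all encoder steps and all windows of the trace
#' (evaluation pass of the final parameters).  Because every per-step
#' attention vector is a softmax over genes, every row sums to 1.
#'
#' @param models a `darnn_ensemble`.
#' @param traces standardized [expression_traces()] (the same gene set the
#'   models were trained on).
#' @return N x N numeric matrix with gene labels and an `aggregation`
#'   attribute.
#' @export
extract_input_attention <- function(models, traces) {
  stopifnot(inherits(models, "darnn_ensemble"),
            inherits(traces, "expression_traces"))
  n <- length(models)
  ids <- models[[1]]$gene_ids
  for (mo in models) {
    if (!identical(mo$gene_ids, ids)) stop("models trained on different gene sets")
  }
  if (!identical(traces$gene_ids, ids)) stop("trace/model gene-set mismatch")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    w <- make_windows(traces, models[[i]]$target, models[[i]]$config$T)
    A[models[[i]]$target, ] <- predict_windows(models[[i]], w,
                                               keep = "alpha")$alpha_mean
  }
  attr(A, "aggregation") <- "mean over encoder steps and windows"
  A
}
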