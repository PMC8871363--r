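#' Robustness of the forecast to Gaussian perturbation of the target gene
#'
#' For one target gene, the whole series is re-predicted step by step: the
#' other genes' rows of the input window stay at the observed (standardized)
#' traces, while the target's own history is its previously predicted
#' values.  At every step, independent Gaussian noise with mean zero and
#' variance `sigma2` (standardized units) is added to the target gene's
#' values inside the input window -- and only there; the noise is re-drawn
#' at each step.  The returned value is the mean squared error between the
#' noisy prediction and the unperturbed original series.
#'
#' @param models a `darnn_ensemble` from [train_parallel()].
#' @param traces standardized [expression_traces()].
#' @param target target gene index.
#' @param sigma2 noise variance (0 gives the noise-free value exactly).
#' @param seed integer seed; deterministic given the seed.
#' @return Nonnegative mean squared error.
#' @export
noisy_autonomous_mse <- function(models, traces, target, sigma2, seed = 1L) {
  stopifnot(sigma2 >= 0)
  drop(noise_mse_levels(models, traces, target, sigma2, seed, level_index = 1L))
}

# Shared engine: predicts the target's series for several noise levels at
# once (levels ride along the batch dimension).  Noise for level `li` of
# target `i` comes from its own derived seed so that a single level
# recomputed in isolation reproduces the batched value bit for bit.
noise_mse_levels <- function(models, traces, target, sigma2_grid, seed,
                             level_index = seq_along(sigma2_grid)) {
  stopifnot(inherits(models, "darnn_ensemble"),
            inherits(traces, "expression_traces"), traces$scaled)
  model <- models[[target]]
  if (is.null(model$params) && is.null(model$predict_fun)) {
    stop("model for target gene is not trained")
  }
  n <- model$n
  T <- model$config$T
  L <- ncol(traces$X)
  nl <- length(sigma2_grid)
  sig <- sqrt(sigma2_grid)

  # per-level noise streams, pregenerated in step order
  steps <- L - T
  noise <- vector("list", nl)
  for (li in seq_len(nl)) {
    cell_seed <- derive_seed(seed, target, level_index[li])
    noise[[li]] <- with_seed(cell_seed,
                             matrix(rnorm(steps * T), steps, T) * sig[li])
  }

  truth <- traces$X[target, ]
  # predicted history per level (starts from the observed first T samples)
  hist <- matrix(rep(truth[seq_len(T)], each = nl), nl, T)
  pred <- matrix(0, nl, steps)
  Xb <- array(0, dim = c(nl, T, n))
  base_win <- NULL
  for (st in seq_len(steps)) {
    t0 <- st            # window covers columns st..st+T-1, label at st+T
    win <- traces$X[, t0:(t0 + T - 1), drop = FALSE]   # n x T observed
    for (j in seq_len(n)) Xb[, , j] <- matrix(rep(win[j, ], each = nl), nl, T)
    noisy_hist <- hist
    for (li in seq_len(nl)) {
      noisy_hist[li, ] <- hist[li, ] + noise[[li]][st, ]
    }
    Xb[, , target] <- noisy_hist
    yhat <- model_predict(model, Xb, noisy_hist, rep(t0 + T, nl))
    pred[, st] <- yhat
    # slide the target's predicted history
    hist <- cbind(hist[, -1, drop = FALSE], yhat)
  }
  mse <- rowMeans((pred - matrix(rep(truth[(T + 1):L], each = nl),
                                 nl, steps))^2)
  mse
}

#' Noise-response matrix and its ranked summary
#'
#' `noise_matrix()` evaluates [noisy_autonomous_mse()] for every gene over a
#' grid of noise variances (default 0.1 to 0.9 in steps of 0.1) and returns
#' the genes x levels MSE matrix with a trailing `mean` column.
#'
#' `noise_summary()` turns such a matrix into the per-architecture feature
#' row used for clustering: per-gene means across levels are sorted in
#' increasing order and normalized to their maximum (so the vector is
#' non-decreasing and ends in 1), per-gene variances are permuted by the
#' *mean* ranking -- preserving the mean/variance pairing per gene -- and
#' normalized to their own maximum; the feature row concatenates both.
#'
#' @param models a `darnn_ensemble`.
#' @param traces standardized [expression_traces()].
#' @param sigma2_grid noise variances (default `seq(0.1, 0.9, by = 0.1)`).
#' @param seed integer seed for the noise draws.
#' @return `noise_matrix()`: genes x (levels + 1) matrix of class
#'   `noise_mse_matrix` with a `mean` column and a `sigma2` attribute.
#' @export
noise_matrix <- function(models, traces, sigma2_grid = seq(0.1, 0.9, by = 0.1),
                         seed = 1L) {
  stopifnot(length(sigma2_grid) >= 1, all(diff(sigma2_grid) > 0),
            all(sigma2_grid >= 0))
  n <- length(models)
  M <- t(vapply(seq_len(n), function(i) {
    noise_mse_levels(models, traces, i, sigma2_grid, seed)
  }, numeric(length(sigma2_grid))))
  out <- cbind(M, mean = rowMeans(M))
  colnames(out) <- c(sprintf("sigma2_%g", sigma2_grid), "mean")
  rownames(out) <- traces$gene_ids
  attr(out, "sigma2") <- sigma2_grid
  class(out) <- c("noise_mse_matrix", class(out))
  out
}

#' @rdname noise_matrix
#' @param mat a `noise_mse_matrix`.
#' @return `noise_summary()`: list with `means` (ranked, normalized),
#'   `variances` (reordered by the mean ranking, normalized) and `feature`
#'   (their concatenation).
#' @export
noise_summary <- function(mat) {
  levels <- attr(mat, "sigma2")
  M <- mat[, seq_along(levels), drop = FALSE]
  mu <- rowMeans(M)
  v <- apply(M, 1, var)
  if (max(mu) == 0) stop("all-zero MSE: nothing to normalize")
  ord <- order(mu)
  mu_r <- mu[ord] / max(mu)
  v_r <- v[ord]
  if (max(v_r) > 0) v_r <- v_r / max(v_r)
  list(means = unname(mu_r), variances = unname(v_r),
       feature = unname(c(mu_r, v_r)))
}
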