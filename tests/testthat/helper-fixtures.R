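# Shared fixtures: small deterministic traces, stub predictors and
# brute-force oracles used across the test files.

# Smooth multi-gene traces (coupled sinusoids plus small noise), standardized.
make_toy_traces <- function(n = 3, L = 200, period = 40, noise = 0.05,
                            seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    tt <- seq_len(L)
    X <- t(sapply(seq_len(n), function(i) {
      sin(2 * pi * tt / period + i) + noise * rnorm(L)
    }))
    standard_scale(expression_traces(tt, X))
  })
}

# Stub predictor posing as a trained model: `fun(Xb, yb, t)` returns the
# predictions for label indices t.
stub_model <- function(target, n, gene_ids, T, fun) {
  structure(list(target = as.integer(target), params = NULL,
                 config = darnn_config(T = T, encoder_hidden = 4,
                                       decoder_hidden = 4),
                 n = n, gene_ids = gene_ids, training_loss = 0,
                 predict_fun = fun),
            class = "darnn_model")
}

stub_ensemble <- function(traces, T, fun_for_target) {
  n <- nrow(traces$X)
  structure(lapply(seq_len(n), function(i) {
    stub_model(i, n, traces$gene_ids, T, fun_for_target(i))
  }), class = "darnn_ensemble")
}

# An ensemble of perfect predictors (ignore inputs, return the true value).
perfect_ensemble <- function(traces, T) {
  stub_ensemble(traces, T, function(i) {
    truth <- traces$X[i, ]
    function(Xb, yb, t) truth[t]
  })
}

small_cfg <- function(epochs = 3, ...) {
  darnn_config(T = 6, encoder_hidden = 5, decoder_hidden = 5,
               batch_size = 32, epochs = epochs, seed = 42, ...)
}

# ---- brute-force oracles -------------------------------------------------

# Barrat weighted clustering by direct enumeration of neighbour pairs.
oracle_barrat <- function(W) {
  W <- (W + t(W)) / 2
  diag(W) <- 0
  A <- (W > 0) * 1
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    si <- sum(W[i, ])
    if (ki < 2 || si == 0) return(0)
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != h && j != i && h != i && A[i, j] && A[i, h] && A[j, h]) {
        tot <- tot + (W[i, j] + W[i, h]) / 2
      }
    }
    tot / (si * (ki - 1))
  })
}

# Directed weighted betweenness via Dijkstra with shortest-path counting.
oracle_betweenness <- function(W) {
  n <- nrow(W)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (v in which(W[u, ] > 0)) {
        alt <- dist[u] + W[u, v]
        if (alt < dist[v] - 1e-12) {
          dist[v] <- alt; sigma[v] <- sigma[u]; preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= 1e-12) {
          sigma[v] <- sigma[v] + sigma[u]; preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    # dependency accumulation (Brandes)
    delta <- numeric(n)
    for (v in order(dist, decreasing = TRUE)) {
      if (!is.finite(dist[v]) || v == s) next
      for (u in preds[[v]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      }
    }
    btw <- btw + ifelse(seq_len(n) == s, 0, delta)
  }
  btw
}

# Hub score via dense eigendecomposition of W W^T.
oracle_hub <- function(W) {
  ev <- eigen(W %*% t(W), symmetric = TRUE)
  v <- abs(ev$vectors[, 1])
  v / max(v)
}

# Variation of information through the joint-entropy identity
# VI = 2 H(joint) - H(C) - H(C').
oracle_vi <- function(p1, p2) {
  n <- length(p1)
  joint <- table(paste(p1, p2)) / n
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  2 * h(as.vector(joint)) - h(as.vector(table(p1) / n)) -
    h(as.vector(table(p2) / n))
}

# Mean silhouette width by direct evaluation of s = (DN - DI)/max(DI, DN).
oracle_mean_silhouette <- function(mat, cl) {
  d <- as.matrix(dist(mat))
  n <- nrow(mat)
  s <- sapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    di <- mean(d[i, own])
    dn <- min(sapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }))
    (dn - di) / max(di, dn)
  })
  mean(s)
}

# Naive O(n^3) complete-linkage: returns the cophenetic distance matrix.
oracle_complete_linkage_cophenetic <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    ia <- clusters[[best[2]]]; ib <- clusters[[best[3]]]
    coph[ia, ib] <- best[1]; coph[ib, ia] <- best[1]
    clusters[[best[2]]] <- c(ia, ib)
    clusters[[best[3]]] <- NULL
  }
  coph
}

# Clustering-information tree distance with exhaustive matching (for trees
# with at most ~5 nontrivial splits per side).
oracle_tree_distance <- function(nwk1, nwk2) {
  t1 <- ape::read.tree(text = nwk1)
  t2 <- ape::read.tree(text = nwk2)
  leaves <- sort(t1$tip.label)
  splits <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    out <- list(); seen <- character(0)
    for (cl in pp) {
      memb <- leaves %in% labs[cl]
      if (!memb[1]) memb <- !memb
      if (sum(memb) < 2 || sum(!memb) < 2) next
      key <- paste(as.integer(memb), collapse = "")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- memb
    }
    out
  }
  ent <- function(m) {
    p <- c(sum(m), length(m) - sum(m)) / length(m)
    -sum(p * log2(p))
  }
  mi <- function(a, b) {
    n <- length(a)
    tot <- 0
    for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE)) {
      p <- sum(a == x & b == y) / n
      if (p > 0) tot <- tot + p * log2(p / (mean(a == x) * mean(b == y)))
    }
    tot
  }
  s1 <- splits(nwk_tree <- t1); s2 <- splits(t2)
  H <- sum(sapply(s1, ent)) + sum(sapply(s2, ent))
  if (length(s1) == 0 || length(s2) == 0) return(H)
  # enumerate all injective matchings of the smaller side into the larger
  if (length(s1) > length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  k <- length(s1); m <- length(s2)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1)) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (assign in perms(seq_len(m), k)) {
    tot <- sum(sapply(seq_len(k), function(i) mi(s1[[i]], s2[[assign[i]]])))
    best <- max(best, tot)
  }
  H - 2 * best
}
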