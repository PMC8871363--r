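#' Autocorrelation time of a trace
#'
#' Returns the first lag at which the sample autocorrelation function enters
#' the large-sample white-noise confidence band `z * n^(-1/2)` (the 95% band
#' by default, the convention used by standard ACF routines).  Used to pick
#' the training window of the forecaster: a window slightly larger than the
#' decorrelation time retains the usable memory of the process.
#'
#' @param trace numeric vector.
#' @param ci confidence level of the band (default 0.95).
#' @param max_lag largest lag examined; default `floor(length(trace) / 3)`.
#'   Returned when the ACF never enters the band.
#' @return Integer lag in samples.
#' @export
autocorrelation_time <- function(trace, ci = 0.95, max_lag = NULL) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (is.null(max_lag)) max_lag <- floor(n / 3)
  stopifnot(max_lag >= 1, n >= 3 * max_lag)
  if (sd(trace) == 0) stop("constant trace has no autocorrelation time")
  band <- qnorm(1 - (1 - ci) / 2) / sqrt(n)
  r <- drop(acf(trace, lag.max = max_lag, plot = FALSE)$acf)[-1]
  inside <- which(abs(r) < band)
  if (length(inside) == 0) max_lag else inside[1]
}

#' Histogram divergences between observed and predicted traces
#'
#' Per gene, both traces are binned on shared equal-width bins spanning the
#' pooled range; a small pseudocount keeps the Kullback-Leibler divergence
#' finite on empty bins.  The Jensen-Shannon distance is the square root of
#' the Jensen-Shannon divergence and is bounded by `sqrt(ln 2)` in nats.
#'
#' @param real,pred [expression_traces()] objects over the same gene set.
#' @param n_bins number of histogram bins (default 50).
#' @param pseudocount mass added to every bin before normalization.
#' @return A data frame with columns `gene`, `kl` (nats, `KL(real || pred)`)
#'   and `js_distance`.
#' @export
distribution_divergences <- function(real, pred, n_bins = 50,
                                     pseudocount = 1e-12) {
  stopifnot(inherits(real, "expression_traces"),
            inherits(pred, "expression_traces"))
  if (!identical(real$gene_ids, pred$gene_ids)) {
    stop("gene sets differ between traces")
  }
  if (ncol(real$X) == 0 || ncol(pred$X) == 0) stop("empty traces")
  out <- lapply(seq_len(nrow(real$X)), function(i) {
    a <- real$X[i, ]
    b <- pred$X[i, ]
    rng <- range(c(a, b))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    p <- tabulate(findInterval(a, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), n_bins) + pseudocount
    q <- tabulate(findInterval(b, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), n_bins) + pseudocount
    p <- p / sum(p)
    q <- q / sum(q)
    m <- (p + q) / 2
    kl <- function(u, v) sum(u * log(u / v))
    js <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
    data.frame(gene = real$gene_ids[i], kl = kl(p, q),
               js_distance = sqrt(max(js, 0)))
  })
  do.call(rbind, out)
}
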