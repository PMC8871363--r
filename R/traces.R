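#' Expression-trace container
#'
#' Holds per-gene protein levels on a uniform time grid.  The default study
#' grid is time 0 to 10,000 sampled every 10 time units, extremes included
#' (1001 points).
#'
#' @param times strictly increasing, uniformly spaced sample times.
#' @param X genes x timepoints matrix of protein levels.
#' @param gene_ids gene labels (default `gene1..geneN`).
#' @param scaled logical; `TRUE` after [standard_scale()].
#' @param scaler per-gene list of `(mean, sd)` recorded when scaling.
#' @return An object of class `expression_traces`.
#' @export
expression_traces <- function(times, X, gene_ids = NULL, scaled = FALSE,
                              scaler = NULL) {
  X <- as.matrix(X)
  if (length(times) != ncol(X)) stop("length(times) must equal ncol(X)")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt)) {
      stop("times must be a strictly increasing uniform grid")
    }
  }
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(rownames(X))) rownames(X)
                else paste0("gene", seq_len(nrow(X)))
  }
  rownames(X) <- gene_ids
  structure(list(times = as.double(times), X = X, gene_ids = gene_ids,
                 scaled = isTRUE(scaled), scaler = scaler),
            class = "expression_traces")
}

#' @export
print.expression_traces <- function(x, ...) {
  cat(sprintf("<expression_traces> %d genes x %d timepoints (t = %g..%g%s)\n",
              nrow(x$X), ncol(x$X), min(x$times), max(x$times),
              if (x$scaled) ", standardized" else ""))
  invisible(x)
}

#' Standardize traces to zero mean and unit variance per gene
#'
#' Scaling parameters are stored so that [inverse_scale()] restores the
#' original levels exactly (round-trip error below 1e-9).
#'
#' @param traces an [expression_traces()] object (unscaled).
#' @return The standardized traces with `scaled = TRUE`.
#' @export
standard_scale <- function(traces) {
  stopifnot(inherits(traces, "expression_traces"))
  mu <- rowMeans(traces$X)
  sdv <- apply(traces$X, 1, sd)
  if (any(sdv == 0)) {
    stop(sprintf("constant trace for gene(s): %s",
                 paste(traces$gene_ids[sdv == 0], collapse = ", ")))
  }
  Xs <- (traces$X - mu) / sdv
  expression_traces(traces$times, Xs, traces$gene_ids, scaled = TRUE,
                    scaler = list(mean = mu, sd = sdv))
}

#' @rdname standard_scale
#' @export
inverse_scale <- function(traces) {
  stopifnot(inherits(traces, "expression_traces"), traces$scaled,
            !is.null(traces$scaler))
  X <- traces$X * traces$scaler$sd + traces$scaler$mean
  expression_traces(traces$times, X, traces$gene_ids, scaled = FALSE)
}

#' Discard the transient start of a simulation
#'
#' Distribution-level statistics (histogram divergences) assume approximate
#' stationarity; dropping the first fraction of the run removes the
#' relaxation from the initial state.
#'
#' @param traces an [expression_traces()] object.
#' @param frac fraction of the time span to drop (default 0.1).
#' @return Truncated traces.
#' @export
drop_burnin <- function(traces, frac = 0.1) {
  stopifnot(inherits(traces, "expression_traces"), frac >= 0, frac < 1)
  keep <- traces$times >= min(traces$times) + frac * diff(range(traces$times))
  expression_traces(traces$times[keep], traces$X[, keep, drop = FALSE],
                    traces$gene_ids, scaled = traces$scaled,
                    scaler = traces$scaler)
}

#' Read / write traces as TSV
#'
#' The file has a `time` first column and one column per gene; gene order is
#' preserved.
#'
#' @param traces an [expression_traces()] object.
#' @param path file path.
#' @return `write_traces_tsv()` returns `path` invisibly;
#'   `read_traces_tsv()` returns an [expression_traces()].
#' @export
write_traces_tsv <- function(traces, path) {
  df <- data.frame(time = traces$times, t(traces$X), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_tsv
#' @export
read_traces_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  expression_traces(df$time, t(as.matrix(df[, -1, drop = FALSE])),
                    gene_ids = colnames(df)[-1])
}
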