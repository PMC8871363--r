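#' Construct a gene regulatory network specification
#'
#' A `grn_spec` bundles the signed interaction matrix of a gene regulatory
#' network (GRN) with the kinetic parameters of its Hill-type regulation and
#' is the ground truth for every downstream step (simulation, forecasting,
#' attention analysis).
#'
#' The interaction matrix `J` follows the row-is-target convention:
#' `J[i, j]` is the effect of gene `j` on gene `i` (+1 activation,
#' -1 repression, 0 none).  All kinetic matrices are dense N x N so that the
#' entries are defined (and positive) wherever `J` is nonzero.
#'
#' @param J integer N x N matrix with entries in \{-1, 0, 1\}.
#' @param k N x N activation rates (1/time), or a scalar recycled.
#' @param k_rep N x N repression-branch rates (1/time), or a scalar.
#' @param h N x N Hill cooperativity exponents, or a scalar.
#' @param K N x N dissociation constants (molecule counts), or a scalar.
#' @param tau N x N interaction delays (time units); this implementation
#'   requires all zeros (delays are out of scope).
#' @param decay per-gene first-order dilution rate (1/time), scalar or
#'   length-N vector.
#' @param basal per-gene basal (leaky) production rate (1/time), scalar or
#'   length-N; see the methods vignette for why basal production is applied
#'   to every gene.
#' @param prod_cap per-gene ceiling on the regulated production rate
#'   (1/time), scalar or length-N; models the finite capacity of the
#'   transcription/translation machinery and bounds the reachable copy
#'   numbers (`Inf` disables it).
#' @param external `NULL`, or a list describing a sinusoidal external driver:
#'   `list(waveform = "sine", amplitude, period, phase = 0, k, h, K)` where
#'   `k` is the length-N vector of activator coupling rates from the driver
#'   to each gene (0 = uncoupled).
#' @param label architecture name string.
#'
#' @return An object of class `grn_spec`.
#' @seealso [build_architecture()], [random_interaction_matrix()],
#'   [simulate_grn()]
#' @export
grn_spec <- function(J, k = 1, k_rep = 1, h = 2, K = 50, tau = 0,
                     decay = 0.02, basal = 0.05, prod_cap = Inf,
                     external = NULL, label = "custom") {
  J <- as.matrix(J)
  n <- nrow(J)
  full <- function(x, what) {
    if (length(x) == 1L) x <- matrix(as.double(x), n, n)
    x <- as.matrix(x)
    if (!all(dim(x) == c(n, n))) {
      stop(sprintf("'%s' must be %d x %d (or scalar)", what, n, n))
    }
    x
  }
  vec <- function(x, what) {
    if (length(x) == 1L) x <- rep(as.double(x), n)
    if (length(x) != n) stop(sprintf("'%s' must have length %d", what, n))
    as.double(x)
  }
  spec <- structure(
    list(
      n_genes = n,
      J = J,
      k = full(k, "k"), k_rep = full(k_rep, "k_rep"),
      h = full(h, "h"), K = full(K, "K"), tau = full(tau, "tau"),
      decay = vec(decay, "decay"), basal = vec(basal, "basal"),
      prod_cap = vec(prod_cap, "prod_cap"),
      external = external, label = as.character(label)
    ),
    class = "grn_spec"
  )
  validate_grn_spec(spec)
}

#' @rdname grn_spec
#' @param spec a `grn_spec` object.
#' @export
validate_grn_spec <- function(spec) {
  stopifnot(inherits(spec, "grn_spec"))
  n <- spec$n_genes
  J <- spec$J
  if (!all(dim(J) == c(n, n)) || !all(J %in% c(-1, 0, 1))) {
    stop("J must be N x N with entries in {-1, 0, 1}")
  }
  for (nm in c("k", "k_rep", "h", "K", "tau")) {
    m <- spec[[nm]]
    if (!all(dim(m) == c(n, n))) stop(sprintf("'%s' must be N x N", nm))
    if (nm == "tau") {
      if (any(m < 0)) stop("tau must be nonnegative")
      if (any(m != 0)) stop("nonzero delays are not supported")
    } else if (any(m[J != 0] <= 0)) {
      stop(sprintf("'%s' must be strictly positive where J != 0", nm))
    }
  }
  if (any(spec$decay <= 0)) stop("decay must be positive")
  if (any(spec$basal < 0)) stop("basal must be nonnegative")
  if (any(spec$prod_cap <= 0)) stop("prod_cap must be positive")
  if (!is.null(spec$external)) {
    ext <- spec$external
    stopifnot(is.list(ext), ext$waveform == "sine",
              length(ext$k) == n, all(ext$k >= 0),
              ext$period > 0, ext$amplitude >= 0, ext$K > 0, ext$h > 0)
  }
  spec
}

#' @export
print.grn_spec <- function(x, ...) {
  nz <- sum(x$J != 0)
  cat(sprintf("<grn_spec> '%s': %d genes, %d edges (%d act / %d rep)%s\n",
              x$label, x$n_genes, nz, sum(x$J == 1), sum(x$J == -1),
              if (!is.null(x$external)) ", external driver" else ""))
  invisible(x)
}

#' Serialize / deserialize a GRN specification as JSON
#'
#' Matrices are stored as nested arrays; the document round-trips through
#' [read_grn_json()].
#'
#' @param spec a `grn_spec`.
#' @param path file path.
#' @return `write_grn_json()` returns `path` invisibly; `read_grn_json()`
#'   returns a `grn_spec`.
#' @export
write_grn_json <- function(spec, path) {
  validate_grn_spec(spec)
  doc <- list(
    n_genes = spec$n_genes, label = spec$label,
    J = spec$J, k = spec$k, k_rep = spec$k_rep, h = spec$h, K = spec$K,
    tau = spec$tau, decay = spec$decay, basal = spec$basal,
    prod_cap = ifelse(is.finite(spec$prod_cap), spec$prod_cap, NA),
    external = spec$external
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grn_json
#' @export
read_grn_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ext <- doc$external
  if (!is.null(ext) && length(ext) == 0) ext <- NULL
  grn_spec(J = doc$J, k = doc$k, k_rep = doc$k_rep, h = doc$h, K = doc$K,
           tau = doc$tau, decay = doc$decay, basal = doc$basal,
           prod_cap = if (is.null(doc$prod_cap)) Inf else
             ifelse(is.na(doc$prod_cap), Inf, doc$prod_cap),
           external = ext, label = doc$label)
}

#' Export the interaction matrix as a signed edge list
#'
#' @param spec a `grn_spec`.
#' @param path optional TSV path; when given the edge list (columns
#'   `source`, `target`, `sign`) is written there.
#' @return A data frame with one row per nonzero interaction.
#' @export
grn_edge_list <- function(spec, path = NULL) {
  idx <- which(spec$J != 0, arr.ind = TRUE)
  el <- data.frame(
    source = idx[, "col"], target = idx[, "row"],
    sign = spec$J[idx]
  )
  el <- el[order(el$source, el$target), , drop = FALSE]
  rownames(el) <- NULL
  if (!is.null(path)) {
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  el
}
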