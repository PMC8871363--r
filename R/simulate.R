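#' Production propensity of one gene
#'
#' Implements the Hill-type regulation law: the production rate of gene `i`
#' is the product, over its regulators `j`, of an activation term
#' `k_ij x_j^h / (x_j^h + K_ij^h)` (when `J[i,j] = +1`) or a repression term
#' `k_rep_ij K_ij^h / (x_j^h + K_ij^h)` (when `J[i,j] = -1`), plus the
#' gene's basal (leaky) rate.  A gene with no regulators produces at its
#' basal rate only.  An external sinusoidal driver, when present and
#' coupled, contributes one more activation factor with the driver waveform
#' in place of a regulator concentration.  The regulated term saturates at
#' the gene's `prod_cap` (finite expression machinery), which bounds the
#' reachable copy numbers at `prod_cap / decay`.
#'
#' This R version is the reference implementation; the Gillespie loop uses
#' an equivalent compiled version.
#'
#' @param i target gene index (1-based).
#' @param x nonnegative state vector of protein counts.
#' @param t time (only relevant with an external driver).
#' @param spec a [grn_spec()].
#' @return Nonnegative production rate (1/time).
#' @export
production_propensity <- function(i, x, t, spec) {
  stopifnot(inherits(spec, "grn_spec"))
  if (any(x < 0)) stop("negative state")
  regs <- which(spec$J[i, ] != 0)
  drv <- !is.null(spec$external) && spec$external$k[i] > 0
  prop <- spec$basal[i]
  if (length(regs) > 0 || drv) {
    prod <- 1
    for (j in regs) {
      xh <- x[j]^spec$h[i, j]
      Kh <- spec$K[i, j]^spec$h[i, j]
      prod <- prod * if (spec$J[i, j] > 0) {
        spec$k[i, j] * xh / (xh + Kh)
      } else {
        spec$k_rep[i, j] * Kh / (xh + Kh)
      }
    }
    if (drv) {
      ext <- spec$external
      d <- external_driver_value(ext, t)
      dh <- d^ext$h
      prod <- prod * ext$k[i] * dh / (dh + ext$K^ext$h)
    }
    prop <- prop + min(prod, spec$prod_cap[i])
  }
  prop
}

external_driver_value <- function(ext, t) {
  0.5 * ext$amplitude * (1 + sin(2 * pi * t / ext$period + ext$phase))
}

#' Simulate a GRN with the Gillespie algorithm
#'
#' Exact stochastic simulation of the jump process with two reaction
#' channels per gene: production `x_i -> x_i + 1` at the rate given by
#' [production_propensity()], and first-order dilution `x_i -> x_i - 1` at
#' rate `decay_i * x_i`.  The trajectory is recorded on a uniform grid by
#' zero-order hold.  With an external (time-dependent) driver the inter-event
#' jump is capped at `grid_step / 10` and propensities are re-evaluated, a
#' documented approximation for the non-homogeneous process.
#'
#' @param spec a [grn_spec()].
#' @param t_max simulation end time (default 10,000).
#' @param grid_step sampling interval (default 10; with the defaults the
#'   grid has 1001 points, extremes included).
#' @param x0 initial counts; default all genes at `floor(K)` of the first
#'   kinetic entry (mid-response start).
#' @param seed integer seed; trajectories are deterministic given the seed.
#' @return An [expression_traces()] object of raw counts.
#' @export
simulate_grn <- function(spec, t_max = 10000, grid_step = 10, x0 = NULL,
                         seed = 1L) {
  stopifnot(inherits(spec, "grn_spec"), t_max > 0, grid_step > 0)
  n <- spec$n_genes
  if (is.null(x0)) x0 <- rep(floor(spec$K[1, 1]), n)
  stopifnot(length(x0) == n, all(x0 >= 0))
  if (all(x0 == 0) && all(spec$basal == 0)) {
    a0 <- sum(vapply(seq_len(n), production_propensity, 0, x = x0, t = 0,
                     spec = spec))
    if (a0 == 0) warning("frozen system: zero state, zero propensities")
  }
  ext <- spec$external
  has_ext <- !is.null(ext)
  X <- with_seed(seed, gillespie_cpp(
    J = spec$J, k = spec$k, krep = spec$k_rep, h = spec$h, K = spec$K,
    decay = spec$decay, basal = spec$basal,
    prod_cap = spec$prod_cap, x0 = as.double(x0),
    t_max = t_max, grid_step = grid_step,
    has_ext = has_ext,
    ext_k = if (has_ext) ext$k else numeric(n),
    ext_amp = if (has_ext) ext$amplitude else 0,
    ext_period = if (has_ext) ext$period else 1,
    ext_phase = if (has_ext) ext$phase else 0,
    ext_h = if (has_ext) ext$h else 1,
    ext_K = if (has_ext) ext$K else 1,
    dt_max = if (has_ext) grid_step / 10 else 0
  ))
  times <- seq(0, t_max, by = grid_step)
  expression_traces(times, X[, seq_along(times), drop = FALSE])
}
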