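#' Default kinetic parameters for the archetypal architectures
#'
#' The defaults define the study conditions of the synthetic benchmark: a
#' common activation/repression rate scale, Hill cooperativity 2, a
#' dissociation constant of 50 molecules, first-order dilution and a small
#' basal (leaky) production.  They were calibrated once so that the
#' autocorrelation time of a fully connected network on the default sampling
#' grid peaks in the tens-of-samples range (see the methods vignette) and are
#' not meant to be tuned per run.
#'
#' @param k activation rate (1/time) on each regulatory edge.
#' @param k_rep repression-branch rate (1/time).
#' @param h Hill cooperativity exponent.
#' @param K dissociation constant (molecule counts).
#' @param decay dilution rate delta (1/time).
#' @param basal_frac basal production as a fraction of `k`.
#' @param prod_cap ceiling on any gene's regulated production rate
#'   (1/time): the expression machinery saturates, bounding copy numbers at
#'   `prod_cap / decay`.
#' @param h_clock cooperativity used on the edges of the oscillatory core
#'   (relaxation oscillations need steep repression).
#' @param k_clock rate scale on the clock-core edges.
#' @param K_clock dissociation constant on the clock-core edges.
#' @param external_period period (time units) of the sinusoidal driver.
#' @param external_k coupling rate from the external driver to each gene.
#' @return A named list of kinetic defaults.
#' @export
default_kinetics <- function(k = 2, k_rep = 2.5, h = 2, K = 50,
                             decay = 0.006, basal_frac = 0.05,
                             prod_cap = 50,
                             h_clock = 6, k_clock = 4, K_clock = 120,
                             external_period = 1000, external_k = 1) {
  list(k = k, k_rep = k_rep, h = h, K = K, decay = decay,
       basal_frac = basal_frac, prod_cap = prod_cap, h_clock = h_clock,
       k_clock = k_clock, K_clock = K_clock,
       external_period = external_period, external_k = external_k)
}

#' Random signed interaction matrix
#'
#' Each off-diagonal entry is independently -1 (repression) with probability
#' `nr`, +1 (activation) with probability `na`, and 0 otherwise.  The
#' diagonal is forced to zero (no self-regulation) unless `self_loops` is
#' set.
#'
#' `nr` and `na` support two conventions: values of at most 1 are
#' per-element probabilities; values above 1 are read as expected counts of
#' regulators per gene and divided by `N`.
#'
#' @param N number of genes.
#' @param nr repressor probability (or expected repressors per gene).
#' @param na activator probability (or expected activators per gene).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param self_loops allow nonzero diagonal entries (default `FALSE`).
#' @return Integer N x N matrix with entries in \{-1, 0, 1\}.
#' @export
random_interaction_matrix <- function(N, nr, na, seed = 1L,
                                      self_loops = FALSE) {
  stopifnot(N >= 1, nr >= 0, na >= 0)
  # counts-per-gene convention whenever the probability reading is
  # impossible (e.g. nr = na = 1 means one regulator of each sign per gene)
  if (nr > 1 || na > 1 || nr + na > 1) {
    nr <- nr / N
    na <- na / N
  }
  if (nr + na > 1) {
    # density saturates at full connectivity, preserving the nr:na ratio
    # (the densest canonical nets request 15 + 15 regulators per 20 genes)
    tot <- nr + na
    nr <- nr / tot
    na <- na / tot
  }
  J <- with_seed(seed, {
    matrix(sample(c(-1L, 1L, 0L), N * N, replace = TRUE,
                  prob = c(nr, na, 1 - nr - na)), N, N)
  })
  if (!self_loops) diag(J) <- 0L
  J
}

#' Canonical architecture manifest
#'
#' The twelve named gene-regulatory-network architectures of the benchmark,
#' with their connectivity parameters (`nr`/`na` in the expected-count
#' convention where above 1).
#'
#' @return A data frame with columns `name`, `class`, `nr`, `na`.
#' @export
canonical_architectures <- function() {
  data.frame(
    name = c("FullyConnected", "FullyRepressed", "MasterRegulator",
             "SparseConnection", "mediumConnection",
             "Oscillating_nr1_na1", "Oscillating_nr5_na5",
             "Oscillating_nr10_na10", "Oscillating_nr15_na15",
             "ExternalSignal_nr1_na1", "ExternalSignal_nr5_na5",
             "ExternalSignal_nr10_na10"),
    class = c("FullyConnected", "FullyRepressed", "MasterRegulator",
              "SparseConnection", "mediumConnection",
              rep("Oscillating", 4), rep("ExternalSignal", 3)),
    nr = c(NA, NA, 1, 1, 5, 1, 5, 10, 15, 1, 5, 10),
    na = c(NA, NA, 1, 1, 5, 1, 5, 10, 15, 1, 5, 10),
    stringsAsFactors = FALSE
  )
}

#' Build an archetypal GRN specification
#'
#' Constructs the ground-truth interaction matrix and kinetic parameters for
#' one of the archetypal architecture classes:
#'
#' * `FullyConnected` - every off-diagonal entry nonzero; signs assigned
#'   activator with probability `na/(na+nr)` (0.5 when both are 0).
#' * `FullyRepressed` - every off-diagonal entry -1.
#' * `MasterRegulator` - gene 1 activates every other gene; remaining pairs
#'   (not involving the hub) are wired at random with `nr`, `na`.
#' * `SparseConnection` / `mediumConnection` - random wiring with small /
#'   intermediate connectivity (defaults: 1 and 5 regulators per gene).
#' * `Oscillating` - a negative-feedback clock core (gene 1 activates gene 2,
#'   gene 2 activates gene 3, gene 3 represses gene 1) plus random wiring of
#'   the peripheral genes; core genes receive no inputs from the periphery so
#'   the clock stays autonomous.
#' * `ExternalSignal` - random internal wiring plus a sinusoidal external
#'   driver coupled to every gene as an activator.
#'
#' `name` may also be a canonical manifest name such as
#' `"Oscillating_nr10_na10"`, in which case `nr`/`na` are taken from the
#' suffix.
#'
#' @inheritParams random_interaction_matrix
#' @param name architecture class or canonical name.
#' @param nr,na connectivity parameters (see
#'   [random_interaction_matrix()]); `NULL` uses the class default.
#' @param params kinetic defaults from [default_kinetics()].
#' @param core_size number of genes in the oscillatory core (default 3).
#' @return A [grn_spec()] labelled with the architecture name.
#' @export
build_architecture <- function(name, N, nr = NULL, na = NULL, seed = 1L,
                               params = default_kinetics(), core_size = 3L) {
  label <- name
  if (grepl("^(Oscillating|ExternalSignal)_nr[0-9]+_na[0-9]+$", name)) {
    m <- regmatches(name, regexec("^([A-Za-z]+)_nr([0-9]+)_na([0-9]+)$", name))[[1]]
    name <- m[2]
    if (is.null(nr)) nr <- as.numeric(m[3])
    if (is.null(na)) na <- as.numeric(m[4])
  }
  classes <- c("FullyConnected", "FullyRepressed", "MasterRegulator",
               "SparseConnection", "mediumConnection", "Oscillating",
               "ExternalSignal")
  if (!name %in% classes) {
    stop(sprintf("unknown architecture '%s'", name))
  }
  defaults <- list(SparseConnection = c(1, 1), mediumConnection = c(5, 5),
                   MasterRegulator = c(1, 1), Oscillating = c(1, 1),
                   ExternalSignal = c(1, 1))
  if (is.null(nr)) nr <- if (name %in% names(defaults)) defaults[[name]][1] else 0
  if (is.null(na)) na <- if (name %in% names(defaults)) defaults[[name]][2] else 0

  external <- NULL
  J <- switch(
    name,
    FullyConnected = {
      p_act <- if (nr + na > 0) na / (na + nr) else 0.5
      J <- with_seed(seed, {
        matrix(sample(c(1L, -1L), N * N, replace = TRUE,
                      prob = c(p_act, 1 - p_act)), N, N)
      })
      diag(J) <- 0L
      J
    },
    FullyRepressed = {
      J <- matrix(-1L, N, N)
      diag(J) <- 0L
      J
    },
    MasterRegulator = {
      J <- matrix(0L, N, N)
      if (N >= 2) {
        sub <- random_interaction_matrix(N - 1L, nr, na,
                                         seed = derive_seed(seed, 1))
        J[2:N, 2:N] <- sub
        J[2:N, 1] <- 1L
        J[1, ] <- 0L
      }
      J
    },
    SparseConnection = random_interaction_matrix(N, nr, na, seed = seed),
    mediumConnection = random_interaction_matrix(N, nr, na, seed = seed),
    Oscillating = {
      if (N < core_size + 1L) {
        stop("Oscillating needs at least core_size + 1 genes")
      }
      J <- random_interaction_matrix(N, nr, na, seed = seed)
      core <- seq_len(core_size)
      J[core, ] <- 0L                       # clock core is autonomous
      for (g in core[-core_size]) J[g + 1L, g] <- 1L
      J[1L, core_size] <- -1L
      J
    },
    ExternalSignal = {
      external <- list(
        waveform = "sine",
        amplitude = params$K, period = params$external_period, phase = 0,
        k = rep(params$external_k, N), h = params$h, K = params$K
      )
      random_interaction_matrix(N, nr, na, seed = seed)
    }
  )

  hmat <- matrix(params$h, N, N)
  kmat <- matrix(params$k, N, N)
  Kmat <- matrix(params$K, N, N)
  krmat <- matrix(params$k_rep, N, N)
  if (name == "Oscillating") {
    # steep, strong clock edges: a three-gene delayed-negative-feedback loop
    # only oscillates with sufficiently cooperative repression
    core <- seq_len(core_size)
    idx <- cbind(c(core[-1L], 1L), core)
    hmat[idx] <- params$h_clock
    kmat[idx] <- params$k_clock
    krmat[idx] <- params$k_clock
    Kmat[idx] <- params$K_clock
  }
  grn_spec(J = J, k = kmat, k_rep = krmat, h = hmat, K = Kmat, tau = 0,
           decay = params$decay, basal = params$basal_frac * params$k,
           prod_cap = if (is.null(params$prod_cap)) Inf else params$prod_cap,
           external = external, label = label)
}
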