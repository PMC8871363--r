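#' Study configuration
#'
#' Bundles everything one end-to-end run needs: the architecture manifest,
#' simulator settings, forecaster configuration, noise grid and the master
#' seed from which every stage seed is derived.  The configuration
#' round-trips through JSON.
#'
#' @param architectures data frame with columns `name`, `N` and optionally
#'   `nr`, `na`; default the twelve canonical architectures at `N = 20`.
#' @param t_max,grid_step simulation span and sampling interval.
#' @param kinetics kinetic defaults from [default_kinetics()].
#' @param darnn a [darnn_config()].
#' @param sigma2_grid noise variances for the robustness scan.
#' @param seed master seed.
#' @param descriptors which attention-graph descriptors to assemble.
#' @return A list of class `study_config`.
#' @export
study_config <- function(architectures = NULL, t_max = 10000, grid_step = 10,
                         kinetics = default_kinetics(),
                         darnn = darnn_config(),
                         sigma2_grid = seq(0.1, 0.9, by = 0.1), seed = 1L,
                         descriptors = c("clustering", "betweenness", "hub")) {
  if (is.null(architectures)) {
    architectures <- canonical_architectures()
    architectures$N <- 20L
  }
  stopifnot(all(c("name", "N") %in% names(architectures)))
  structure(list(architectures = architectures, t_max = t_max,
                 grid_step = grid_step, kinetics = kinetics, darnn = darnn,
                 sigma2_grid = sigma2_grid, seed = as.integer(seed),
                 descriptors = descriptors),
            class = "study_config")
}

#' Run the full study
#'
#' Orchestrates the pipeline: simulate each architecture, standardize the
#' traces, train the parallel forecaster ensemble, extract attention
#' matrices and their graph descriptors, run the noise-response scan, then
#' cluster, ordinate and cross-compare the architecture feature matrices
#' (dendrograms, silhouette partitions, PCA, tree distances, variation of
#' information).  Every artifact is written under `outdir` as TSV / Newick /
#' JSON, and reruns with the same configuration reproduce identical files.
#'
#' @param config a [study_config()].
#' @param outdir output directory (created if missing); `NULL` skips
#'   writing.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with per-architecture results (`traces`,
#'   `models`, `attention`, `rmse`, `noise`), the descriptor matrices, the
#'   comparison objects and the output paths.
#' @export
run_study <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  arch <- config$architectures
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(outdir)) writer(file.path(outdir, name))
  }
  emit("config.json", function(p) {
    plain <- unclass(config)
    plain$darnn <- unclass(plain$darnn)
    jsonlite::write_json(plain, p, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  })

  per_arch <- vector("list", nrow(arch))
  names(per_arch) <- arch$name
  for (a in seq_len(nrow(arch))) {
    nm <- arch$name[a]
    say("architecture %s (%d/%d)", nm, a, nrow(arch))
    spec <- build_architecture(
      nm, N = arch$N[a],
      nr = if ("nr" %in% names(arch) && !is.na(arch$nr[a])) arch$nr[a] else NULL,
      na = if ("na" %in% names(arch) && !is.na(arch$na[a])) arch$na[a] else NULL,
      seed = derive_seed(config$seed, 100, a), params = config$kinetics
    )
    traces <- simulate_grn(spec, t_max = config$t_max,
                           grid_step = config$grid_step,
                           seed = derive_seed(config$seed, 200, a))
    scaled <- standard_scale(traces)
    cfg <- config$darnn
    cfg$seed <- derive_seed(config$seed, 300, a)
    models <- train_parallel(scaled, cfg, verbose = verbose)
    rmse <- rmse_table(models, scaled)
    A <- extract_input_attention(models, scaled)
    nm_mat <- noise_matrix(models, scaled, config$sigma2_grid,
                           seed = derive_seed(config$seed, 400, a))
    per_arch[[a]] <- list(spec = spec, traces = traces, scaled = scaled,
                          models = models, rmse = rmse, attention = A,
                          noise = nm_mat, noise_summary = noise_summary(nm_mat),
                          truth_correlation =
                            suppressWarnings(attention_truth_correlation(A, spec$J)))
    slug <- gsub("[^A-Za-z0-9_]", "_", nm)
    emit(sprintf("traces_%s.tsv", slug),
         function(p) write_traces_tsv(traces, p))
    emit(sprintf("attention_%s.tsv", slug), function(p) {
      write.table(A, p, sep = "\t", quote = FALSE)
    })
    emit(sprintf("noise_mse_%s.tsv", slug), function(p) {
      write.table(as.matrix(per_arch[[a]]$noise), p, sep = "\t", quote = FALSE)
    })
    emit(sprintf("grn_%s.json", slug), function(p) write_grn_json(spec, p))
  }

  # architecture-level feature matrices
  att_list <- lapply(per_arch, `[[`, "attention")
  feat <- list()
  for (d in config$descriptors) {
    feat[[d]] <- assemble_descriptor_matrix(att_list, d)
  }
  feat$noise <- do.call(rbind, lapply(per_arch, function(x) x$noise_summary$feature))
  rownames(feat$noise) <- names(per_arch)

  comparisons <- list()
  newicks <- character(0)
  for (d in names(feat)) {
    hc <- descriptor_hclust(feat[[d]])
    sil <- silhouette_best_k(feat[[d]], hc)
    pca <- descriptor_pca(feat[[d]])
    nwk <- dendrogram_to_newick(hc)
    comparisons[[d]] <- list(hclust = hc, silhouette = sil, pca = pca,
                             newick = nwk)
    newicks[d] <- nwk
    slug <- gsub("[^A-Za-z0-9_]", "_", d)
    emit(sprintf("features_%s.tsv", slug), function(p) {
      write.table(feat[[d]], p, sep = "\t", quote = FALSE)
    })
    emit(sprintf("dendrogram_%s.nwk", slug), function(p) {
      writeLines(nwk, p)
    })
  }

  dn <- names(feat)
  tree_d <- matrix(0, length(dn), length(dn), dimnames = list(dn, dn))
  vi <- matrix(0, length(dn), length(dn), dimnames = list(dn, dn))
  for (i in seq_along(dn)) for (j in seq_along(dn)) {
    if (i < j) {
      tree_d[i, j] <- tree_d[j, i] <-
        tree_distance(newicks[dn[i]], newicks[dn[j]])
      vi[i, j] <- vi[j, i] <- variation_of_information(
        comparisons[[dn[i]]]$silhouette$partition,
        comparisons[[dn[j]]]$silhouette$partition)
    }
  }
  emit("tree_distance.tsv", function(p) {
    write.table(tree_d, p, sep = "\t", quote = FALSE)
  })
  emit("variation_of_information.tsv", function(p) {
    write.table(vi, p, sep = "\t", quote = FALSE)
  })
  rmse_all <- do.call(rbind, lapply(names(per_arch), function(nm) {
    data.frame(network = nm, mean_rmse = attr(per_arch[[nm]]$rmse, "mean"),
               sd_rmse = attr(per_arch[[nm]]$rmse, "sd"))
  }))
  emit("rmse_summary.tsv", function(p) {
    write.table(rmse_all, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  invisible(list(architectures = per_arch, features = feat,
                 comparisons = comparisons, tree_distance = tree_d,
                 variation_of_information = vi, rmse = rmse_all,
                 config = config))
}
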