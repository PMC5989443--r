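#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model behind [generate_cohort()]: samples fall
#' into latent subtypes; each subtype owns a disjoint set of driver genes
#' that its samples mutate at `driver_mut_rate`, on top of uniform
#' passenger noise; the drivers of each subtype form a dense module in an
#' otherwise sparse interaction network; and expression profiles carry a
#' subtype-specific mean shift so that within-subtype sample correlation
#' exceeds between-subtype correlation.
#'
#' @param n_samples,n_genes Cohort dimensions of the mutation matrix.
#' @param n_subtypes Number of latent sample groups.
#' @param drivers_per_subtype Drivers owned by each subtype (disjoint sets).
#' @param driver_mut_rate Probability a sample mutates each of its
#'   subtype's drivers.
#' @param passenger_rate Background per-gene mutation probability.
#' @param module_edge_prob Edge probability within a subtype's driver
#'   module.
#' @param background_edge_prob Edge probability for every other gene pair.
#' @param expr_genes Number of expression genes (independent of the
#'   mutation gene universe).
#' @param subtype_effect Mean expression shift on a subtype's gene block.
#' @param noise_sd Standard deviation of i.i.d. Gaussian expression noise.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 100, n_genes = 300, n_subtypes = 3,
                              drivers_per_subtype = 10, driver_mut_rate = 0.2,
                              passenger_rate = 0.05, module_edge_prob = 0.3,
                              background_edge_prob = 0.01, expr_genes = 500,
                              subtype_effect = 2, noise_sd = 1, seed = 1) {
  probs <- c(driver_mut_rate, passenger_rate, module_edge_prob,
             background_edge_prob)
  stopifnot(n_samples >= 1, n_genes >= 1, n_subtypes >= 1,
            drivers_per_subtype >= 1, all(probs >= 0), all(probs <= 1),
            expr_genes >= 2, noise_sd >= 0)
  structure(as.list(environment())[names(formals(simulation_config))],
            class = "simulation_config")
}

#' Generate a synthetic cohort with planted drivers
#'
#' Draws a coupled mutation matrix, expression matrix and gene network
#' under the model described in [simulation_config()], with the planted
#' driver set as ground truth. Fully deterministic given the seed.
#'
#' @param cfg A `simulation_config`.
#' @return A `synthetic_cohort`: list with `mutation`, `expression`,
#'   `network`, `true_drivers` (a `benchmark_genes`), `subtype_labels`
#'   (named integer vector) and the `config`.
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_drivers <- cfg$n_subtypes * cfg$drivers_per_subtype
  if (n_drivers > cfg$n_genes) {
    stop(sprintf("infeasible config: %d drivers exceed %d genes",
                 n_drivers, cfg$n_genes), call. = FALSE)
  }
  set.seed(cfg$seed)
  n <- cfg$n_samples; p <- cfg$n_genes; S <- cfg$n_subtypes
  sample_ids <- sprintf("s%03d", seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(p))
  subtype <- stats::setNames(rep(seq_len(S), length.out = n), sample_ids)

  # disjoint driver sets: subtype s owns gene block [(s-1)*d+1, s*d]
  driver_of <- split(gene_ids[seq_len(n_drivers)],
                     rep(seq_len(S), each = cfg$drivers_per_subtype))

  X <- matrix(stats::rbinom(n * p, 1, cfg$passenger_rate), n, p,
              dimnames = list(sample_ids, gene_ids))
  for (s in seq_len(S)) {
    rows <- which(subtype == s)
    cols <- match(driver_of[[s]], gene_ids)
    hits <- matrix(stats::rbinom(length(rows) * length(cols), 1,
                                 cfg$driver_mut_rate),
                   length(rows), length(cols))
    X[rows, cols] <- pmax(X[rows, cols], hits)
  }

  # network: dense modules on driver sets, sparse background elsewhere
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  module_id <- integer(p)
  for (s in seq_len(S)) module_id[match(driver_of[[s]], gene_ids)] <- s
  same_module <- module_id[pairs[, 1]] > 0 &
    module_id[pairs[, 1]] == module_id[pairs[, 2]]
  prob <- ifelse(same_module, cfg$module_edge_prob, cfg$background_edge_prob)
  drawn <- stats::runif(nrow(pairs)) < prob
  network <- new_gene_network(
    gene_ids,
    tibble::tibble(from = gene_ids[pairs[drawn, 1]],
                   to = gene_ids[pairs[drawn, 2]])
  )

  # expression: subtype mean shift on a subtype-specific block + noise
  expr_ids <- sprintf("e%04d", seq_len(cfg$expr_genes))
  block <- rep(seq_len(S), length.out = cfg$expr_genes)
  means <- matrix(0, S, cfg$expr_genes)
  for (s in seq_len(S)) means[s, block == s] <- cfg$subtype_effect
  E <- means[subtype, , drop = FALSE] +
    matrix(stats::rnorm(n * cfg$expr_genes, sd = cfg$noise_sd), n,
           cfg$expr_genes)
  dimnames(E) <- list(sample_ids, expr_ids)

  structure(list(
    mutation = X,
    expression = E,
    network = network,
    true_drivers = structure(unlist(driver_of, use.names = FALSE),
                             name = "planted_drivers",
                             class = c("benchmark_genes", "character")),
    subtype_labels = subtype,
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d samples x %d genes, %d subtypes, %d planted drivers>\n",
    nrow(x$mutation), ncol(x$mutation), x$config$n_subtypes,
    length(x$true_drivers)))
  invisible(x)
}

#' Within- versus between-subtype expression correlation
#'
#' Mean pairwise Pearson correlation of expression profiles for sample
#' pairs sharing a subtype versus pairs that do not -- a direct check that
#' the simulated expression carries the subtype structure the
#' sample-similarity prior relies on.
#'
#' @param cohort A `synthetic_cohort` with at least two subtypes.
#' @return One-row tibble: `within_mean`, `between_mean`, `gap`.
#' @export
empirical_similarity_gap <- function(cohort) {
  labels <- cohort$subtype_labels
  if (length(unique(labels)) < 2) {
    stop("similarity gap needs at least two subtypes", call. = FALSE)
  }
  rho <- sample_correlation(cohort$expression)
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(rho)
  tibble::tibble(
    within_mean = mean(rho[ut & same]),
    between_mean = mean(rho[ut & !same]),
    gap = mean(rho[ut & same]) - mean(rho[ut & !same])
  )
}

#' Planted-driver recovery across prior-ablation variants
#'
#' For each replicate seed: generate a cohort, build both priors, fit every
#' requested variant, rank genes by mutation score, and measure the PR-AUC
#' of the planted drivers. Optionally adds the mutation-frequency baseline
#' as a pseudo-variant. Replicate r uses seed `cfg$seed + r - 1` for both
#' the cohort and the factorization initialization.
#'
#' @param cfg A `simulation_config`; its seed is the base seed.
#' @param variants Character vector of variant names (see
#'   [variant_config()]).
#' @param n_seeds Number of replicates.
#' @param fit_cfg Base `crnmf_config` for all variants.
#' @param include_baseline Add a `"frequency"` row per seed?
#' @return Tibble with columns `seed`, `variant`, `auc`.
#' @export
recovery_experiment <- function(cfg = simulation_config(),
                                variants = c("proposed", "only_network",
                                             "only_expression", "no_prior"),
                                n_seeds = 1,
                                fit_cfg = crnmf_config(),
                                include_baseline = FALSE) {
  stopifnot(n_seeds >= 1)
  purrr::map_dfr(seq_len(n_seeds), function(r) {
    seed_r <- cfg$seed + r - 1
    cfg_r <- cfg
    cfg_r$seed <- seed_r
    cohort <- generate_cohort(cfg_r)
    ds <- align_datasets(cohort$mutation, cohort$expression, cohort$network)
    priors <- build_priors(ds)
    freq <- mutation_frequency_scores(ds$mutation)
    rows <- purrr::map_dfr(variants, function(v) {
      vcfg <- variant_config(fit_cfg, v)
      vcfg$seed <- seed_r
      fit <- crnmf(ds, priors, vcfg)
      ranking <- rank_genes(gene_scores(fit), tiebreak_freq = freq,
                            method_label = v)
      tibble::tibble(seed = seed_r, variant = v,
                     auc = pr_auc(precision_recall(ranking, cohort$true_drivers)))
    })
    if (include_baseline) {
      ranking <- rank_genes(freq, method_label = "frequency")
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        seed = seed_r, variant = "frequency",
        auc = pr_auc(precision_recall(ranking, cohort$true_drivers))))
    }
    rows
  })
}

#' Plot a recovery-experiment table
#'
#' @param object Tibble from [recovery_experiment()].
#' @return A ggplot: per-variant PR-AUC distribution across seeds.
#' @export
plot_recovery <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$variant, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "planted-driver PR-AUC")
}
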