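#' Precision-recall sweep over ranking cutoffs
#'
#' Sweeps the cutoff rank r from 1 to p. At each cutoff,
#' precision = TP / r and recall = TP / positives, where TP is the number
#' of benchmark genes in the top r and positives counts benchmark genes
#' present in the scored universe (benchmark genes absent from the ranking
#' are undiscoverable by construction and are dropped).
#'
#' @param ranking A `gene_ranking` tibble.
#' @param benchmark Character vector of benchmark driver genes (e.g. from
#'   [read_gene_list()]).
#' @return A `pr_curve` tibble with columns `rank`, `gene_id`, `hit`, `tp`,
#'   `precision`, `recall`, and attribute `positives`.
#' @export
precision_recall <- function(ranking, benchmark) {
  hit <- ranking$gene_id %in% benchmark
  positives <- sum(hit)
  if (positives == 0) {
    stop("benchmark has no genes in common with the ranked universe", call. = FALSE)
  }
  tp <- cumsum(hit)
  out <- tibble::tibble(
    rank = ranking$rank,
    gene_id = ranking$gene_id,
    hit = hit,
    tp = tp,
    precision = tp / ranking$rank,
    recall = tp / positives
  )
  attr(out, "positives") <- positives
  class(out) <- c("pr_curve", class(out))
  out
}

#' Area under a precision-recall curve
#'
#' Default is the trapezoidal rule over the recall axis, with the point
#' (recall = 0, precision at rank 1) prepended as anchor; consecutive points
#' with equal recall contribute zero width. `"average_precision"` instead
#' averages the precision at each hit rank over the positives.
#'
#' @param curve A `pr_curve` from [precision_recall()].
#' @param method "trapezoid" (default) or "average_precision".
#' @return AUC in \[0, 1\].
#' @export
pr_auc <- function(curve, method = c("trapezoid", "average_precision")) {
  method <- match.arg(method)
  if (method == "average_precision") {
    return(sum(curve$precision[curve$hit]) / attr(curve, "positives"))
  }
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Fisher's exact enrichment of a candidate set
#'
#' One-sided (enrichment) Fisher's exact test of the 2x2 table crossing
#' candidate membership with benchmark membership over the scored gene
#' universe; the p-value is the hypergeometric upper tail
#' P(overlap >= observed). Benchmark genes outside the universe are ignored.
#'
#' @param candidates Character vector of candidate genes, a subset of
#'   `universe`.
#' @param benchmark Character vector of benchmark genes.
#' @param universe Character vector: the full scored gene universe.
#' @return One-row tibble: `cutoff`, `overlap`, `p_value`, and the 2x2
#'   counts `cand_bench`, `cand_only`, `bench_only`, `neither`.
#' @export
fisher_enrichment <- function(candidates, benchmark, universe) {
  candidates <- unique(candidates)
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  if (!all(candidates %in% universe)) {
    stop("candidates must lie within the gene universe", call. = FALSE)
  }
  bench <- intersect(benchmark, universe)
  m <- length(bench)
  N <- length(universe)
  k <- length(candidates)
  overlap <- length(intersect(candidates, bench))
  p_value <- stats::phyper(overlap - 1, m, N - m, k, lower.tail = FALSE)
  tibble::tibble(
    cutoff = k,
    overlap = overlap,
    p_value = p_value,
    cand_bench = overlap,
    cand_only = k - overlap,
    bench_only = m - overlap,
    neither = N - m - (k - overlap)
  )
}

#' Enrichment across standard top-k cutoffs
#'
#' Fisher's exact enrichment of the top-k candidates at each cutoff
#' (default 50, 100, 150, 200).
#'
#' @param ranking A `gene_ranking` tibble.
#' @param benchmark Character vector of benchmark genes.
#' @param cutoffs Integer cutoff ranks.
#' @return Tibble with one row per cutoff.
#' @export
enrichment_table <- function(ranking, benchmark, cutoffs = c(50, 100, 150, 200)) {
  universe <- ranking$gene_id
  purrr::map_dfr(cutoffs, function(k) {
    fisher_enrichment(top_genes(ranking, k), benchmark, universe)
  })
}

#' Exclusive top-k overlap counts between methods
#'
#' For every non-empty subset of the supplied rankings, counts the genes
#' appearing in the top k of exactly that subset -- the cell counts of a
#' Venn diagram over the methods' candidate sets.
#'
#' @param rankings Named list of `gene_ranking` tibbles over one shared
#'   gene universe.
#' @param k Top-k cutoff.
#' @return Tibble with columns `methods` (subset label, "+"-separated),
#'   `n_methods`, `count`.
#' @export
overlap_counts <- function(rankings, k) {
  if (length(rankings) < 2) stop("need at least two rankings", call. = FALSE)
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    names(rankings) <- purrr::map_chr(rankings, function(r) r$method[1])
  }
  universes <- purrr::map(rankings, function(r) sort(r$gene_id))
  if (!all(purrr::map_lgl(universes[-1], identical, universes[[1]]))) {
    stop("rankings do not share a common gene universe", call. = FALSE)
  }
  tops <- purrr::map(rankings, top_genes, k = k)
  all_genes <- unique(unlist(tops))
  membership <- vapply(tops, function(tk) all_genes %in% tk,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(rankings)))
  m <- length(rankings)
  subsets <- purrr::map(seq_len(2^m - 1), function(bits) {
    as.logical(bitwAnd(bits, 2^(seq_len(m) - 1)))
  })
  purrr::map_dfr(subsets, function(sel) {
    exact <- apply(membership, 1, function(row) all(row == sel))
    tibble::tibble(
      methods = paste(names(rankings)[sel], collapse = "+"),
      n_methods = sum(sel),
      count = sum(exact)
    )
  })
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot of precision against recall over the cutoff sweep.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = sprintf("PR curve (AUC = %.3f)", pr_auc(object)))
}
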