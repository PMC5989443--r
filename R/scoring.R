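#' Mutation scores from the fitted gene factor
#'
#' Each gene's score is the maximum of its coefficients across the K latent
#' dimensions. The maximum (rather than the mean) lets a gene that loads
#' strongly on a single latent mutation profile -- a driver for one tumor
#' subset -- score highly even in a heterogeneous cohort.
#'
#' @param fit A `crnmf_fit`, or a nonnegative gene-factor matrix V with
#'   gene rownames.
#' @return Named numeric vector of scores, one per gene.
#' @export
gene_scores <- function(fit) {
  V <- if (inherits(fit, "crnmf_fit")) fit$V else fit
  stopifnot(is.matrix(V), !is.null(rownames(V)))
  apply(V, 1, max)
}

#' Mutation-frequency baseline scores
#'
#' The number of samples in which each gene is mutated (column sums of the
#' binary matrix). Ranking by this count is the baseline any driver
#' prioritization method should beat.
#'
#' @param X Binary mutation matrix, samples in rows.
#' @return Named numeric vector of per-gene mutation counts.
#' @export
mutation_frequency_scores <- function(X) {
  stopifnot(is.matrix(X), all(X %in% c(0, 1)))
  colSums(X)
}

#' Rank genes by score
#'
#' Stable descending sort by score. Ties are broken by higher mutation
#' frequency when supplied, then lexicographically by gene id, so the
#' ranking is deterministic and invariant to input order.
#'
#' @param scores Numeric score vector.
#' @param gene_ids Gene identifiers; defaults to `names(scores)`.
#' @param tiebreak_freq Optional per-gene mutation frequencies for
#'   tie-breaking (same length/order as `scores`).
#' @param method_label Label stored in the `method` column.
#' @return A `gene_ranking` tibble with columns `rank`, `gene_id`, `score`,
#'   `method`, sorted with scores non-increasing.
#' @export
rank_genes <- function(scores, gene_ids = names(scores),
                       tiebreak_freq = NULL, method_label = "crnmf") {
  if (length(scores) != length(gene_ids)) {
    stop("scores and gene_ids must have the same length", call. = FALSE)
  }
  if (!is.null(tiebreak_freq) && length(tiebreak_freq) != length(scores)) {
    stop("tiebreak_freq must match scores in length", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates", call. = FALSE)
  freq <- if (is.null(tiebreak_freq)) rep(0, length(scores)) else tiebreak_freq
  ord <- order(-scores, -freq, gene_ids)
  out <- tibble::tibble(
    rank = seq_along(scores),
    gene_id = gene_ids[ord],
    score = unname(scores[ord]),
    method = method_label
  )
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Top-k candidate set of a ranking
#'
#' The first `k` gene ids in rank order; with the default k = 200 these are
#' the driver-gene candidates handed to enrichment analysis.
#'
#' @param ranking A `gene_ranking` tibble.
#' @param k Number of candidates; must not exceed the ranking length.
#' @return Character vector of `k` gene ids.
#' @export
top_genes <- function(ranking, k = 200) {
  if (k < 1 || k > nrow(ranking)) {
    stop(sprintf("k = %d out of range for a ranking of %d genes", k,
                 nrow(ranking)), call. = FALSE)
  }
  ranking$gene_id[seq_len(k)]
}
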