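#' Sample-sample expression correlation
#'
#' Correlation between every pair of sample expression profiles, the raw
#' material for the similarity kernel. A constant profile (zero variance)
#' has undefined correlation and is rejected rather than silently imputed.
#'
#' @param expression Numeric matrix, samples in rows, genes in columns.
#' @param method "pearson" (default) or "spearman".
#' @return Symmetric n-by-n correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(expression, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(expression) < 2) {
    stop("need at least 2 expression genes to correlate samples", call. = FALSE)
  }
  sds <- apply(expression, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant expression profile for sample '%s': correlation undefined",
                 rownames(expression)[which(sds == 0)[1]]), call. = FALSE)
  }
  rho <- stats::cor(t(expression), method = method)
  diag(rho) <- 1
  (rho + t(rho)) / 2
}

#' Gaussian similarity kernel from sample correlations
#'
#' Maps a correlation matrix to the sample-similarity kernel
#' \deqn{W_{ij} = \exp\{-|1-\rho_{ij}|^2 / (2\sigma^2)\},}
#' so perfectly correlated samples have similarity 1 and the similarity
#' falls off with the bandwidth \eqn{\sigma} as correlation drops. The
#' degree matrix (row sums) and un-normalized Laplacian \eqn{L_W = D_W - W}
#' are computed alongside; this sample-side Laplacian is deliberately left
#' un-normalized.
#'
#' @param rho Symmetric correlation matrix with unit diagonal.
#' @param sigma Positive bandwidth; default 1.
#' @return A `sample_similarity` object: list with `W`, `D_W` (diagonal
#'   matrix), `L_W`, `sigma`, `rho`.
#' @export
similarity_from_correlation <- function(rho, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  if (max(abs(rho - t(rho))) > 1e-8 || max(abs(diag(rho) - 1)) > 1e-8) {
    stop("rho must be symmetric with unit diagonal", call. = FALSE)
  }
  W <- exp(-abs(1 - rho)^2 / (2 * sigma^2))
  W <- (W + t(W)) / 2
  lap <- graph_laplacian(W)
  structure(list(W = W, D_W = lap$D, L_W = lap$L, sigma = sigma, rho = rho),
            class = "sample_similarity")
}

#' @export
print.sample_similarity <- function(x, ...) {
  cat(sprintf("<sample_similarity: %d samples, sigma = %g>\n", nrow(x$W), x$sigma))
  invisible(x)
}

#' Degree matrix and un-normalized graph Laplacian
#'
#' For a symmetric nonnegative similarity/adjacency matrix S, returns the
#' diagonal degree matrix D (row sums) and L = D - S. No normalization is
#' applied.
#'
#' @param S Symmetric numeric matrix.
#' @return List with `D` and `L`.
#' @export
graph_laplacian <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    stop("S must be a symmetric square matrix", call. = FALSE)
  }
  D <- diag(rowSums(S), nrow = nrow(S))
  dimnames(D) <- dimnames(S)
  list(D = D, L = D - S)
}

#' Network adjacency priors with symmetric normalization
#'
#' Assembles the binary adjacency A over `gene_ids` (in that order), its
#' degree matrix, the symmetrically normalized adjacency
#' \eqn{\hat A = D_A^{-1/2} A D_A^{-1/2}} and the normalized Laplacian
#' \eqn{\hat L = I - \hat A}. Under this normalization the gene-side degree
#' matrix reduces to the identity, which is how the factorization updates
#' use it. Genes with no edges get the convention \eqn{d^{-1/2} = 0}: their
#' rows and columns of \eqn{\hat A} are zero, so the gene-side graph term
#' acts as a pure ridge on their representations.
#'
#' @param network A `gene_network` whose edges fall within `gene_ids`.
#' @param gene_ids Ordered, duplicate-free gene universe.
#' @return A `network_priors` object: list with `A`, `D_A`, `A_hat`,
#'   `L_hat` and `degree` (vector of raw degrees).
#' @export
build_network_priors <- function(network, gene_ids) {
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates", call. = FALSE)
  outside <- setdiff(unique(c(network$edges$from, network$edges$to)), gene_ids)
  if (length(outside) > 0) {
    stop(sprintf("network edge endpoint '%s' not in gene_ids", outside[1]), call. = FALSE)
  }
  p <- length(gene_ids)
  A <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
  if (nrow(network$edges) > 0) {
    i <- match(network$edges$from, gene_ids)
    j <- match(network$edges$to, gene_ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  deg <- rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A_hat <- A * outer(inv_sqrt, inv_sqrt)
  L_hat <- diag(p) - A_hat
  dimnames(L_hat) <- dimnames(A)
  structure(list(A = A, D_A = diag(deg, nrow = p), A_hat = A_hat,
                 L_hat = L_hat, degree = deg),
            class = "network_priors")
}

#' @export
print.network_priors <- function(x, ...) {
  cat(sprintf("<network_priors: %d genes, %d edges, %d isolated>\n",
              nrow(x$A), sum(x$A) / 2, sum(x$degree == 0)))
  invisible(x)
}

#' Build both priors for an aligned dataset
#'
#' Convenience wrapper: expression correlation -> similarity kernel on the
#' sample side, and normalized network adjacency/Laplacian on the gene side.
#'
#' @param aligned An `aligned_dataset` from [align_datasets()].
#' @param sigma Kernel bandwidth, default 1.
#' @param cor_method Correlation type, "pearson" (default) or "spearman".
#' @return A `priors_bundle`: list with `sample` (`sample_similarity`) and
#'   `gene` (`network_priors`).
#' @export
build_priors <- function(aligned, sigma = 1, cor_method = "pearson") {
  stopifnot(inherits(aligned, "aligned_dataset"))
  rho <- sample_correlation(aligned$expression, method = cor_method)
  structure(list(
    sample = similarity_from_correlation(rho, sigma = sigma),
    gene = build_network_priors(aligned$network, colnames(aligned$mutation))
  ), class = "priors_bundle")
}

#' @export
print.priors_bundle <- function(x, ...) {
  cat("<priors_bundle>\n")
  print(x$sample)
  print(x$gene)
  invisible(x)
}
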