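#' Read a binary somatic mutation matrix
#'
#' Loads a tab-separated sample-by-gene mutation matrix. The first row is a
#' header of gene identifiers (its first cell, naming the sample column, may
#' be blank or any label such as "sample"); the first column holds sample
#' identifiers; every body cell must be exactly 0 or 1.
#'
#' @param path Path to a TSV file.
#' @return A binary numeric matrix with samples as rownames and genes as
#'   colnames, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tg1\tg2", "s1\t1\t0", "s2\t0\t1"), tf)
#' read_mutation_matrix(tf)
read_mutation_matrix <- function(path) {
  x <- read_matrix_tsv(path, what = "mutation matrix")
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary cell in mutation matrix '%s': value %s at sample '%s', gene '%s'",
      path, format(x[bad[1, 1], bad[1, 2]]),
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]
    ), call. = FALSE)
  }
  x
}

#' Read a real-valued expression matrix
#'
#' Same TSV layout as [read_mutation_matrix()]: gene-id header, sample-id
#' first column, real-valued body. Expression is assumed already normalized
#' upstream. Any missing or non-finite cell is a load error.
#'
#' @inheritParams read_mutation_matrix
#' @return A numeric matrix, samples in rows, genes in columns.
#' @export
read_expression_matrix <- function(path) {
  read_matrix_tsv(path, what = "expression matrix")
}

# Shared strict TSV matrix loader: rejects duplicates and non-finite cells,
# names the offending row/column in the error.
read_matrix_tsv <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop(sprintf("%s '%s': no gene columns", what, path), call. = FALSE)
  sample_ids <- df[[1]]
  gene_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("%s '%s': duplicate sample id '%s'", what, path,
                 sample_ids[duplicated(sample_ids)][1]), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("%s '%s': duplicate gene id '%s'", what, path,
                 gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "%s '%s': non-numeric or missing cell '%s' at sample '%s', gene '%s'",
      what, path, body[bad[1, 1], bad[1, 2]],
      sample_ids[bad[1, 1]], gene_ids[bad[1, 2]]
    ), call. = FALSE)
  }
  dimnames(num) <- list(sample_ids, gene_ids)
  num
}

#' Write a sample-by-gene matrix as TSV
#'
#' Inverse of [read_mutation_matrix()] / [read_expression_matrix()]: header
#' cell "sample", then gene ids; one row per sample.
#'
#' @param x Numeric matrix with sample rownames and gene colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("sample", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an undirected gene interaction network from an edge list
#'
#' Each non-comment line holds at least two whitespace- or tab-separated
#' gene identifiers; extra columns (e.g. interaction type or confidence) are
#' ignored. Lines starting with "#" and blank lines are skipped. Self-loops
#' are stripped and duplicate edges (in either orientation) collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A `gene_network`: list with `gene_ids` (character, first-seen
#'   order) and `edges` (tibble with columns `from`, `to`, each row an
#'   unordered pair stored with `from` < `to` lexicographically).
#' @export
read_network_edgelist <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("network file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop(sprintf("malformed network line %d in '%s': fewer than 2 columns",
                 idx[which(nf < 2)[1]], path), call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  gene_ids <- unique(c(rbind(from, to)))
  keep_e <- from != to
  a <- pmin(from[keep_e], to[keep_e])
  b <- pmax(from[keep_e], to[keep_e])
  dup <- duplicated(paste(a, b, sep = "\r"))
  new_gene_network(gene_ids, tibble::tibble(from = a[!dup], to = b[!dup]))
}

new_gene_network <- function(gene_ids, edges) {
  structure(list(gene_ids = gene_ids, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network: %d genes, %d undirected edges>\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Write a gene network as a two-column edge list
#'
#' Isolated genes (no incident edges) are preserved as comment lines
#' `# node <id>` so that a write/read round trip keeps the gene universe.
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  touched <- unique(c(net$edges$from, net$edges$to))
  isolated <- setdiff(net$gene_ids, touched)
  lines <- paste(net$edges$from, net$edges$to, sep = "\t")
  if (length(isolated) > 0) lines <- c(lines, paste("# node", isolated))
  writeLines(lines, path)
  invisible(path)
}

# read_network_edgelist drops "# node" comments; reader that restores them.
read_network_nodes <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^# node (\\S+)$", lines))
  unlist(lapply(m, function(x) if (length(x) == 2) x[2] else character(0)))
}

#' Read a benchmark gene list
#'
#' One gene identifier per line; blank lines and "#" comments ignored;
#' duplicates collapsed. An empty result is an error.
#'
#' @param path Path to the list file.
#' @param name Label for the set; defaults to the file name without extension.
#' @return A `benchmark_genes` object: character vector of unique ids with a
#'   `name` attribute.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("gene list file not found: '%s'", path), call. = FALSE)
  }
  lines <- trimws(readLines(path))
  genes <- unique(lines[!grepl("^(#|$)", lines)])
  if (length(genes) == 0) {
    stop(sprintf("gene list '%s' contains no gene identifiers", path), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  structure(genes, name = name, class = c("benchmark_genes", "character"))
}

#' @export
print.benchmark_genes <- function(x, ...) {
  cat(sprintf("<benchmark_genes '%s': %d genes>\n", attr(x, "name"), length(x)))
  invisible(x)
}

#' Write a gene list, one identifier per line
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Align mutation, expression and network onto common universes
#'
#' Samples are intersected between the mutation and expression matrices
#' (kept in mutation-file order); the gene universe is the mutation matrix's
#' gene set; network edges are restricted to that universe, with genes that
#' lose all edges kept as isolated nodes so that every mutated gene can be
#' scored. Expression genes are left untouched -- they only feed the
#' sample-sample correlation.
#'
#' @param mutation Binary matrix from [read_mutation_matrix()].
#' @param expression Numeric matrix from [read_expression_matrix()].
#' @param network A `gene_network`.
#' @return An `aligned_dataset`: list with `mutation`, `expression`,
#'   `network` and a `provenance` tibble counting dropped samples/edges.
#' @export
align_datasets <- function(mutation, expression, network) {
  samples <- intersect(rownames(mutation), rownames(expression))
  if (length(samples) == 0) {
    stop("no samples shared between mutation and expression matrices", call. = FALSE)
  }
  samples <- rownames(mutation)[rownames(mutation) %in% samples]
  genes <- colnames(mutation)
  in_universe <- network$edges$from %in% genes & network$edges$to %in% genes
  net <- new_gene_network(genes, network$edges[in_universe, ])
  provenance <- tibble::tibble(
    dropped_mutation_samples = nrow(mutation) - length(samples),
    dropped_expression_samples = nrow(expression) - length(samples),
    dropped_network_edges = sum(!in_universe),
    dropped_network_genes = length(setdiff(network$gene_ids, genes))
  )
  structure(list(
    mutation = mutation[samples, , drop = FALSE],
    expression = expression[samples, , drop = FALSE],
    network = net,
    provenance = provenance
  ), class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf(
    "<aligned_dataset: %d samples, %d mutated genes, %d expression genes, %d network edges>\n",
    nrow(x$mutation), ncol(x$mutation), ncol(x$expression), nrow(x$network$edges)))
  invisible(x)
}

#' Write a ranked gene list as TSV
#'
#' Columns `rank` (1-based), `gene_id`, `score`; scores printed with six
#' significant digits; row order preserved.
#'
#' @param ranking Tibble from [rank_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(all(c("rank", "gene_id", "score") %in% names(ranking)))
  header <- "rank\tgene_id\tscore"
  if (nrow(ranking) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- paste(ranking$rank, ranking$gene_id,
                formatC(ranking$score, format = "g", digits = 6), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a ranking written by [write_ranking()]
#' @param path Path to the ranking TSV.
#' @return Tibble with columns `rank`, `gene_id`, `score`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c("integer", "character", "numeric"))
  tibble::as_tibble(df)
}
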