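# Independent oracles: explicit-loop implementations kept deliberately free
# of the matrix identities used inside the package.

# Term-by-term objective via double loops (no trace/norm shortcuts).
brute_objective <- function(X, U, V, priors, cfg) {
  n <- nrow(X); p <- ncol(X); K <- ncol(U)
  recon <- 0
  for (i in seq_len(n)) for (j in seq_len(p)) {
    xhat <- 0
    for (k in seq_len(K)) xhat <- xhat + U[i, k] * V[j, k]
    recon <- recon + (X[i, j] - xhat)^2
  }
  LW <- priors$sample$L_W
  tr_u <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dot <- 0
    for (k in seq_len(K)) dot <- dot + U[i, k] * U[j, k]
    tr_u <- tr_u + dot * LW[i, j]
  }
  LH <- priors$gene$L_hat
  tr_v <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    dot <- 0
    for (k in seq_len(K)) dot <- dot + V[i, k] * V[j, k]
    tr_v <- tr_v + dot * LH[i, j]
  }
  ridge_u <- 0
  for (i in seq_len(n)) for (k in seq_len(K)) ridge_u <- ridge_u + U[i, k]^2
  sparse_v <- 0
  for (k in seq_len(K)) {
    s <- 0
    for (j in seq_len(p)) s <- s + abs(V[j, k])
    sparse_v <- sparse_v + s^2
  }
  recon + cfg$lambda_lu * tr_u + cfg$lambda_ru * ridge_u +
    cfg$lambda_lv * tr_v + cfg$lambda_rv * sparse_v
}

# Classical multiplicative NMF (Lee-Seung) step, loop implementation with the
# same denominator guard convention.
lee_seung_step <- function(X, U, V, eps = 1e-12) {
  n <- nrow(X); p <- ncol(X); K <- ncol(U)
  VtV <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    for (j in seq_len(p)) VtV[a, b] <- VtV[a, b] + V[j, a] * V[j, b]
  }
  U2 <- U
  for (i in seq_len(n)) for (k in seq_len(K)) {
    num <- 0
    for (j in seq_len(p)) num <- num + X[i, j] * V[j, k]
    den <- 0
    for (a in seq_len(K)) den <- den + U[i, a] * VtV[a, k]
    U2[i, k] <- U[i, k] * num / (den + eps)
  }
  UtU <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    for (i in seq_len(n)) UtU[a, b] <- UtU[a, b] + U2[i, a] * U2[i, b]
  }
  V2 <- V
  for (j in seq_len(p)) for (k in seq_len(K)) {
    num <- 0
    for (i in seq_len(n)) num <- num + X[i, j] * U2[i, k]
    den <- 0
    for (a in seq_len(K)) den <- den + V[j, a] * UtU[a, k]
    V2[j, k] <- V[j, k] * num / (den + eps)
  }
  list(U = U2, V = V2)
}

# Pearson correlation of two vectors from first principles.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Precision/recall by set enumeration at every cutoff.
enum_pr <- function(gene_order, benchmark) {
  positives <- length(intersect(gene_order, benchmark))
  prec <- rec <- numeric(length(gene_order))
  for (r in seq_along(gene_order)) {
    tp <- length(intersect(gene_order[seq_len(r)], benchmark))
    prec[r] <- tp / r
    rec[r] <- tp / positives
  }
  list(precision = prec, recall = rec, positives = positives)
}

# Trapezoid AUC over the recall axis with a (0, precision@1) anchor.
enum_auc <- function(precision, recall) {
  r <- c(0, recall)
  p <- c(precision[1], precision)
  a <- 0
  for (i in seq_len(length(r) - 1)) {
    a <- a + (r[i + 1] - r[i]) * (p[i] + p[i + 1]) / 2
  }
  a
}

# Hypergeometric upper tail P(X >= overlap) by full enumeration.
enum_hyper_tail <- function(overlap, n_bench, n_universe, n_drawn) {
  total <- choose(n_universe, n_drawn)
  s <- 0
  for (x in seq(overlap, min(n_bench, n_drawn))) {
    s <- s + choose(n_bench, x) * choose(n_universe - n_bench, n_drawn - x)
  }
  s / total
}

# Random factorization instance: binary X plus priors built from a random
# expression matrix and a random gene network.
random_instance <- function(n, p, K, seed, density = 0.3) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, density), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(p))))
  E <- matrix(rnorm(n * 8), n, 8, dimnames = list(rownames(X), paste0("e", 1:8)))
  n_edges <- max(1, rbinom(1, p * (p - 1) / 2, 0.2))
  pair_idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  sel <- sample(nrow(pair_idx), min(n_edges, nrow(pair_idx)))
  net <- drivernmf:::new_gene_network(
    colnames(X),
    tibble::tibble(from = colnames(X)[pair_idx[sel, 1]],
                   to = colnames(X)[pair_idx[sel, 2]]))
  priors <- structure(list(
    sample = similarity_from_correlation(sample_correlation(E)),
    gene = build_network_priors(net, colnames(X))
  ), class = "priors_bundle")
  U <- matrix(runif(n * K, 0.1, 1.1), n, K)
  V <- matrix(runif(p * K, 0.1, 1.1), p, K)
  list(X = X, E = E, net = net, priors = priors, U = U, V = V)
}

# Gradient split of the objective: list of positive and negative parts for
# U and V; their difference is the exact gradient (factor 2 dropped on both
# sides, irrelevant to stationarity checks).
gradient_parts <- function(X, U, V, priors, cfg) {
  list(
    u_neg = X %*% V + cfg$lambda_lu * (priors$sample$W %*% U),
    u_pos = U %*% crossprod(V) + cfg$lambda_lu * (diag(priors$sample$D_W) * U) +
      cfg$lambda_ru * U,
    v_neg = crossprod(X, U) + cfg$lambda_lv * (priors$gene$A_hat %*% V),
    v_pos = V %*% crossprod(U) + cfg$lambda_lv * V +
      cfg$lambda_rv * matrix(colSums(V), nrow(V), ncol(V), byrow = TRUE)
  )
}
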