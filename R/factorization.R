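#' Factorization configuration
#'
#' Settings for the robust sparse co-regularized NMF solver. Defaults follow
#' the method's stated settings: K = 4 latent dimensions and all four tuning
#' parameters equal to 1.
#'
#' @param K Number of latent dimensions (>= 1).
#' @param lambda_lu Weight of the sample-graph smoothness term
#'   Tr(U' L_W U).
#' @param lambda_ru Weight of the robustness (ridge) term ||U||_F^2.
#' @param lambda_lv Weight of the gene-graph smoothness term
#'   Tr(V' L_hat V).
#' @param lambda_rv Weight of the sparsity term, the squared L1 norm of each
#'   column of V.
#' @param max_iter Maximum alternating iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed for the random initialization.
#' @param eps_guard Tiny positive constant added to update denominators.
#' @return A `crnmf_config` list.
#' @export
crnmf_config <- function(K = 4, lambda_lu = 1, lambda_ru = 1,
                         lambda_lv = 1, lambda_rv = 1,
                         max_iter = 1000, tol = 1e-6, seed = 1,
                         eps_guard = 1e-12) {
  stopifnot(K >= 1, lambda_lu >= 0, lambda_ru >= 0, lambda_lv >= 0,
            lambda_rv >= 0, max_iter >= 1, tol > 0, eps_guard > 0)
  structure(list(K = as.integer(K), lambda_lu = lambda_lu,
                 lambda_ru = lambda_ru, lambda_lv = lambda_lv,
                 lambda_rv = lambda_rv, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed), eps_guard = eps_guard),
            class = "crnmf_config")
}

#' Prior-ablation variants of a configuration
#'
#' The four configurations compared in prior-information ablations:
#' \describe{
#'   \item{proposed}{the base configuration, both priors active;}
#'   \item{only_network}{sample-side terms off (`lambda_lu = lambda_ru = 0`),
#'     keeping only the gene-network prior;}
#'   \item{only_expression}{gene-side terms off (`lambda_lv = lambda_rv = 0`),
#'     keeping only the expression-similarity prior;}
#'   \item{no_prior}{all four tuning parameters zero -- plain NMF.}
#' }
#'
#' @param base A `crnmf_config`.
#' @param variant One of "proposed", "only_network", "only_expression",
#'   "no_prior".
#' @return A `crnmf_config`.
#' @export
variant_config <- function(base, variant = c("proposed", "only_network",
                                             "only_expression", "no_prior")) {
  variant <- match.arg(variant)
  cfg <- base
  if (variant %in% c("only_network", "no_prior")) {
    cfg$lambda_lu <- 0
    cfg$lambda_ru <- 0
  }
  if (variant %in% c("only_expression", "no_prior")) {
    cfg$lambda_lv <- 0
    cfg$lambda_rv <- 0
  }
  cfg
}

#' Five-term factorization objective
#'
#' \deqn{J = \|X - UV^T\|_F^2 + \lambda_{LU}\,\mathrm{Tr}(U^T L_W U)
#'   + \lambda_{RU}\,\|U\|_F^2 + \lambda_{LV}\,\mathrm{Tr}(V^T \hat L V)
#'   + \lambda_{RV} \sum_k \big(\sum_j |v_{jk}|\big)^2}
#'
#' @param X Binary mutation matrix (n x p).
#' @param U Nonnegative sample factor (n x K).
#' @param V Nonnegative gene factor (p x K).
#' @param priors A `priors_bundle`.
#' @param cfg A `crnmf_config`.
#' @return The nonnegative objective value.
#' @export
crnmf_objective <- function(X, U, V, priors, cfg) {
  check_factor_shapes(X, U, V, priors)
  R <- X - U %*% t(V)
  sum(R^2) +
    cfg$lambda_lu * sum(U * (priors$sample$L_W %*% U)) +
    cfg$lambda_ru * sum(U^2) +
    cfg$lambda_lv * sum(V * (priors$gene$L_hat %*% V)) +
    cfg$lambda_rv * sum(colSums(abs(V))^2)
}

check_factor_shapes <- function(X, U, V, priors) {
  if (nrow(U) != nrow(X) || nrow(V) != ncol(X) || ncol(U) != ncol(V)) {
    stop(sprintf(
      "factor shape mismatch: X is %dx%d, U is %dx%d, V is %dx%d",
      nrow(X), ncol(X), nrow(U), ncol(U), nrow(V), ncol(V)), call. = FALSE)
  }
  if (nrow(priors$sample$W) != nrow(X) || nrow(priors$gene$A_hat) != ncol(X)) {
    stop("priors dimensions do not match X", call. = FALSE)
  }
  invisible(TRUE)
}

#' One multiplicative update of the sample factor U
#'
#' \deqn{U_{ij} \leftarrow U_{ij}
#'   \frac{(XV + \lambda_{LU} W U)_{ij}}
#'        {(U V^T V + \lambda_{LU} D_W U + \lambda_{RU} U + \epsilon)_{ij}}}
#' Nonnegativity is preserved; zero entries stay zero.
#'
#' @inheritParams crnmf_objective
#' @return Updated U.
#' @export
update_u <- function(X, U, V, priors, cfg) {
  dW <- diag(priors$sample$D_W)
  num <- X %*% V + cfg$lambda_lu * (priors$sample$W %*% U)
  den <- U %*% crossprod(V) + cfg$lambda_lu * (dW * U) + cfg$lambda_ru * U
  U * num / (den + cfg$eps_guard)
}

#' One multiplicative update of the gene factor V
#'
#' \deqn{V_{ij} \leftarrow V_{ij}
#'   \frac{(X^T U + \lambda_{LV} \hat A V)_{ij}}
#'        {(V U^T U + \lambda_{LV} V + \lambda_{RV} E V + \epsilon)_{ij}}}
#' where E is the p-by-p all-ones matrix, so (EV) is the column sums of V
#' broadcast to every row (computed that way, E is never materialized), and
#' the normalized gene-side degree matrix is the identity.
#'
#' @inheritParams crnmf_objective
#' @return Updated V.
#' @export
update_v <- function(X, U, V, priors, cfg) {
  num <- crossprod(X, U) + cfg$lambda_lv * (priors$gene$A_hat %*% V)
  ones_V <- matrix(colSums(V), nrow = nrow(V), ncol = ncol(V), byrow = TRUE)
  den <- V %*% crossprod(U) + cfg$lambda_lv * V + cfg$lambda_rv * ones_V
  V * num / (den + cfg$eps_guard)
}

#' Fit robust sparse co-regularized NMF
#'
#' Alternates the multiplicative updates of U and V from a seeded,
#' strictly positive uniform(0.1, 1.1) initialization, recording the
#' objective after each full sweep, until the relative objective change
#' drops below `tol` or `max_iter` is reached. The multiplicative form
#' guarantees the factors stay nonnegative and the objective is
#' non-increasing.
#'
#' @param data An `aligned_dataset` (or a bare binary matrix X with
#'   dimnames).
#' @param priors A `priors_bundle` matching `data`.
#' @param cfg A `crnmf_config`; defaults to `crnmf_config()`.
#' @return A `crnmf_fit` object: list with factors `U` (samples x K) and
#'   `V` (genes x K), `objective_trace` (value after each iteration,
#'   preceded by the initial objective), `n_iter`, `converged`, and the
#'   `config` used.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_samples = 30, n_genes = 40,
#'   expr_genes = 50, seed = 7))
#' ds <- align_datasets(cohort$mutation, cohort$expression, cohort$network)
#' fit <- crnmf(ds, build_priors(ds), crnmf_config(K = 2, max_iter = 50))
#' glance(fit)
crnmf <- function(data, priors, cfg = crnmf_config()) {
  X <- if (inherits(data, "aligned_dataset")) data$mutation else data
  stopifnot(is.matrix(X), all(X %in% c(0, 1)))
  n <- nrow(X); p <- ncol(X); K <- cfg$K
  set.seed(cfg$seed)
  U <- matrix(stats::runif(n * K, 0.1, 1.1), n, K)
  V <- matrix(stats::runif(p * K, 0.1, 1.1), p, K)
  rownames(U) <- rownames(X); rownames(V) <- colnames(X)
  obj <- crnmf_objective(X, U, V, priors, cfg)
  trace <- numeric(cfg$max_iter + 1)
  trace[1] <- obj
  converged <- FALSE
  iter <- 0
  while (iter < cfg$max_iter) {
    iter <- iter + 1
    U <- update_u(X, U, V, priors, cfg)
    V <- update_v(X, U, V, priors, cfg)
    new_obj <- crnmf_objective(X, U, V, priors, cfg)
    trace[iter + 1] <- new_obj
    if (abs(obj - new_obj) / max(obj, .Machine$double.xmin) < cfg$tol) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  structure(list(U = U, V = V, objective_trace = trace[seq_len(iter + 1)],
                 n_iter = iter, converged = converged, config = cfg),
            class = "crnmf_fit")
}

#' @export
print.crnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<crnmf_fit: %d samples x %d genes, K = %d; %d iterations, %s; objective %.6g>\n",
    nrow(x$U), nrow(x$V), x$config$K, x$n_iter,
    if (x$converged) "converged" else "not converged",
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the gene factor of a fitted model
#'
#' One row per gene and latent dimension with the loading, plus each gene's
#' mutation score (its maximum loading across dimensions).
#'
#' @param x A `crnmf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `dimension`, `loading`, `score`.
#' @method tidy crnmf_fit
#' @export
tidy.crnmf_fit <- function(x, ...) {
  V <- x$V
  tibble::tibble(
    gene_id = rep(rownames(V), times = ncol(V)),
    dimension = rep(seq_len(ncol(V)), each = nrow(V)),
    loading = as.vector(V),
    score = rep(apply(V, 1, max), times = ncol(V))
  )
}

#' One-row fit summary
#'
#' @param x A `crnmf_fit`.
#' @param ... Unused.
#' @return A tibble with the final objective, iteration count, convergence
#'   flag and the configuration's key parameters.
#' @method glance crnmf_fit
#' @export
glance.crnmf_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter,
    converged = x$converged,
    K = x$config$K,
    lambda_lu = x$config$lambda_lu,
    lambda_ru = x$config$lambda_ru,
    lambda_lv = x$config$lambda_lv,
    lambda_rv = x$config$lambda_rv
  )
}

#' Objective-trace plot for a fitted model
#'
#' @param object A `crnmf_fit`.
#' @param ... Unused.
#' @return A ggplot of objective value against iteration (log10 y scale).
#' @method autoplot crnmf_fit
#' @export
autoplot.crnmf_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective",
                  title = "Multiplicative-update objective trace")
}
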