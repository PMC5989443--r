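# 1x1 priors with no graph structure: W = [1] so L_W = [0]; empty network.
tiny_priors <- function() {
  structure(list(
    sample = similarity_from_correlation(matrix(1, 1, 1)),
    gene = build_network_priors(
      drivernmf:::new_gene_network("g1", tibble::tibble(from = character(0),
                                                        to = character(0))),
      "g1")
  ), class = "priors_bundle")
}

lambda0 <- function(...) crnmf_config(lambda_lu = 0, lambda_ru = 0,
                                      lambda_lv = 0, lambda_rv = 0, ...)

test_that("objective reduces correctly in closed-form corner cases", {
  inst <- random_instance(5, 6, 2, seed = 1)
  U0 <- matrix(0, 5, 2); V0 <- matrix(0, 6, 2)
  expect_equal(crnmf_objective(inst$X, U0, V0, inst$priors, crnmf_config(K = 2)),
               sum(inst$X))

  # exact factorization with no regularization scores zero
  U <- matrix(c(1, 2, 0.5), 3, 1)
  V <- matrix(c(1, 0, 3), 3, 1)
  X <- U %*% t(V)
  dimnames(X) <- list(paste0("s", 1:3), paste0("g", 1:3))
  inst3 <- random_instance(3, 3, 1, seed = 2)
  expect_equal(crnmf_objective(X, U, V, inst3$priors, lambda0(K = 1)), 0)

  expect_error(crnmf_objective(inst$X, U0[1:3, ], V0, inst$priors,
                               crnmf_config(K = 2)), "shape mismatch")
})

test_that("U update matches hand arithmetic and structural properties", {
  pri <- tiny_priors()
  X <- matrix(2, 1, 1); U <- matrix(1, 1, 1); V <- matrix(1, 1, 1)
  expect_equal(update_u(X, U, V, pri, lambda0(K = 1)), matrix(2, 1, 1),
               tolerance = 1e-9, ignore_attr = TRUE)

  inst <- random_instance(6, 8, 3, seed = 3)
  U <- inst$U; U[cbind(c(1, 4), c(2, 3))] <- 0
  U2 <- update_u(inst$X, U, inst$V, inst$priors, crnmf_config(K = 3))
  expect_identical(U2[cbind(c(1, 4), c(2, 3))], c(0, 0))
  expect_true(all(U2 >= 0))
})

test_that("V update matches hand arithmetic, zeros stay zero", {
  pri <- tiny_priors()
  X <- matrix(1, 1, 1); U <- matrix(2, 1, 1); V <- matrix(1, 1, 1)
  cfg <- crnmf_config(K = 1, lambda_lu = 0, lambda_ru = 0, lambda_lv = 0,
                      lambda_rv = 1)
  # numerator X'U = 2; denominator V U'U + E V = 4 + 1
  expect_equal(update_v(X, U, V, pri, cfg), matrix(0.4, 1, 1),
               tolerance = 1e-9, ignore_attr = TRUE)

  inst <- random_instance(6, 8, 3, seed = 4)
  V <- inst$V; V[cbind(c(2, 7), c(1, 3))] <- 0
  V2 <- update_v(inst$X, inst$U, V, inst$priors, crnmf_config(K = 3))
  expect_identical(V2[cbind(c(2, 7), c(1, 3))], c(0, 0))
  expect_true(all(V2 >= 0))
})

test_that("with no regularization one sweep equals the classical NMF step", {
  inst <- random_instance(7, 9, 3, seed = 5)
  cfg <- lambda0(K = 3)
  U2 <- update_u(inst$X, inst$U, inst$V, inst$priors, cfg)
  V2 <- update_v(inst$X, U2, inst$V, inst$priors, cfg)
  ls <- lee_seung_step(inst$X, inst$U, inst$V)
  expect_equal(U2, ls$U, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(V2, ls$V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fit recovers an exact rank-1 factorization of the ones matrix", {
  X <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("g", 1:3)))
  inst <- random_instance(3, 3, 1, seed = 6)
  fit <- crnmf(X, inst$priors, lambda0(K = 1, seed = 6, max_iter = 500))
  trace <- fit$objective_trace
  expect_lt(trace[length(trace)], 1e-4 * trace[1])
  expect_equal(unname(fit$U %*% t(fit$V)), matrix(1, 3, 3), tolerance = 1e-2)
})

test_that("all-zero input collapses U and the objective to zero", {
  X <- matrix(0, 3, 4, dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  inst <- random_instance(3, 4, 2, seed = 7)
  fit <- crnmf(X, inst$priors, lambda0(K = 2, seed = 7))
  expect_true(all(fit$U == 0))
  expect_equal(fit$objective_trace[length(fit$objective_trace)], 0)
})

test_that("identical seeds give bit-identical fits", {
  inst <- random_instance(8, 10, 2, seed = 8)
  f1 <- crnmf(inst$X, inst$priors, crnmf_config(K = 2, seed = 99, max_iter = 60))
  f2 <- crnmf(inst$X, inst$priors, crnmf_config(K = 2, seed = 99, max_iter = 60))
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("variant configurations zero the documented parameter pairs", {
  base <- crnmf_config()
  expect_identical(variant_config(base, "proposed"), base)
  on <- variant_config(base, "only_network")
  expect_equal(c(on$lambda_lu, on$lambda_ru, on$lambda_lv, on$lambda_rv),
               c(0, 0, 1, 1))
  oe <- variant_config(base, "only_expression")
  expect_equal(c(oe$lambda_lu, oe$lambda_ru, oe$lambda_lv, oe$lambda_rv),
               c(1, 1, 0, 0))
  np <- variant_config(base, "no_prior")
  expect_equal(c(np$lambda_lu, np$lambda_ru, np$lambda_lv, np$lambda_rv),
               c(0, 0, 0, 0))
  expect_error(variant_config(base, "bogus"))
})

test_that("a fixed point of the updates leaves the factors unchanged", {
  # at entries where numerator equals denominator the multiplier is ~1
  inst <- random_instance(4, 5, 2, seed = 9)
  cfg <- crnmf_config(K = 2, tol = 1e-12, max_iter = 4000)
  fit <- crnmf(inst$X, inst$priors, cfg)
  U3 <- update_u(inst$X, fit$U, fit$V, inst$priors, cfg)
  expect_equal(U3, fit$U, tolerance = 1e-4)
})

test_that("doubling the denominator guard barely moves the optimum", {
  inst <- random_instance(8, 10, 3, seed = 10)
  cfg1 <- crnmf_config(K = 3, seed = 1, tol = 1e-9, max_iter = 2000)
  cfg2 <- cfg1; cfg2$eps_guard <- 2 * cfg1$eps_guard
  o1 <- glance(crnmf(inst$X, inst$priors, cfg1))$objective
  o2 <- glance(crnmf(inst$X, inst$priors, cfg2))$objective
  expect_equal(o1, o2, tolerance = 1e-6)
})

test_that("tidy and glance expose loadings and fit metadata", {
  inst <- random_instance(5, 6, 2, seed = 11)
  fit <- crnmf(inst$X, inst$priors, crnmf_config(K = 2, seed = 2, max_iter = 30))
  td <- tidy(fit)
  expect_equal(nrow(td), 6 * 2)
  expect_setequal(unique(td$gene_id), colnames(inst$X))
  expect_equal(td$score[td$dimension == 1],
               apply(fit$V, 1, max), ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_equal(gl$objective, fit$objective_trace[length(fit$objective_trace)])
  expect_s3_class(autoplot(fit), "ggplot")
})
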