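test_that("per-gene condition representation matches the explicit loop", {
  model <- tiny_model()
  with_test_seed(10, {
    g0 <- rnorm(12); D <- rnorm(12)
  })
  Q <- gene_condition_representation(g0, D, model$params)
  expect_identical(dim(Q), c(12L, 5L))
  oracle <- matrix(0, 12, 5)
  for (i in 1:12)
    oracle[i, ] <- g0[i] * model$params$W_gene[i, ] +
      D[i] * model$params$W_comp[i, ]
  expect_lt(max(abs(Q - oracle)), 1e-6)
  # additive decomposition: D = 0 leaves only the gene term
  expect_equal(gene_condition_representation(g0, rep(0, 12), model$params),
               g0 * model$params$W_gene)
  expect_error(gene_condition_representation(g0[1:5], D, model$params), "match")
})

test_that("attention scores equal the double-loop dot products and are symmetric", {
  with_test_seed(11, Q <- matrix(rnorm(150), 30, 5))
  A <- attention_scores(Q)
  oracle <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) oracle[i, j] <- sum(Q[i, ] * Q[j, ])
  expect_lt(max(abs(A - oracle)), 1e-6)
  expect_lt(max(abs(A - t(A))), 1e-6)
  # orthonormal rows give the identity
  expect_equal(attention_scores(diag(4)), diag(4))
  expect_equal(attention_scores(matrix(0, 3, 2)), matrix(0, 3, 3))
  # optional scaling divides by sqrt(h)
  expect_equal(attention_scores(Q, scale = TRUE), A / sqrt(5))
})

test_that("prior fusion is an element-wise sum with order checks", {
  with_test_seed(12, {
    Q <- matrix(rnorm(20), 10, 2)
    P <- matrix(rbinom(100, 1, 0.3), 10, 10)
    P <- (P + t(P) > 0) * 1; diag(P) <- 0
  })
  A_QC <- attention_scores(Q)
  expect_equal(combine_with_prior(A_QC, P), A_QC + P)
  expect_equal(combine_with_prior(A_QC, P * 0), A_QC)      # PPI-removed ablation
  expect_equal(combine_with_prior(A_QC * 0, P), P + 0)     # zero attention
  bad <- P
  dimnames(bad) <- list(letters[1:10], letters[1:10])
  dimnames(A_QC) <- list(LETTERS[1:10], LETTERS[1:10])
  expect_error(combine_with_prior(A_QC, bad), "ordering")
})

test_that("attention-as-weights forward matches a hand-rolled product", {
  model <- tiny_model(activation = "identity")
  with_test_seed(13, {
    g0 <- rnorm(12)
    A <- matrix(rnorm(144), 12, 12); A <- (A + t(A)) / 2
  })
  gc <- forward_perturbation(g0, A, model$params, model$config)
  oracle <- drop(model$params$W_final %*% (A %*% g0))
  expect_lt(max(abs(gc - oracle)), 1e-6)

  # identity pipeline returns g0 exactly
  idp <- model$params; idp$W_final <- diag(12)
  expect_equal(forward_perturbation(g0, diag(12), idp, model$config), g0)

  # zero attention with an odd activation gives zero
  expect_equal(forward_perturbation(g0, matrix(0, 12, 12), model$params,
                                    csg2a_config(activation = "tanh")),
               rep(0, 12))
})

test_that("the composite prediction equals manual chaining and is deterministic", {
  model <- tiny_model()
  with_test_seed(14, g0 <- rnorm(12))
  names(g0) <- model$gene_ids
  cond <- chemical_condition("CCO", 10, 24)
  out1 <- predict_perturbed_profile(model, g0, cond)
  out2 <- predict_perturbed_profile(model, g0, cond)
  expect_identical(out1, out2)

  D <- encode_condition(cond, model)
  Q <- gene_condition_representation(unname(g0), as.numeric(D), model$params)
  A <- combine_with_prior(attention_scores(Q), model$A_PPI)
  gc <- forward_perturbation(unname(g0), A, model$params, model$config)
  expect_lt(max(abs(out1$gc - gc)), 1e-12)
  expect_lt(max(abs(out1$attention - A)), 1e-12)

  expect_error(predict_perturbed_profile(model, unname(g0[1:5]), cond), "length")
})

test_that("with zero compound weights the prediction ignores the compound", {
  model <- tiny_model()
  model$params$W_comp[] <- 0
  with_test_seed(15, g0 <- rnorm(12))
  a <- predict_perturbed_profile(model, g0, chemical_condition("CCO", 10, 24))
  b <- predict_perturbed_profile(model, g0,
                                 chemical_condition("Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                                                    100, 72))
  expect_equal(a$gc, b$gc)
})

test_that("different compounds induce different attention on the same basal", {
  model <- tiny_model()
  with_test_seed(16, g0 <- rnorm(12))
  a <- predict_perturbed_profile(model, g0, chemical_condition("CCO"))
  b <- predict_perturbed_profile(model, g0,
                                 chemical_condition("CC(=O)Oc1ccccc1C(=O)O"))
  expect_gt(max(abs(a$attention - b$attention)), 0)
})

test_that("analytic gradients agree with finite differences", {
  model <- tiny_model()
  cfg <- model$config
  act <- csg2a:::activation_fns(cfg$activation)
  with_test_seed(17, {
    B <- 3
    G0 <- matrix(rnorm(B * 12), B, 12)
    FP <- matrix(rbinom(B * 16, 1, 0.3), B, 16)
    dp <- runif(B); tp <- runif(B)
    Y <- matrix(rnorm(B * 12), B, 12)
  })
  loss_fn <- function(params) {
    cce <- csg2a:::cce_forward(FP, dp, tp, params, act)
    fw <- csg2a:::core_forward(G0, cce$D, params, cfg, model$A_PPI)
    mean((fw$Gc - Y)^2)
  }
  params <- model$params
  cce <- csg2a:::cce_forward(FP, dp, tp, params, act)
  fw <- csg2a:::core_forward(G0, cce$D, params, cfg, model$A_PPI)
  dGc <- 2 * (fw$Gc - Y) / length(Y)
  bw <- csg2a:::core_backward(dGc, G0, cce$D, fw, params, cfg)
  grads <- c(bw$grads, csg2a:::cce_backward(bw$dD, cce$cache, params, act))
  eps <- 1e-5
  with_test_seed(18, {
    for (nm in c("W_gene", "W_comp", "W_final", "W_cce1")) {
      for (trial in 1:10) {
        i <- sample(length(params[[nm]]), 1)
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        fd <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        expect_lt(abs(fd - grads[[nm]][i]) / max(abs(fd), abs(grads[[nm]][i]), 1e-8),
                  1e-3)
      }
    }
  })
})

test_that("checkpoints round-trip through a single archive", {
  model <- tiny_model()
  path <- withr_local_file("model.ckpt")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$gene_ids, model$gene_ids)
  expect_identical(back$A_PPI, model$A_PPI)
})
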