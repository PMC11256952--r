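test_that("rmse and pcc match their textbook formulas", {
  with_test_seed(40, {
    y <- rnorm(25); yhat <- rnorm(25)
  })
  expect_identical(rmse(y, y), 0)
  expect_identical(pcc(y, y), 1)
  yc <- y - mean(y)
  expect_equal(pcc(yc, -yc), -1)
  expect_lt(abs(rmse(y, yhat) - sqrt(sum((y - yhat)^2) / 25)), 1e-10)
  ora <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  expect_lt(abs(pcc(y, yhat) - ora), 1e-10)
  expect_error(pcc(rep(1, 5), y[1:5]), "zero-variance")
  expect_error(rmse(y, yhat[1:3]), "equal-length")
})

test_that("mean_attention averages element-wise", {
  with_test_seed(41, A <- matrix(rnorm(16), 4, 4))
  expect_equal(mean_attention(list(A)), A)
  expect_equal(mean_attention(list(A, -A)), matrix(0, 4, 4))
  B <- A + 1; C <- A * 2
  expect_equal(mean_attention(list(A, B, C)), (A + B + C) / 3)
  expect_error(mean_attention(list()), "empty")
})

test_that("top_gene_pairs matches a brute-force sort and breaks ties lexicographically", {
  with_test_seed(42, {
    A <- matrix(rnorm(400), 20, 20); A <- (A + t(A)) / 2
  })
  dimnames(A) <- list(paste0("g", 1:20), paste0("g", 1:20))
  tp <- top_gene_pairs(A, k = 10)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  brute <- data.frame(i = ut[, 1], j = ut[, 2], s = A[upper.tri(A)])
  brute <- brute[order(-brute$s, brute$i, brute$j), ][1:10, ]
  expect_identical(tp$pairs$gene_i, paste0("g", brute$i))
  expect_identical(tp$pairs$gene_j, paste0("g", brute$j))
  expect_equal(tp$pairs$score, brute$s)
  expect_setequal(tp$genes, unique(c(tp$pairs$gene_i, tp$pairs$gene_j)))

  # all-equal scores: first pairs in lexicographic order
  E <- matrix(1, 3, 3)
  te <- top_gene_pairs(E, k = 2)
  expect_identical(te$pairs$gene_i, c("1", "1"))
  expect_identical(te$pairs$gene_j, c("2", "3"))

  # single largest pair
  S <- matrix(0, 3, 3); S[1, 3] <- S[3, 1] <- 5; S[1, 2] <- S[2, 1] <- 1
  t1 <- top_gene_pairs(S, k = 1)
  expect_identical(c(t1$pairs$gene_i, t1$pairs$gene_j), c("1", "3"))
  expect_error(top_gene_pairs(S, k = 10), "exceeds")
  # stability: repeated calls agree
  expect_identical(top_gene_pairs(A, 10), top_gene_pairs(A, 10))
})

test_that("attention correlation uses the upper triangle and ignores affine maps", {
  with_test_seed(43, {
    A1 <- matrix(rnorm(100), 10, 10); A1 <- A1 + t(A1)
    A2 <- matrix(rnorm(100), 10, 10); A2 <- A2 + t(A2)
  })
  expect_equal(attention_correlation(A1, A1), 1)
  expect_equal(attention_correlation(A1, 2 * A1 + 3), 1)
  ora <- cor(A1[upper.tri(A1)], A2[upper.tri(A2)])
  expect_lt(abs(attention_correlation(A1, A2) - ora), 1e-12)
  expect_error(attention_correlation(A1, matrix(1, 10, 10)), "zero variance")
})

test_that("group contrast separates within from between correlations", {
  with_test_seed(44, {
    base <- matrix(rnorm(100), 10, 10); base <- base + t(base)
    ortho <- matrix(rnorm(100), 10, 10); ortho <- ortho + t(ortho)
  })
  maps <- list(d1 = base, d2 = base, d3 = ortho)
  groups <- c(d1 = "A", d2 = "A", d3 = "B")
  expect_warning(res <- group_correlation_contrast(maps, groups), "single drug")
  expect_equal(res$within_mean, 1)
  expect_lt(res$between_mean, res$within_mean)
  expect_identical(nrow(res$pair_table), 3L)

  # all identical maps: both means are 1
  maps2 <- list(d1 = base, d2 = base, d3 = base, d4 = base)
  groups2 <- c(d1 = "A", d2 = "A", d3 = "B", d4 = "B")
  res2 <- group_correlation_contrast(maps2, groups2)
  expect_equal(res2$within_mean, 1)
  expect_equal(res2$between_mean, 1)
})

test_that("deg_analysis ranks a planted effect first and is quiet under the null", {
  with_test_seed(45, {
    g1 <- matrix(rnorm(20 * 30), 20, 30)
    g2 <- matrix(rnorm(20 * 30), 20, 30)
    colnames(g1) <- colnames(g2) <- paste0("g", 1:30)
    g1[, 7] <- g1[, 7] + 5          # +5 SD shift in group 1
  })
  deg <- deg_analysis(g1, g2)
  expect_identical(deg$gene[1], "g7")
  expect_identical(deg$direction[1], "up")
  expect_lt(deg$padj[1], 1e-6)
  expect_true(all(diff(deg$p) >= 0))
  # BH adjustment is monotone in raw p
  expect_true(all(diff(deg$padj[order(deg$p)]) >= -1e-12))

  # identical groups: nothing flagged after adjustment
  null_deg <- deg_analysis(g2, g2 + 0)
  expect_true(all(null_deg$padj[is.finite(null_deg$padj)] >= 0.99))
  expect_error(deg_analysis(g1[1, , drop = FALSE], g2), ">= 2 samples")
})

test_that("deg_by_response supports median and potent-quantile splits", {
  with_test_seed(46, {
    profiles <- matrix(rnorm(40 * 10), 40, 10,
                       dimnames = list(NULL, paste0("g", 1:10)))
    ic50 <- rnorm(40)
  })
  res <- deg_by_response(profiles, ic50)
  expect_identical(nrow(res), 10L)
  res_q <- deg_by_response(profiles, ic50, potent_quantile = 0.25)
  expect_identical(nrow(res_q), 10L)
})

test_that("perturbation distance is the Euclidean norm with a one-sided comparison", {
  g0 <- c(0, 0, 0, 1)
  expect_identical(perturbation_distance(g0, g0), 0)
  expect_identical(perturbation_distance(g0, g0 + c(3, 4, 0, 0)), 5)
  with_test_seed(47, {
    a <- rnorm(30); b <- rnorm(30)
  })
  expect_lt(abs(perturbation_distance(a, b) - sqrt(sum((b - a)^2))), 1e-10)
  expect_error(perturbation_distance(a, b[1:5]), "mismatch")
  with_test_seed(48, {
    far <- abs(rnorm(20, 5)); near <- abs(rnorm(20, 1))
  })
  cmp <- perturbation_distance_test(far, near)
  expect_lt(cmp$p_value, 0.01)
})

test_that("responder separation is one-sided with the expected symmetry", {
  x <- c(1, 2, 3, 4, 5)
  same <- responder_separation_test(x, x)
  expect_equal(same$p_value, 0.5)
  with_test_seed(49, {
    resp <- rnorm(30, -3); nonresp <- rnorm(30, 0)
  })
  sep <- responder_separation_test(resp, nonresp)
  expect_lt(sep$p_value, 0.001)
  # swapping the groups negates t and complements the one-sided p
  swapped <- responder_separation_test(nonresp, resp)
  expect_equal(swapped$t, -sep$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, 1 - sep$p_value, tolerance = 1e-10)
  expect_error(responder_separation_test(1, x), ">= 2")
})

test_that("hypergeometric enrichment matches the closed-form tail sum", {
  universe <- paste0("g", 1:15)
  sets <- list(hit = paste0("g", 1:5), miss = paste0("g", 11:14))
  query <- paste0("g", c(1:4, 10))
  res <- hypergeometric_enrichment(query, sets, universe)
  # exact tail: P(X >= k) enumerated from binomial coefficients
  exact_tail <- function(k, K, N, n)
    sum(sapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j))) / choose(N, n)
  expect_lt(abs(res$p[res$set == "hit"] - exact_tail(4, 5, 15, 5)), 1e-12)
  expect_lt(abs(res$p[res$set == "miss"] - exact_tail(0, 4, 15, 5)), 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)   # disjoint query and set
  # query == set == universe is the boundary case p = 1
  bound <- hypergeometric_enrichment(universe, list(all = universe), universe)
  expect_equal(bound$p, 1)
  expect_error(hypergeometric_enrichment(character(0), sets, universe), "empty")
  expect_error(hypergeometric_enrichment("zz", sets, universe), "universe")
})

test_that("GMT gene sets load as named lists", {
  f <- withr_local_file("sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
})
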