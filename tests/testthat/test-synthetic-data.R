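test_that("the same seed reproduces the world exactly", {
  w1 <- generate_world(n_genes = 30, n_drugs = 8, n_classes = 2, n_cells = 10,
                       seed = 5)
  w2 <- generate_world(n_genes = 30, n_drugs = 8, n_classes = 2, n_cells = 10,
                       seed = 5)
  expect_identical(w1, w2)
  w3 <- generate_world(n_genes = 30, n_drugs = 8, n_classes = 2, n_cells = 10,
                       seed = 6)
  expect_false(identical(w1$basal, w3$basal))
  expect_error(generate_world(n_drugs = 2, n_classes = 4), "n_classes")
  expect_error(generate_world(edge_density = 0), "edge_density")
})

test_that("drug masks are network-edge subsets sharing their class signal", {
  w <- world_fixture()
  n_edges <- nrow(w$edges)
  for (d in seq_len(nrow(w$drugs)))
    expect_true(all(w$drug_masks[[d]] %in% seq_len(n_edges)))
  # within-class mask overlap (Jaccard) exceeds between-class overlap
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  classes <- w$drugs$class
  within <- c(); between <- c()
  for (i in 1:(nrow(w$drugs) - 1)) for (j in (i + 1):nrow(w$drugs)) {
    v <- jac(w$drug_masks[[i]], w$drug_masks[[j]])
    if (classes[i] == classes[j]) within <- c(within, v)
    else between <- c(between, v)
  }
  expect_gt(mean(within), mean(between))
  # single class: all drugs share one mask up to the 5% jitter
  w1 <- generate_world(n_genes = 30, n_drugs = 5, n_classes = 1, n_cells = 5,
                       seed = 3)
  overlaps <- sapply(2:5, function(d)
    jac(w1$drug_masks[[1]], w1$drug_masks[[d]]))
  expect_true(all(overlaps > 0.7))
})

test_that("network edge counts track the binomial expectation", {
  counts <- sapply(0:9, function(s)
    nrow(generate_world(n_genes = 40, n_drugs = 4, n_classes = 2,
                        n_cells = 5, edge_density = 0.15, seed = s)$edges))
  expected <- 0.15 * 40 * 39 / 2
  expect_true(all(abs(counts - expected) / expected < 0.2))
})

test_that("perturbation follows gc = g0 + s(d,t) M g0 + noise", {
  w <- world_fixture()
  # zero dose leaves only noise
  sim0 <- simulate_perturbation(w, "C001", "D01", dose_uM = 0, noise_sd = 0)
  expect_equal(sim0$gc, sim0$g0)
  # noiseless case matches the matrix-product oracle
  M <- csg2a:::drug_matrix(w, "D03")
  sim <- simulate_perturbation(w, "C002", "D03", dose_uM = 50, time_h = 36,
                               noise_sd = 0)
  s <- (50 / 100) * (36 / 72)
  expect_lt(max(abs(sim$gc - (sim$g0 + s * drop(M %*% sim$g0)))), 1e-12)
  # doubling the dose doubles the perturbation term
  sim2 <- simulate_perturbation(w, "C002", "D03", dose_uM = 100, time_h = 36,
                                noise_sd = 0)
  expect_lt(max(abs((sim2$gc - sim2$g0) - 2 * (sim$gc - sim$g0))), 1e-12)
  # time saturates at 72 h
  sA <- simulate_perturbation(w, "C002", "D03", 10, 72, noise_sd = 0)
  sB <- simulate_perturbation(w, "C002", "D03", 10, 144, noise_sd = 0)
  expect_identical(sA$gc, sB$gc)
  expect_error(simulate_perturbation(w, "C999", "D01"), "unknown cell")
  expect_error(simulate_perturbation(w, "C001", "D99"), "unknown drug")
})

test_that("viability couples essential-gene perturbation to sensitivity", {
  w <- world_fixture()
  # zero essentiality: log IC50 is pure baseline plus noise
  w0 <- w; w0$essentiality[] <- 0
  expect_identical(simulate_viability(w0, "C001", "D01", sigma_v = 0), w$beta0)
  # deterministic given sigma_v = 0
  expect_identical(simulate_viability(w, "C001", "D01", sigma_v = 0),
                   simulate_viability(w, "C001", "D01", sigma_v = 0))
  # nested masks: the containing mask perturbs more, so is more potent
  wn <- w
  full <- wn$drug_masks[[2]]
  wn$drug_masks[[1]] <- full[seq_len(floor(length(full) / 2))]
  y_small <- sapply(rownames(wn$basal), function(cl)
    simulate_viability(wn, cl, "D01", sigma_v = 0))
  y_big <- sapply(rownames(wn$basal), function(cl)
    simulate_viability(wn, cl, "D02", sigma_v = 0))
  expect_lt(mean(y_big), mean(y_small))
})

test_that("dataset emission is fast, complete and byte-identical per seed", {
  d1 <- withr_local_file("w1"); d2 <- withr_local_file("w2")
  w <- world_fixture()
  t0 <- Sys.time()
  write_world(w, d1, n_triples = 3000, seed = 0)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  write_world(w, d2, n_triples = 3000, seed = 0)
  for (f in c("basal.tsv", "g0.tsv", "perturbed.tsv", "compounds.csv",
              "responses.csv", "edges.txt")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # emitted sizes match the study conditions
  expect_identical(nrow(read_response_table(file.path(d1, "responses.csv"))),
                   600L)
  expect_identical(nrow(read_expression_matrix(file.path(d1, "perturbed.tsv"))),
                   3000L)
  # the true network round-trips through the STRING-format reader
  A <- load_ppi_adjacency(file.path(d1, "edges.txt"), w$gene_ids)
  expect_equal(unname(A), unname((w$network > 0) * 1), ignore_attr = TRUE)
})

test_that("emitted files feed the training pipeline end to end", {
  d <- withr_local_file("w3")
  w <- generate_world(n_genes = 15, n_drugs = 4, n_classes = 2, n_cells = 6,
                      seed = 9)
  write_world(w, d, n_triples = 40, seed = 9)
  g0 <- read_expression_matrix(file.path(d, "g0.tsv"))
  gc <- read_expression_matrix(file.path(d, "perturbed.tsv"))
  cond <- read_compound_table(file.path(d, "compounds.csv"))
  tri <- as_triples(g0, gc, cond)
  A <- load_ppi_adjacency(file.path(d, "edges.txt"), colnames(g0))
  fit <- pretrain(tri, A,
                  pretrain_config(epochs = 2, batch_size = 20, lr = 1e-3,
                                  seed = 1, patience = 2),
                  csg2a_config(h = 4, cce_hidden = 16))
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$val_mse)))
})
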