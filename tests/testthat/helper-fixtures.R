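# Shared fixtures.  Heavy objects (the synthetic world and the pretrained
# model used by several training-level tests) are built once per session and
# memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# study-condition world: 50 genes, 20 drugs in 4 classes, 30 cells
world_fixture <- function(seed = 0L) {
  memo(paste0("world", seed), function() generate_world(seed = seed))
}

triples_fixture <- function(seed = 0L, n = 3000L) {
  memo(paste0("triples", seed, "_", n), function()
    make_pretrain_triples(world_fixture(seed), n, seed = seed))
}

# model sizes used throughout the desk-scale experiments
small_model_config <- function() csg2a_config(h = 16L, cce_hidden = 128L)

fast_pretrain_config <- function(seed = 1L, epochs = 25L) {
  pretrain_config(epochs = epochs, batch_size = 64L, lr = 2e-3, seed = seed,
                  patience = epochs, val_fraction = 0.1)
}

pretrained_fixture <- function(seed = 0L) {
  memo(paste0("pretrained", seed), function() {
    w <- world_fixture(seed)
    pretrain(triples_fixture(seed), (w$network > 0) * 1,
             fast_pretrain_config(seed = seed + 1L),
             small_model_config())
  })
}

response_fixture <- function(seed = 0L) {
  memo(paste0("responses", seed), function()
    make_response_records(world_fixture(seed), seed = seed))
}

# tiny random model for unit-level math tests
tiny_model <- function(n_genes = 12L, h = 5L, m = 16L, seed = 7L,
                       activation = "relu", ppi = TRUE) {
  gid <- sprintf("g%02d", seq_len(n_genes))
  P <- NULL
  if (ppi) {
    P <- with_test_seed(seed, {
      M <- matrix(stats::rbinom(n_genes^2, 1L, 0.2), n_genes, n_genes)
      M <- (M + t(M) > 0) * 1
      diag(M) <- 0
      M
    })
    dimnames(P) <- list(gid, gid)
  }
  csg2a_model(gid, P, csg2a_config(h = h, cce_hidden = 20L,
                                   encoder = structure_encoder(bits = m),
                                   activation = activation, dropout = 0),
              seed = seed)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# held-out RMSE of a fine-tuned drug-response model on test records
test_rmse <- function(drm, basal, test) {
  yhat <- vapply(seq_len(nrow(test)), function(i)
    predict_log_ic50(drm, basal[test$cell_id[i], ], test$smiles[i]),
    numeric(1L))
  rmse(test$log_ic50, yhat)
}

# scratch file path helper (unique per call)
withr_local_file <- function(name) tempfile(pattern = sub("\\..*$", "_", name),
                                            fileext = sub("^[^.]*", "", name))

# small response-record grids for partition tests
response_grid <- function(n_cells, n_drugs, n = NULL, seed = 0L) {
  grid <- expand.grid(cell_id = sprintf("C%02d", seq_len(n_cells)),
                      compound_id = sprintf("D%02d", seq_len(n_drugs)),
                      stringsAsFactors = FALSE)
  with_test_seed(seed, {
    if (!is.null(n)) grid <- grid[sample(nrow(grid), n), ]
    grid$smiles <- "CCO"
    grid$log_ic50 <- stats::rnorm(nrow(grid))
  })
  rownames(grid) <- NULL
  grid
}
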