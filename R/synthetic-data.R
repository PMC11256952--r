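# A seed-reproducible synthetic perturbation universe for desk-scale testing:
# a sparse signed gene network, drug classes sharing perturbation masks
# (mechanism-of-action structure), cell-line basal profiles, dose/time
# modulated linear network perturbation, and viability coupled to the
# perturbation of essential genes.
#
# Perturbation:  gc = g0 + s(d, t) * M_drug g0 + eps,
#                s(d, t) = (d / 100) * min(t / 72, 1)
# Viability:     log IC50 = beta0 - beta1 * <e, |Delta|> + eta,
#                Delta the noiseless perturbation at the reference condition.

# bundled valid small-molecule SMILES assigned to synthetic drugs
.builtin_smiles <- c(
  "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(=O)Nc1ccc(O)cc1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccc2c(c1)cccn2", "CCN(CC)CC(=O)Nc1c(C)cccc1C",
  "OC(=O)c1ccccc1O", "Nc1ccc(cc1)S(N)(=O)=O", "CN1CCC[C@H]1c1cccnc1",
  "OCC(O)CO", "CC(N)Cc1ccccc1", "Oc1ccc(cc1)C(O)CNC",
  "CC(=O)OCC(=O)O", "NCCc1ccc(O)c(O)c1", "COc1cc2c(cc1OC)CCN2",
  "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O", "Clc1ccccc1Cl", "OC(=O)CCc1ccccc1",
  "CN(C)CCCN1c2ccccc2CCc2ccccc21", "NC(=O)c1ccc[nH]1", "Oc1ccccc1C(=O)Nc1ccccc1",
  "CCOC(=O)c1ccccc1N", "CSCCC(N)C(=O)O", "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  "OC(=O)C1CCCN1", "Nc1ncnc2[nH]cnc12", "Cc1ccc(cc1)S(=O)(=O)N",
  "OCC1OC(O)C(O)C(O)C1O", "CC(C)(C)NCC(O)c1ccc(O)c(O)c1", "ClCCN(CCCl)N=O",
  "CN1CCN(CC1)c1ccccc1", "COc1ccc(CCN)cc1", "CC(C)NCC(O)COc1ccccc1",
  "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O", "Fc1ccc(cc1)C(=O)CCCN1CCC(O)CC1",
  "CCC(C)C(N)C(=O)O", "CC(C)CC(N)C(=O)O", "OC(=O)c1cccnc1",
  "Cc1ncc(CO)c(CN)c1O", "OCCN1CCN(CC1)c1ccccc1"
)

# grow a connected edge subset of the network by frontier expansion
connected_edge_subset <- function(edges, n_target) {
  # edges: 2-column matrix of gene indices (i < j)
  chosen <- sample(nrow(edges), 1L)
  nodes <- unique(as.integer(edges[chosen, ]))
  while (length(chosen) < n_target) {
    frontier <- which(!(seq_len(nrow(edges)) %in% chosen) &
                        (edges[, 1L] %in% nodes | edges[, 2L] %in% nodes))
    if (length(frontier) == 0L) break
    pick <- frontier[sample.int(length(frontier), 1L)]
    chosen <- c(chosen, pick)
    nodes <- unique(c(nodes, as.integer(edges[pick, ])))
  }
  sort(chosen)
}

#' Generate a synthetic perturbation world
#'
#' Samples, once and deterministically per seed: a sparse symmetric gene
#' network with signed edge weights; `n_classes` mechanism classes, each
#' owning a random connected edge subset of the network as its perturbation
#' mask; drugs inheriting their class mask with 5% edge jitter and a bundled
#' real SMILES string each; cell basal profiles from a per-gene
#' location/scale model; and a per-gene essentiality vector coupling
#' perturbation to viability.
#'
#' @param n_genes,n_drugs,n_classes,n_cells World sizes
#'   (`n_classes <= n_drugs`).
#' @param edge_density Network edge probability, in (0, 1).
#' @param noise_sd Additive expression noise SD.
#' @param seed Integer seed; the same seed reproduces the world exactly.
#' @param mask_fraction Fraction of network edges in each class mask.
#' @param beta0,beta1,sigma_v Viability model: baseline log IC50, coupling
#'   to essential-gene perturbation, response noise SD.
#' @return A `synthetic_world` list.
#' @export
generate_world <- function(n_genes = 50L, n_drugs = 20L, n_classes = 4L,
                           n_cells = 30L, edge_density = 0.1, noise_sd = 0.1,
                           seed = 0L, mask_fraction = 0.35, beta0 = 2.5,
                           beta1 = 2, sigma_v = 0.3) {
  if (n_classes > n_drugs) stop("n_classes must be <= n_drugs")
  if (edge_density <= 0 || edge_density >= 1) stop("edge_density must be in (0, 1)")
  if (n_genes < 3L || n_drugs < 1L || n_cells < 1L) stop("degenerate world size")
  with_seed(seed, {
    gene_ids <- sprintf("G%03d", seq_len(n_genes))
    # network: symmetric 0/1 with signed weights on the edges
    ut <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    present <- runif(nrow(ut)) < edge_density
    edges <- ut[present, , drop = FALSE]
    if (nrow(edges) < 2L) stop("network degenerate: raise edge_density or n_genes")
    weights <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
      runif(nrow(edges), 0.5, 1.5)
    network <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
    network[edges] <- 1; network[edges[, c(2L, 1L)]] <- 1
    n_mask <- max(2L, round(mask_fraction * nrow(edges)))
    class_masks <- lapply(seq_len(n_classes), function(cl)
      connected_edge_subset(edges, n_mask))
    class_of <- rep_len(seq_len(n_classes), n_drugs)
    drug_masks <- lapply(seq_len(n_drugs), function(d) {
      mask <- class_masks[[class_of[d]]]
      n_jit <- max(1L, round(0.05 * length(mask)))
      drop_idx <- sample(length(mask), n_jit)
      pool <- setdiff(seq_len(nrow(edges)), mask)
      add <- if (length(pool) > 0L) sample(pool, min(n_jit, length(pool))) else integer()
      sort(c(mask[-drop_idx], add))
    })
    smiles <- rep_len(.builtin_smiles, n_drugs)
    drugs <- data.frame(compound_id = sprintf("D%02d", seq_len(n_drugs)),
                        smiles = smiles[seq_len(n_drugs)],
                        class = sprintf("MoA%d", class_of),
                        stringsAsFactors = FALSE)
    loc <- rnorm(n_genes); scl <- runif(n_genes, 0.5, 1.5)
    basal <- matrix(rnorm(n_cells * n_genes, mean = rep(loc, each = n_cells),
                          sd = rep(scl, each = n_cells)),
                    n_cells, n_genes,
                    dimnames = list(sprintf("C%03d", seq_len(n_cells)), gene_ids))
    essentiality <- runif(n_genes)
    structure(list(
      n_genes = n_genes, gene_ids = gene_ids, network = network,
      edges = edges, edge_weights = weights, class_masks = class_masks,
      drugs = drugs, drug_masks = drug_masks, basal = basal,
      essentiality = essentiality, noise_sd = noise_sd,
      beta0 = beta0, beta1 = beta1, sigma_v = sigma_v,
      ref_dose_uM = 10, ref_time_h = 72, seed = seed),
      class = "synthetic_world")
  })
}

# signed masked weight matrix of one drug (symmetric)
drug_matrix <- function(world, drug) {
  d <- match(drug, world$drugs$compound_id)
  if (is.na(d)) stop("unknown drug: ", drug)
  mask <- world$drug_masks[[d]]
  M <- matrix(0, world$n_genes, world$n_genes,
              dimnames = list(world$gene_ids, world$gene_ids))
  e <- world$edges[mask, , drop = FALSE]
  M[e] <- world$edge_weights[mask]
  M[e[, c(2L, 1L)]] <- world$edge_weights[mask]
  M
}

dose_time_strength <- function(dose_uM, time_h) {
  (dose_uM / 100) * min(time_h / 72, 1)
}

#' Simulate a chemical perturbation
#'
#' `gc = g0 + s(d, t) * M_drug g0 + eps` with
#' `s(d, t) = (d / 100) * min(t / 72, 1)` and `eps ~ N(0, noise_sd^2)`.
#'
#' @param world A [generate_world()] result.
#' @param cell,drug Cell and compound identifiers in the world.
#' @param dose_uM,time_h Condition.
#' @param noise_sd Override the world's noise SD (e.g. 0 for the noiseless
#'   perturbation).
#' @return `list(g0, gc)` named expression vectors.
#' @export
simulate_perturbation <- function(world, cell, drug, dose_uM = 10,
                                  time_h = 24, noise_sd = world$noise_sd) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!(cell %in% rownames(world$basal))) stop("unknown cell: ", cell)
  g0 <- world$basal[cell, ]
  M <- drug_matrix(world, drug)
  s <- dose_time_strength(dose_uM, time_h)
  gc <- g0 + s * drop(M %*% g0) + rnorm(length(g0), sd = noise_sd)
  names(gc) <- world$gene_ids
  list(g0 = g0, gc = gc)
}

#' Simulate a cell-level viability response
#'
#' `log IC50 = beta0 - beta1 * <e, |Delta|> + eta` with `Delta` the noiseless
#' perturbation at the world's reference condition (10 uM, 72 h) and
#' `eta ~ N(0, sigma_v^2)`: the stronger a drug perturbs essential genes in a
#' cell, the lower (more sensitive) its log IC50 in expectation.
#'
#' @param world A [generate_world()] result.
#' @param cell,drug Identifiers in the world.
#' @param sigma_v Override the response noise SD.
#' @return Scalar log IC50.
#' @export
simulate_viability <- function(world, cell, drug, sigma_v = world$sigma_v) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!(cell %in% rownames(world$basal))) stop("unknown cell: ", cell)
  g0 <- world$basal[cell, ]
  M <- drug_matrix(world, drug)
  s <- dose_time_strength(world$ref_dose_uM, world$ref_time_h)
  delta <- s * drop(M %*% g0)
  world$beta0 - world$beta1 * sum(world$essentiality * abs(delta)) +
    rnorm(1L, sd = sigma_v)
}

#' Emit a pretraining dataset from the world
#'
#' Samples `(cell, drug, dose, time)` combinations uniformly from a dose/time
#' grid spanning the condition range the model is meant to resolve, and
#' simulates the paired perturbed profiles.
#'
#' @param world A [generate_world()] result.
#' @param n_triples Number of triples.
#' @param doses,times Candidate doses (uM) and times (h).
#' @param seed Seed for sampling and noise.
#' @return A `csg2a_triples` object; `conditions` also carries `compound_id`
#'   and `cell_id`.
#' @export
make_pretrain_triples <- function(world, n_triples = 3000L,
                                  doses = c(10, 100), times = c(24, 72),
                                  seed = 0L) {
  stopifnot(inherits(world, "synthetic_world"))
  with_seed(seed + 17L, {
    cells <- sample(rownames(world$basal), n_triples, replace = TRUE)
    di <- sample(nrow(world$drugs), n_triples, replace = TRUE)
    dose <- sample(doses, n_triples, replace = TRUE)
    time <- sample(times, n_triples, replace = TRUE)
    g0 <- matrix(0, n_triples, world$n_genes,
                 dimnames = list(sprintf("S%05d", seq_len(n_triples)),
                                 world$gene_ids))
    gc <- g0
    for (i in seq_len(n_triples)) {
      sim <- simulate_perturbation(world, cells[i],
                                   world$drugs$compound_id[di[i]],
                                   dose[i], time[i])
      g0[i, ] <- sim$g0; gc[i, ] <- sim$gc
    }
    conditions <- data.frame(sample_id = rownames(g0),
                             cell_id = cells,
                             compound_id = world$drugs$compound_id[di],
                             smiles = world$drugs$smiles[di],
                             dose_uM = dose, time_h = time,
                             stringsAsFactors = FALSE)
    as_triples(g0, gc, conditions)
  })
}

#' Emit a drug-response dataset from the world
#'
#' Simulates log IC50 for the full cell x drug grid (or a random subset).
#'
#' @param world A [generate_world()] result.
#' @param n_records `NULL` for the full grid, else a subset size.
#' @param seed Seed for noise (and subsetting).
#' @return Response `data.frame` (`cell_id`, `compound_id`, `smiles`,
#'   `log_ic50`).
#' @export
make_response_records <- function(world, n_records = NULL, seed = 0L) {
  stopifnot(inherits(world, "synthetic_world"))
  grid <- expand.grid(cell_id = rownames(world$basal),
                      compound_id = world$drugs$compound_id,
                      stringsAsFactors = FALSE)
  with_seed(seed + 29L, {
    if (!is.null(n_records) && n_records < nrow(grid))
      grid <- grid[sample(nrow(grid), n_records), ]
    grid$smiles <- world$drugs$smiles[match(grid$compound_id,
                                            world$drugs$compound_id)]
    grid$log_ic50 <- vapply(seq_len(nrow(grid)), function(i)
      simulate_viability(world, grid$cell_id[i], grid$compound_id[i]),
      numeric(1L))
    rownames(grid) <- NULL
    grid
  })
}

#' Write a synthetic world as a file bundle
#'
#' Emits `basal.tsv` (cells x genes), `g0.tsv`/`perturbed.tsv` (paired
#' pretraining profiles), `compounds.csv` (per-sample conditions),
#' `responses.csv` and `edges.txt` (the true network in STRING-like
#' `protein1 protein2 combined_score` format with score 950, so the
#' high-confidence filter keeps it).
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @param n_triples,seed Passed to the dataset emitters.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, n_triples = 3000L, seed = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  triples <- make_pretrain_triples(world, n_triples, seed = seed)
  responses <- make_response_records(world, seed = seed)
  write_expression_matrix(world$basal, file.path(dir, "basal.tsv"))
  write_expression_matrix(triples$g0, file.path(dir, "g0.tsv"))
  write_expression_matrix(triples$gc, file.path(dir, "perturbed.tsv"))
  utils::write.table(triples$conditions, file.path(dir, "compounds.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(responses, file.path(dir, "responses.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  edge_df <- data.frame(protein1 = world$gene_ids[world$edges[, 1L]],
                        protein2 = world$gene_ids[world$edges[, 2L]],
                        combined_score = 950L)
  utils::write.table(edge_df, file.path(dir, "edges.txt"),
                     sep = " ", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
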