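# Evaluation metrics and the interpretability procedures: drug-averaged
# attention maps, top-pair extraction, mechanism-of-action correlation
# contrasts, differential expression on predicted profiles, zero-shot
# perturbation distance and responder separation.

#' Root-mean-square error
#'
#' @param y True values.
#' @param yhat Predicted values, same length (>= 2).
#' @return Scalar RMSE.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("rmse needs two equal-length vectors of length >= 2")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation coefficient
#'
#' @param y True values.
#' @param yhat Predicted values, same length (>= 2); both must have positive
#'   variance.
#' @return Scalar PCC.
#' @export
pcc <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("pcc needs two equal-length vectors of length >= 2")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("pcc undefined for zero-variance input")
  stats::cor(y, yhat)
}

#' Element-wise mean of attention maps
#'
#' Attention maps of the samples treated with one drug are averaged to
#' capture the common signal across diverse basal expressions.
#'
#' @param maps List of Ngene x Ngene matrices with identical shape/order.
#' @return The element-wise mean matrix.
#' @export
mean_attention <- function(maps) {
  if (length(maps) == 0L) stop("empty attention map list")
  dims <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1L))))
    stop("attention maps differ in shape")
  Reduce(`+`, maps) / length(maps)
}

#' Top attention gene pairs
#'
#' Extracts the top-k unordered off-diagonal gene pairs by attention score
#' (descending), ties broken by lexicographic order on the canonical gene
#' indices, plus the union of all genes involved (the input for downstream
#' over-representation analysis).
#'
#' @param A Symmetric attention matrix with gene ids as dimnames (or indices
#'   are used).
#' @param k Number of pairs (default 1000).
#' @return `list(pairs = data.frame(gene_i, gene_j, score), genes = <union>)`.
#' @export
top_gene_pairs <- function(A, k = 1000L) {
  n <- nrow(A)
  if (k > n * (n - 1L) / 2L) stop("k exceeds the number of off-diagonal pairs")
  ids <- colnames(A) %||% as.character(seq_len(n))
  ut <- which(upper.tri(A), arr.ind = TRUE)
  score <- A[upper.tri(A)]
  ord <- order(-score, ut[, 1L], ut[, 2L])[seq_len(k)]
  pairs <- data.frame(gene_i = ids[ut[ord, 1L]], gene_j = ids[ut[ord, 2L]],
                      score = score[ord], stringsAsFactors = FALSE)
  list(pairs = pairs, genes = unique(c(pairs$gene_i, pairs$gene_j)))
}

#' Correlation between two attention maps
#'
#' Pearson correlation over the strict upper-triangle entries; the diagonal
#' is excluded (self-scores would inflate agreement) and the lower triangle
#' is redundant by symmetry.
#'
#' @param A1,A2 Attention matrices of identical shape.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
attention_correlation <- function(A1, A2) {
  if (!all(dim(A1) == dim(A2))) stop("attention maps differ in shape")
  v1 <- A1[upper.tri(A1)]; v2 <- A2[upper.tri(A2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("attention map with zero variance")
  stats::cor(v1, v2)
}

#' Within- versus between-group attention correlation contrast
#'
#' Computes all pairwise attention-map correlations between drugs, splits the
#' pairs into within-group (same mechanism-of-action label) and
#' between-group, and summarizes the contrast.  Significance is assessed by a
#' one-sided Mann-Whitney rank test (within > between); drug pairs share
#' drugs and are not independent, so the rank test is the conservative
#' choice.
#'
#' @param maps_by_drug Named list of drug-averaged attention matrices.
#' @param group_of Named character vector mapping drug name to group label.
#' @return A `list` with `within_mean`, `between_mean`, `median_difference`
#'   (median within - median between), `p_value` and the full `pair_table`.
#' @export
group_correlation_contrast <- function(maps_by_drug, group_of) {
  drugs <- names(maps_by_drug)
  if (length(drugs) < 2L) stop("need at least two drugs")
  groups <- group_of[drugs]
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  singleton <- names(table(groups))[table(groups) == 1L]
  if (length(singleton) > 0L)
    warning("group(s) with a single drug contribute no within pairs: ",
            paste(singleton, collapse = ", "))
  pairs <- utils::combn(drugs, 2L)
  pair_table <- data.frame(
    drug_a = pairs[1L, ], drug_b = pairs[2L, ],
    correlation = apply(pairs, 2L, function(p)
      attention_correlation(maps_by_drug[[p[1L]]], maps_by_drug[[p[2L]]])),
    within = groups[pairs[1L, ]] == groups[pairs[2L, ]],
    stringsAsFactors = FALSE)
  w <- pair_table$correlation[pair_table$within]
  b <- pair_table$correlation[!pair_table$within]
  p <- if (length(w) > 0L && length(b) > 0L)
    suppressWarnings(stats::wilcox.test(w, b, alternative = "greater")$p.value)
  else NA_real_
  list(within_mean = mean(w), between_mean = mean(b),
       median_difference = stats::median(w) - stats::median(b),
       p_value = p, pair_table = pair_table)
}

#' Differential expression between two profile groups
#'
#' Per-gene Welch two-sample t-test between two groups of (predicted)
#' expression profiles, with Benjamini-Hochberg adjustment.  Effect is
#' `mean(group1) - mean(group2)`; direction `"up"` means higher in group 1
#' (e.g. the sensitive low-IC50 group).
#'
#' @param profiles_group1,profiles_group2 Samples x genes matrices with the
#'   same gene order, each with >= 2 samples.
#' @return `data.frame(gene, mean_group1, mean_group2, effect, t, p, padj,
#'   direction)` sorted by p-value.
#' @export
deg_analysis <- function(profiles_group1, profiles_group2) {
  if (nrow(profiles_group1) < 2L || nrow(profiles_group2) < 2L)
    stop("each group needs >= 2 samples")
  if (!identical(colnames(profiles_group1), colnames(profiles_group2)))
    stop("gene orderings differ between groups")
  genes <- colnames(profiles_group1) %||% as.character(seq_len(ncol(profiles_group1)))
  res <- vapply(seq_along(genes), function(j) {
    x <- profiles_group1[, j]; y <- profiles_group2[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(c(mean(x), mean(y), 0, NA_real_, 1))
    tt <- stats::t.test(x, y)
    c(mean(x), mean(y), mean(x) - mean(y), unname(tt$statistic), tt$p.value)
  }, numeric(5L))
  out <- data.frame(gene = genes, mean_group1 = res[1L, ],
                    mean_group2 = res[2L, ], effect = res[3L, ],
                    t = res[4L, ], p = res[5L, ],
                    padj = stats::p.adjust(res[5L, ], method = "BH"),
                    direction = ifelse(res[3L, ] >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Split profiles by response and run differential expression
#'
#' Groups predicted profiles into low- and high-IC50 sets and compares them.
#' The default split is at the median; `potent_quantile` instead selects the
#' lowest-q fraction as the sensitive group (e.g. 0.25 for the lowest 25%
#' IC50 "potent" samples) against the rest.
#'
#' @param profiles Samples x genes matrix of (predicted) expression.
#' @param log_ic50 Response value per sample.
#' @param potent_quantile `NULL` (median split) or a fraction in (0, 1).
#' @return As [deg_analysis()]; group 1 is the low-IC50 (sensitive) group.
#' @export
deg_by_response <- function(profiles, log_ic50, potent_quantile = NULL) {
  cut <- if (is.null(potent_quantile)) stats::median(log_ic50)
         else stats::quantile(log_ic50, potent_quantile)
  low <- log_ic50 <= cut
  deg_analysis(profiles[low, , drop = FALSE], profiles[!low, , drop = FALSE])
}

#' Euclidean perturbation distance
#'
#' Distance between expression before and after (predicted) treatment; the
#' zero-shot readout separating sensitive from resistant samples.
#'
#' @param g0,gc_pred Expression vectors of equal length.
#' @return Scalar Euclidean norm of `gc_pred - g0`.
#' @export
perturbation_distance <- function(g0, gc_pred) {
  if (length(g0) != length(gc_pred)) stop("length mismatch")
  sqrt(sum((gc_pred - g0)^2))
}

#' Compare perturbation-distance distributions of two record sets
#'
#' One-sided Welch t-test for the sensitive group being perturbed farther
#' than the resistant group.
#'
#' @param dist_sensitive,dist_resistant Perturbation distances per sample
#'   (>= 2 each).
#' @return `list(t, p_value)`.
#' @export
perturbation_distance_test <- function(dist_sensitive, dist_resistant) {
  if (length(dist_sensitive) < 2L || length(dist_resistant) < 2L)
    stop("need >= 2 distances per group")
  tt <- stats::t.test(dist_sensitive, dist_resistant, alternative = "greater")
  list(t = unname(tt$statistic), p_value = tt$p.value)
}

#' Responder separation test
#'
#' One-sided Welch t-test that responders have a lower predicted log IC50
#' distribution than non-responders.
#'
#' @param pred_ic50_responders,pred_ic50_nonresponders Predicted log IC50
#'   values (>= 2 per group).
#' @return `list(t, p_value)`.
#' @export
responder_separation_test <- function(pred_ic50_responders,
                                      pred_ic50_nonresponders) {
  if (length(pred_ic50_responders) < 2L || length(pred_ic50_nonresponders) < 2L)
    stop("need >= 2 values per group")
  tt <- stats::t.test(pred_ic50_responders, pred_ic50_nonresponders,
                      alternative = "less")
  list(t = unname(tt$statistic), p_value = tt$p.value)
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric test of each gene set's overlap with a query
#' list against a finite gene universe, BH-adjusted.  A generic stand-in for
#' web-service enrichment tools, consuming user-supplied gene sets (e.g. from
#' [read_gmt()]).
#'
#' @param query Character vector of query genes (subset of `universe`,
#'   nonempty).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the gene universe.
#' @return `data.frame(set, set_size, overlap, p, padj)` sorted by p.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  query <- unique(query)
  if (length(query) == 0L) stop("empty query gene list")
  if (!all(query %in% universe)) stop("query genes must lie in the universe")
  if (any(lengths(gene_sets) == 0L)) stop("empty gene set supplied")
  N <- length(unique(universe)); n <- length(query)
  res <- vapply(gene_sets, function(set) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1L, length(set), N - length(set), n,
                       lower.tail = FALSE)
    c(length(set), k, p)
  }, numeric(3L))
  out <- data.frame(set = names(gene_sets), set_size = res[1L, ],
                    overlap = res[2L, ], p = res[3L, ],
                    padj = stats::p.adjust(res[3L, ], method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>genes...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t")
  fields <- fields[lengths(fields) >= 3L]
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, character(1L), 1L))
}

#' Drug-averaged attention maps
#'
#' Runs the model over the basal profiles of each record, extracts the
#' per-sample attention matrix and averages it per drug.
#'
#' @param model A `csg2a_model` or a fine-tuned `csg2a_drm` (whose scaling
#'   layer is then applied to the basal input first).
#' @param basal Samples x genes matrix in the model gene order.
#' @param records `data.frame` with `compound_id`, `smiles` and the basal row
#'   per record in `cell_id` (rows of `basal`).
#' @param dose_uM,time_h Condition applied to every record.
#' @return Named list (by compound id) of averaged attention matrices.
#' @export
drug_attention_maps <- function(model, basal, records, dose_uM = 10,
                                time_h = 72) {
  core <- if (inherits(model, "csg2a_drm")) model$core else model
  scaled <- if (inherits(model, "csg2a_drm"))
    scale_basal(basal, model$scaling) else basal
  maps <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    g0 <- scaled[records$cell_id[i], ]
    cond <- chemical_condition(records$smiles[i], dose_uM, time_h)
    A <- predict_perturbed_profile(core, g0, cond)$attention
    id <- records$compound_id[i]
    if (is.null(maps[[id]])) {
      maps[[id]] <- A; counts[[id]] <- 1L
    } else {
      maps[[id]] <- maps[[id]] + A; counts[[id]] <- counts[[id]] + 1L
    }
  }
  ids <- ls(maps)
  stats::setNames(lapply(ids, function(id) maps[[id]] / counts[[id]]), ids)
}
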