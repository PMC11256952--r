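# The condition-specific gene-gene attention core.
#
# For one sample with basal profile g0 and compound representation D:
#   Q[i, ] = g0[i] * W_gene[i, ] + D[i] * W_comp[i, ]   (per-gene expansion)
#   A_QC   = Q Q^T                                       (dot-product scores)
#   A      = A_QC + A_PPI                                (prior fusion)
#   gc     = W_final %*% dropout(act(A %*% g0))          (attention as weights)
# No layer carries a bias term.

#' Model configuration
#'
#' @param h Hidden width of the per-gene expansion (rows of Q).
#' @param activation Global activation: `"relu"` (default), `"identity"`,
#'   `"tanh"` or `"leaky_relu"`.
#' @param dropout Dropout rate applied to the activation output during
#'   training.
#' @param cce_hidden Hidden width of the condition-encoder MLP.
#' @param encoder A [structure_encoder()]; its `bits` fixes the structure
#'   embedding length m.
#' @param scale_attention If `TRUE`, divide dot-product scores by `sqrt(h)`.
#'   Off by default: the prior is added on the raw score scale and
#'   normalization would break the additive semantics.
#' @return A `csg2a_config` list.
#' @export
csg2a_config <- function(h = 64L, activation = "relu", dropout = 0.1,
                         cce_hidden = 512L, encoder = structure_encoder(),
                         scale_attention = FALSE) {
  activation_fns(activation)  # validate early
  structure(list(h = as.integer(h), activation = activation,
                 dropout = dropout, cce_hidden = as.integer(cce_hidden),
                 encoder = encoder, scale_attention = scale_attention),
            class = "csg2a_config")
}

# parameter initialization.  W_final starts near identity so the untrained
# network approximates gc ~ act(A g0); W_gene/W_comp are scaled so the raw
# attention scores have O(1) entries at init.
init_params <- function(config, n_genes, seed = 0L) {
  m <- config$encoder$bits; h <- config$h; H <- config$cce_hidden
  with_seed(seed, {
    sd_q <- 0.5 * (n_genes * h)^(-1 / 4)
    list(
      W_proj = matrix(rnorm(m * m, sd = 1 / sqrt(m)), m, m),
      W_dose = matrix(rnorm(2), 1L, 2L),
      W_time = matrix(rnorm(2), 1L, 2L),
      W_cce1 = matrix(rnorm((m + 4L) * H, sd = sqrt(2 / (m + 4L))), m + 4L, H),
      W_cce2 = matrix(rnorm(H * n_genes, sd = sqrt(2 / H)), H, n_genes),
      W_gene = matrix(rnorm(n_genes * h, sd = sd_q), n_genes, h),
      W_comp = matrix(rnorm(n_genes * h, sd = sd_q), n_genes, h),
      W_final = diag(n_genes) + matrix(rnorm(n_genes^2, sd = 0.01),
                                       n_genes, n_genes)
    )
  })
}

#' Assemble a perturbation model
#'
#' @param gene_ids Canonical gene ordering; fixes Ngene and the meaning of
#'   every attention row/column for the lifetime of the model.
#' @param A_PPI PPI prior adjacency aligned to `gene_ids` (see
#'   [load_ppi_adjacency()]); pass a zero matrix (or `ppi = FALSE` ablation
#'   in training wrappers) to remove the prior.
#' @param config A [csg2a_config()].
#' @param seed Seed for parameter initialization.
#' @param params Optional pre-built parameter list (checkpoints).
#' @return A `csg2a_model` list with elements `params`, `gene_ids`, `config`,
#'   `A_PPI`.
#' @export
csg2a_model <- function(gene_ids, A_PPI = NULL, config = csg2a_config(),
                        seed = 0L, params = NULL) {
  n <- length(gene_ids)
  if (is.null(A_PPI)) A_PPI <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  if (!all(dim(A_PPI) == n)) stop("A_PPI dimension mismatch with gene_ids")
  if (!is.null(colnames(A_PPI)) && !identical(colnames(A_PPI), gene_ids))
    stop("A_PPI gene ordering differs from gene_ids")
  if (is.null(params)) params <- init_params(config, n, seed)
  structure(list(params = params, gene_ids = gene_ids, config = config,
                 A_PPI = unname(as.matrix(A_PPI))),
            class = "csg2a_model")
}

#' Per-gene condition representation Q
#'
#' Expands each gene's basal expression value and compound-representation
#' value to `h` dimensions with that gene's own weight rows and sums them:
#' `Q[i, ] = g0[i] * W_gene[i, ] + D[i] * W_comp[i, ]`.
#'
#' @param g0 Basal expression vector (length Ngene).
#' @param D Compound representation vector (length Ngene).
#' @param params Parameter list holding `W_gene` and `W_comp`.
#' @return Ngene x h matrix.
#' @export
gene_condition_representation <- function(g0, D, params) {
  if (length(g0) != nrow(params$W_gene) || length(D) != nrow(params$W_comp))
    stop("length of g0/D does not match the per-gene weight rows")
  g0 * params$W_gene + D * params$W_comp
}

#' Dot-product attention scores
#'
#' `A[i, j] = Q[i, ] . Q[j, ]`.  No softmax: the scores are summed with the
#' PPI prior and used directly as linear-layer weights.
#'
#' @param Q Ngene x h condition representation.
#' @param scale If `TRUE`, divide by `sqrt(h)`.
#' @return Symmetric Ngene x Ngene matrix.
#' @export
attention_scores <- function(Q, scale = FALSE) {
  A <- tcrossprod(Q)
  if (scale) A <- A / sqrt(ncol(Q))
  A
}

#' Fuse attention scores with the PPI prior
#'
#' Element-wise sum `A_CSG2A = A_QC + A_PPI`.
#'
#' @param A_QC Attention score matrix.
#' @param A_PPI Prior adjacency of identical shape and gene order.
#' @return Ngene x Ngene matrix.
#' @export
combine_with_prior <- function(A_QC, A_PPI) {
  if (!all(dim(A_QC) == dim(A_PPI)))
    stop("attention and prior shapes differ")
  if (!is.null(colnames(A_QC)) && !is.null(colnames(A_PPI)) &&
      !identical(colnames(A_QC), colnames(A_PPI)))
    stop("attention and prior gene orderings differ")
  unname(A_QC) + unname(as.matrix(A_PPI))
}

#' Attention-as-weights forward pass
#'
#' The first layer is a linear map whose weights are the fused attention
#' matrix; an activation, a dropout layer (training only) and a bias-free
#' final linear layer follow.
#'
#' @param g0 Basal expression vector.
#' @param A Fused attention matrix.
#' @param params Parameter list holding `W_final`.
#' @param config A [csg2a_config()] (activation and dropout rate).
#' @param training If `TRUE`, dropout is sampled; deterministic otherwise.
#' @return Predicted perturbed profile (length Ngene).
#' @export
forward_perturbation <- function(g0, A, params, config = csg2a_config(),
                                 training = FALSE) {
  act <- activation_fns(config$activation)
  z <- drop(A %*% g0)
  stopifnot_finite(z, "attention linear layer")
  a <- act$f(z)
  if (training && config$dropout > 0) {
    keep <- stats::rbinom(length(a), 1L, 1 - config$dropout)
    a <- a * keep / (1 - config$dropout)
  }
  gc <- drop(params$W_final %*% a)
  stopifnot_finite(gc, "final linear layer")
  gc
}

#' Predict a chemically perturbed expression profile
#'
#' Full composite: condition encoding, per-gene condition representation,
#' dot-product attention, prior fusion and the attention-as-weights network.
#' Returns both the prediction and the attention matrix for interpretability.
#'
#' @param model A `csg2a_model`.
#' @param g0 Basal profile, either a named vector in the model's gene order
#'   or an unnamed vector of length Ngene.
#' @param cond A [chemical_condition()].
#' @param training If `TRUE`, dropout is sampled.
#' @return `list(gc = <profile>, attention = <Ngene x Ngene matrix>)`.
#' @export
predict_perturbed_profile <- function(model, g0, cond, training = FALSE) {
  stopifnot(inherits(model, "csg2a_model"))
  if (!is.null(names(g0)) && !identical(names(g0), model$gene_ids))
    stop("g0 gene ordering differs from the model's canonical ordering")
  if (length(g0) != length(model$gene_ids))
    stop("g0 length differs from the model's gene universe")
  D <- encode_condition(cond, model)
  Q <- gene_condition_representation(unname(g0), drop(D), model$params)
  A_QC <- attention_scores(Q, scale = model$config$scale_attention)
  A <- combine_with_prior(A_QC, model$A_PPI)
  gc <- forward_perturbation(unname(g0), A, model$params, model$config, training)
  names(gc) <- model$gene_ids
  dimnames(A) <- list(model$gene_ids, model$gene_ids)
  list(gc = gc, attention = A)
}

# --- batched internal forward/backward used by the trainers ----------------

# G0: B x N; cce: result of cce_forward (D = B x N).  Per-sample attention is
# materialized as one N x N matrix and discarded after use, so Ngene = 978
# fits on a commodity CPU with mini-batching over samples.
core_forward <- function(G0, D, params, config, A_PPI, training = FALSE,
                         keep_attention = FALSE, keep_cache = TRUE) {
  act <- activation_fns(config$activation)
  B <- nrow(G0); N <- ncol(G0)
  scale <- if (config$scale_attention) sqrt(config$h) else 1
  Gc <- matrix(0, B, N)
  caches <- vector("list", B)
  atts <- if (keep_attention) vector("list", B) else NULL
  for (b in seq_len(B)) {
    g0 <- G0[b, ]
    Q <- g0 * params$W_gene + D[b, ] * params$W_comp
    A <- tcrossprod(Q) / scale + A_PPI
    z <- drop(A %*% g0)
    a <- act$f(z)
    mask <- NULL
    if (training && config$dropout > 0) {
      mask <- stats::rbinom(N, 1L, 1 - config$dropout) / (1 - config$dropout)
      a <- a * mask
    }
    Gc[b, ] <- drop(params$W_final %*% a)
    if (keep_cache) caches[[b]] <- list(Q = Q, A = A, z = z, a = a, mask = mask)
    if (keep_attention) atts[[b]] <- A
  }
  list(Gc = Gc, caches = caches, attention = atts)
}

# backward through the core.  dGc: B x N.  Returns parameter gradients for
# W_gene, W_comp, W_final, plus dD (B x N) and dG0 (B x N) for upstream use.
core_backward <- function(dGc, G0, D, fw, params, config) {
  act <- activation_fns(config$activation)
  B <- nrow(G0); N <- ncol(G0)
  scale <- if (config$scale_attention) sqrt(config$h) else 1
  dW_gene <- matrix(0, N, config$h); dW_comp <- matrix(0, N, config$h)
  dW_final <- matrix(0, N, N)
  dD <- matrix(0, B, N); dG0 <- matrix(0, B, N)
  for (b in seq_len(B)) {
    cc <- fw$caches[[b]]
    g0 <- G0[b, ]
    dgc <- dGc[b, ]
    dW_final <- dW_final + tcrossprod(dgc, cc$a)
    da <- drop(crossprod(params$W_final, dgc))
    if (!is.null(cc$mask)) da <- da * cc$mask
    dz <- da * drop(act$g(cc$z))
    dA <- tcrossprod(dz, g0)
    dg0 <- drop(crossprod(cc$A, dz))
    dSym <- (dA + t(dA)) / scale
    dQ <- dSym %*% cc$Q
    dW_gene <- dW_gene + g0 * dQ
    dW_comp <- dW_comp + D[b, ] * dQ
    dg0 <- dg0 + rowSums(dQ * params$W_gene)
    dD[b, ] <- rowSums(dQ * params$W_comp)
    dG0[b, ] <- dg0
  }
  list(grads = list(W_gene = dW_gene, W_comp = dW_comp, W_final = dW_final),
       dD = dD, dG0 = dG0)
}
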