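#' Mean-squared-error loss
#'
#' Mean over all entries of squared differences; the pretraining objective on
#' the perturbed expression profile.
#'
#' @param pred,target Numeric vectors or matrices of identical shape.
#' @return Scalar MSE.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  mean((pred - target)^2)
}

#' Pretraining configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed fixing every stochastic choice (split, shuffling,
#'   dropout, initialization).
#' @param patience Early-stopping patience on validation MSE.
#' @param val_fraction Fraction of triples held out for validation,
#'   in (0, 1).
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-4,
                            optimizer = "adam", seed = 0L, patience = 10L,
                            val_fraction = 0.1) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = optimizer, seed = as.integer(seed),
                 patience = as.integer(patience), val_fraction = val_fraction),
            class = "pretrain_config")
}

# evaluation-mode MSE over a (possibly large) set, chunked to bound memory
eval_mse <- function(G0, Gc, FP, dprime, tprime, params, config, A_PPI,
                     chunk = 256L) {
  act <- activation_fns(config$activation)
  total <- 0
  n <- nrow(G0)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    cce <- cce_forward(FP[idx, , drop = FALSE], dprime[idx], tprime[idx],
                       params, act)
    fw <- core_forward(G0[idx, , drop = FALSE], cce$D, params, config, A_PPI,
                       training = FALSE, keep_cache = FALSE)
    total <- total + sum((fw$Gc - Gc[idx, , drop = FALSE])^2)
  }
  total / (n * ncol(G0))
}

#' Pretrain the attention network on perturbation triples
#'
#' Trains the full model (condition encoder and attention core) to predict
#' perturbed from basal expression with MSE loss, with a random
#' validation split, per-epoch logging and best-checkpoint selection on
#' validation MSE.
#'
#' @param triples A `csg2a_triples` object (see [pair_with_controls()] /
#'   [as_triples()]): paired basal and perturbed profiles plus their chemical
#'   conditions (`smiles`, `dose_uM`, `time_h`).
#' @param A_PPI PPI prior adjacency aligned to the triple gene ordering, or
#'   `NULL` for the prior-free ablation.
#' @param config A [pretrain_config()].
#' @param model_config A [csg2a_config()].
#' @return A `csg2a_pretrain_fit`: `list(model, history, best_epoch)` where
#'   `history` is a per-epoch `data.frame` with `train_mse` and `val_mse` and
#'   `model` carries the parameters of the best epoch.
#' @export
pretrain <- function(triples, A_PPI = NULL, config = pretrain_config(),
                     model_config = csg2a_config()) {
  stopifnot(inherits(triples, "csg2a_triples"))
  if (is.null(triples$conditions))
    stop("pretraining requires chemical conditions on the triples")
  gene_ids <- colnames(triples$g0)
  if (is.null(gene_ids)) stop("triples must carry gene identifiers")
  n <- nrow(triples$g0)
  if (n < 2L) stop("need at least 2 triples")
  model <- csg2a_model(gene_ids, A_PPI, model_config, seed = config$seed)
  act <- activation_fns(model_config$activation)
  A_prior <- model$A_PPI

  FP <- fingerprint_matrix(triples$conditions$smiles, model_config$encoder)
  dprime <- triples$conditions$dose_uM / 100
  tprime <- triples$conditions$time_h / 72
  G0 <- unname(triples$g0); Gc <- unname(triples$gc)

  history <- data.frame(epoch = integer(), train_mse = double(),
                        val_mse = double())
  params <- model$params
  best <- list(val = Inf, params = params, epoch = 0L)

  with_seed(config$seed + 1L, {
    val_idx <- sample(n, max(1L, round(config$val_fraction * n)))
    train_idx <- setdiff(seq_len(n), val_idx)
    opt <- adam_init(params, lr = config$lr)
    wait <- 0L
    for (epoch in seq_len(config$epochs)) {
      order <- sample(train_idx)
      train_loss <- 0
      for (s in seq(1L, length(order), by = config$batch_size)) {
        idx <- order[s:min(s + config$batch_size - 1L, length(order))]
        cce <- cce_forward(FP[idx, , drop = FALSE], dprime[idx], tprime[idx],
                           params, act)
        fw <- core_forward(G0[idx, , drop = FALSE], cce$D, params,
                           model_config, A_prior, training = TRUE)
        resid <- fw$Gc - Gc[idx, , drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("NaN loss at epoch ", epoch, ", batch starting at sample ", s)
        train_loss <- train_loss + loss * length(idx)
        dGc <- 2 * resid / length(resid)
        bw <- core_backward(dGc, G0[idx, , drop = FALSE], cce$D, fw, params,
                            model_config)
        grads <- c(bw$grads, cce_backward(bw$dD, cce$cache, params, act))
        step <- adam_step(params, grads, opt)
        params <- step$params; opt <- step$state
      }
      val_mse <- eval_mse(G0[val_idx, , drop = FALSE],
                          Gc[val_idx, , drop = FALSE],
                          FP[val_idx, , drop = FALSE], dprime[val_idx],
                          tprime[val_idx], params, model_config, A_prior)
      history[epoch, ] <- list(epoch, train_loss / length(train_idx), val_mse)
      if (val_mse < best$val) {
        best <- list(val = val_mse, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 val_idx = sort(val_idx)),
            class = "csg2a_pretrain_fit")
}
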