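# Transfer to cell-level drug response (log IC50).
#
# The pretrained perturbation network is kept (by default fully frozen) and
# two trainable pieces are added:
#   * a scaling layer g0' = (g0 - mu) / sigma with learnable per-gene latent
#     mean and standard deviation, aligning fine-tuning expression with the
#     pretraining space (sigma = softplus(rho) + 1e-4 keeps it positive);
#   * a bias-free prediction head mapping the concatenation
#     [gc_pred, D, g0'] (length 3 Ngene) to the scalar log IC50.

#' Scaling layer constructor
#'
#' @param n_genes Gene count.
#' @param mu Initial per-gene mean (default 0).
#' @param sigma Initial per-gene scale (default 1); stored internally as an
#'   unconstrained parameter `rho` with `sigma = softplus(rho) + 1e-4`.
#' @return A `scaling_layer` list with elements `mu` and `rho`.
#' @export
scaling_layer <- function(n_genes, mu = 0, sigma = 1) {
  if (any(sigma <= 1e-4))
    stop("initial sigma must exceed the positivity floor 1e-4")
  structure(list(mu = rep_len(mu, n_genes),
                 rho = rep_len(inv_softplus(sigma - 1e-4), n_genes)),
            class = "scaling_layer")
}

#' Effective per-gene standard deviation of a scaling layer
#'
#' The positive scale actually applied by [scale_basal()]:
#' `softplus(rho) + 1e-4`.
#'
#' @param layer A [scaling_layer()].
#' @return Numeric vector of per-gene sigma values, all `> 0`.
#' @export
effective_sigma <- function(layer) softplus(layer$rho) + 1e-4

#' Apply the learnable scaling layer
#'
#' Element-wise `(g0 - mu) / sigma`.
#'
#' @param g0 Basal expression vector or samples x genes matrix.
#' @param layer A [scaling_layer()].
#' @return Scaled expression, same shape as `g0`.
#' @export
scale_basal <- function(g0, layer) {
  sigma <- effective_sigma(layer)
  if (is.matrix(g0)) {
    if (ncol(g0) != length(layer$mu)) stop("gene count mismatch with scaling layer")
    sweep(sweep(g0, 2L, layer$mu, "-"), 2L, sigma, "/")
  } else {
    if (length(g0) != length(layer$mu)) stop("gene count mismatch with scaling layer")
    (g0 - layer$mu) / sigma
  }
}

#' Fine-tuning configuration
#'
#' @param freeze_pretrained Keep every pretrained parameter fixed (default
#'   `TRUE`; the configuration reported as best-performing).
#' @param dose_uM,time_h Condition injected for response records, which carry
#'   no dose/time of their own: 10 uM and 72 h, the standard IC50 assay
#'   convention.
#' @param head_hidden Hidden width of the prediction head.
#' @param epochs,batch_size,lr,optimizer,seed,patience,val_fraction As in
#'   [pretrain_config()].
#' @param scaling_lr Learning rate for the scaling-layer parameters
#'   (default: same as `lr`).  Exposed separately because the scaling
#'   layer's gradients arrive diluted through the frozen network while the
#'   head sees the loss directly.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(freeze_pretrained = TRUE, dose_uM = 10,
                            time_h = 72, head_hidden = 256L, epochs = 100L,
                            batch_size = 32L, lr = 1e-4, optimizer = "adam",
                            seed = 0L, patience = 10L, val_fraction = 0.1,
                            scaling_lr = lr) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(freeze_pretrained = isTRUE(freeze_pretrained),
                 dose_uM = dose_uM, time_h = time_h,
                 head_hidden = as.integer(head_hidden),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = optimizer, seed = as.integer(seed),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 scaling_lr = scaling_lr),
            class = "finetune_config")
}

init_head <- function(n_genes, hidden, seed) {
  with_seed(seed, list(
    W_head1 = matrix(rnorm(3L * n_genes * hidden, sd = sqrt(2 / (3L * n_genes))),
                     3L * n_genes, hidden),
    w_head2 = matrix(rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1L)
  ))
}

# head forward: V = [Gc, D, G0'] (B x 3N) -> scalar per sample
head_forward <- function(V, head, act) {
  Zh <- V %*% head$W_head1
  Hh <- act$f(Zh)
  yhat <- drop(Hh %*% head$w_head2)
  list(yhat = yhat, Zh = Zh, Hh = Hh)
}

head_backward <- function(dy, V, fw, head, act) {
  dYh <- matrix(dy, ncol = 1L)
  dw2 <- crossprod(fw$Hh, dYh)
  dHh <- dYh %*% t(head$w_head2)
  dZh <- dHh * act$g(fw$Zh)
  dW1 <- crossprod(V, dZh)
  dV <- dZh %*% t(head$W_head1)
  list(grads = list(W_head1 = dW1, w_head2 = dw2), dV = dV)
}

# full drug-response forward for a batch; returns prediction and caches
drm_forward <- function(G0, FP, dprime, tprime, model, scaling, head, config,
                        training = FALSE) {
  act <- activation_fns(model$config$activation)
  G0p <- scale_basal(G0, scaling)
  cce <- cce_forward(FP, dprime, tprime, model$params, act)
  fw <- core_forward(G0p, cce$D, model$params, model$config, model$A_PPI,
                     training = training && !config$freeze_pretrained)
  V <- cbind(fw$Gc, cce$D, G0p)
  hf <- head_forward(V, head, act)
  list(yhat = hf$yhat, G0p = G0p, cce = cce, core = fw, V = V, head_fw = hf)
}

#' Predict log IC50 for basal profiles under a compound
#'
#' Composes the scaling layer, the (frozen) perturbation network and the
#' prediction head.  Deterministic in evaluation mode.
#'
#' @param drm A fine-tuned drug-response model (`csg2a_drm`, from
#'   [finetune()]).
#' @param g0 Basal profile vector, or a samples x genes matrix in the model's
#'   gene order.
#' @param smiles Compound SMILES (single string).
#' @param dose_uM,time_h Condition; defaults to the model's configured
#'   convention (10 uM, 72 h).
#' @return Numeric vector of predicted log IC50 values (one per row of `g0`).
#' @export
predict_log_ic50 <- function(drm, g0, smiles, dose_uM = NULL, time_h = NULL) {
  stopifnot(inherits(drm, "csg2a_drm"))
  G0 <- if (is.matrix(g0)) g0 else matrix(g0, nrow = 1L)
  if (!is.null(colnames(G0)) && !identical(colnames(G0), drm$core$gene_ids))
    stop("gene ordering differs from the fine-tuned checkpoint")
  if (ncol(G0) != length(drm$core$gene_ids))
    stop("gene count differs from the fine-tuned checkpoint")
  dose <- dose_uM %||% drm$config$dose_uM
  time <- time_h %||% drm$config$time_h
  FP <- fingerprint_matrix(rep(canonicalize_smiles(smiles), nrow(G0)),
                           drm$core$config$encoder)
  fw <- drm_forward(unname(G0), FP, rep(dose / 100, nrow(G0)),
                    rep(time / 72, nrow(G0)), drm$core, drm$scaling,
                    drm$head, drm$config, training = FALSE)
  fw$yhat
}

#' Fine-tune a pretrained model to log IC50 prediction
#'
#' Adds the scaling layer and prediction head to a pretrained perturbation
#' model and optimizes MSE against observed log IC50.  With
#' `freeze_pretrained` (default) only the scaling layer and head are updated
#' and the pretrained tensors are bitwise unchanged; switching it off updates
#' everything (the ablation reported to perform worse).
#'
#' @param records Response records `data.frame` (`cell_id`, `compound_id`,
#'   `smiles`, `log_ic50`).
#' @param basal Cells x genes basal expression matrix; row names must resolve
#'   every `cell_id`.
#' @param pretrained A `csg2a_model` (e.g. `pretrain(...)$model`).
#' @param config A [finetune_config()].
#' @return A `csg2a_finetune_fit`: `list(model, history, best_epoch,
#'   val_idx)`; `model` is a `csg2a_drm` holding `core`, `scaling`, `head`
#'   and the config, with best-epoch parameters.
#' @export
finetune <- function(records, basal, pretrained, config = finetune_config()) {
  stopifnot(inherits(pretrained, "csg2a_model"))
  missing_cells <- setdiff(unique(records$cell_id), rownames(basal))
  if (length(missing_cells) > 0L)
    stop("cell id(s) without basal profile: ",
         paste(head(missing_cells, 5L), collapse = ", "))
  if (!identical(colnames(basal), pretrained$gene_ids))
    stop("basal gene ordering differs from the pretrained checkpoint")
  n <- nrow(records)
  N <- length(pretrained$gene_ids)
  act <- activation_fns(pretrained$config$activation)

  G0 <- unname(basal[records$cell_id, , drop = FALSE])
  FP <- fingerprint_matrix(records$smiles, pretrained$config$encoder)
  dprime <- rep(config$dose_uM / 100, n)
  tprime <- rep(config$time_h / 72, n)
  y <- records$log_ic50

  scaling <- scaling_layer(N)
  head <- init_head(N, config$head_hidden, config$seed)
  core_params <- pretrained$params
  model <- pretrained

  history <- data.frame(epoch = integer(), train_rmse = double(),
                        val_rmse = double(), val_pcc = double())
  best <- list(val = Inf, scaling = scaling, head = head,
               core = core_params, epoch = 0L)

  trainable <- function() {
    out <- head
    if (!config$freeze_pretrained) out <- c(out, core_params)
    out
  }
  with_seed(config$seed + 1L, {
    val_idx <- sample(n, max(1L, round(config$val_fraction * n)))
    train_idx <- setdiff(seq_len(n), val_idx)
    opt <- adam_init(trainable(), lr = config$lr)
    opt_s <- adam_init(list(mu = scaling$mu, rho = scaling$rho),
                       lr = config$scaling_lr)
    wait <- 0L
    eval_rmse_pcc <- function(idx) {
      model$params <- core_params
      fw <- drm_forward(G0[idx, , drop = FALSE], FP[idx, , drop = FALSE],
                        dprime[idx], tprime[idx], model, scaling, head,
                        config, training = FALSE)
      c(rmse(y[idx], fw$yhat),
        if (stats::sd(fw$yhat) > 0) pcc(y[idx], fw$yhat) else NA_real_)
    }
    for (epoch in seq_len(config$epochs)) {
      order <- sample(train_idx)
      sq_sum <- 0
      for (s in seq(1L, length(order), by = config$batch_size)) {
        idx <- order[s:min(s + config$batch_size - 1L, length(order))]
        B <- length(idx)
        model$params <- core_params
        fw <- drm_forward(G0[idx, , drop = FALSE], FP[idx, , drop = FALSE],
                          dprime[idx], tprime[idx], model, scaling, head,
                          config, training = TRUE)
        resid <- fw$yhat - y[idx]
        if (!all(is.finite(resid)))
          stop("NaN loss at epoch ", epoch, ", batch starting at sample ", s)
        sq_sum <- sq_sum + sum(resid^2)
        dy <- 2 * resid / B
        hb <- head_backward(dy, fw$V, fw$head_fw, head, act)
        dGc <- hb$dV[, seq_len(N), drop = FALSE]
        dD_head <- hb$dV[, N + seq_len(N), drop = FALSE]
        dG0p_head <- hb$dV[, 2L * N + seq_len(N), drop = FALSE]
        cb <- core_backward(dGc, fw$G0p, fw$cce$D, fw$core, core_params,
                            model$config)
        dD <- cb$dD + dD_head
        dG0p <- cb$dG0 + dG0p_head
        ccb <- cce_backward(dD, fw$cce$cache, core_params, act)
        sigma <- effective_sigma(scaling)
        dmu <- colSums(sweep(dG0p, 2L, -1 / sigma, "*"))
        dsigma <- colSums(dG0p * sweep(-fw$G0p, 2L, sigma, "/"))
        drho <- dsigma * stats::plogis(scaling$rho)
        grads <- list(W_head1 = hb$grads$W_head1, w_head2 = hb$grads$w_head2)
        if (!config$freeze_pretrained) grads <- c(grads, cb$grads, ccb)
        step <- adam_step(trainable(), grads, opt)
        opt <- step$state
        head$W_head1 <- step$params$W_head1; head$w_head2 <- step$params$w_head2
        if (!config$freeze_pretrained)
          core_params[names(core_params)] <- step$params[names(core_params)]
        step_s <- adam_step(list(mu = scaling$mu, rho = scaling$rho),
                            list(mu = dmu, rho = drho), opt_s)
        opt_s <- step_s$state
        scaling$mu <- step_s$params$mu; scaling$rho <- step_s$params$rho
      }
      val <- eval_rmse_pcc(val_idx)
      history[epoch, ] <- list(epoch, sqrt(sq_sum / length(train_idx)),
                               val[1L], val[2L])
      if (val[1L] < best$val) {
        best <- list(val = val[1L], scaling = scaling, head = head,
                     core = core_params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$core
  drm <- structure(list(core = model, scaling = best$scaling,
                        head = best$head, config = config),
                   class = "csg2a_drm")
  structure(list(model = drm, history = history, best_epoch = best$epoch,
                 val_idx = sort(val_idx)),
            class = "csg2a_finetune_fit")
}
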