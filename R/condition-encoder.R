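# Chemical condition encoder (CCE).
#
# A condition triple (S, d, t) is encoded as
#   D = MLP_CCE([proj(fp(S)), d' * W_dose, t' * W_time]),
# where d' = d/100 and t' = t/72 are the dose and time scaled by 100 uM and
# 72 h, W_dose and W_time (1 x 2) expand each scalar to two dimensions, and
# MLP_CCE is a bias-free two-layer perceptron mapping the concatenation
# (length m + 4) to one value per gene (length Ngene).

#' A chemical condition triple
#'
#' @param smiles SMILES string (validated by canonicalization).
#' @param dose_uM Dose in micromolar, nonnegative.
#' @param time_h Treatment time in hours, nonnegative.
#' @return A `chemical_condition` list.
#' @export
chemical_condition <- function(smiles, dose_uM = 10, time_h = 72) {
  if (dose_uM < 0 || time_h < 0) stop("dose and time must be nonnegative")
  canon <- canonicalize_smiles(smiles)
  structure(list(smiles = canon, dose_uM = dose_uM, time_h = time_h),
            class = "chemical_condition")
}

#' Scale dose and time to the model's reference units
#'
#' Dose is scaled by 100 uM and time by 72 h before expansion, so that the
#' common experimental ranges map near the unit interval.
#'
#' @param dose_uM Dose in micromolar, nonnegative.
#' @param time_h Time in hours, nonnegative.
#' @return Numeric vector `c(scaled_dose, scaled_time)`.
#' @export
scale_dose_time <- function(dose_uM, time_h) {
  if (any(dose_uM < 0) || any(time_h < 0))
    stop("dose and time must be nonnegative")
  c(scaled_dose = dose_uM / 100, scaled_time = time_h / 72)
}

# batched CCE forward.
# FP: B x m fingerprint matrix; dprime, tprime: length-B scaled dose/time.
# Returns list(D = B x Ngene, cache) where cache holds intermediates for
# backprop: U (concatenation), Z1 (hidden pre-activation), H1.
cce_forward <- function(FP, dprime, tprime, params, act) {
  E <- FP %*% params$W_proj                       # B x m
  U <- cbind(E, outer(dprime, drop(params$W_dose)),
             outer(tprime, drop(params$W_time))) # B x (m + 4)
  Z1 <- U %*% params$W_cce1
  H1 <- act$f(Z1)
  D <- H1 %*% params$W_cce2                       # B x Ngene
  list(D = D, cache = list(FP = FP, dprime = dprime, tprime = tprime,
                           U = U, Z1 = Z1, H1 = H1))
}

# backward through the CCE given dD (B x Ngene); returns gradients
cce_backward <- function(dD, cache, params, act) {
  m <- ncol(cache$FP)
  dW_cce2 <- crossprod(cache$H1, dD)
  dH1 <- dD %*% t(params$W_cce2)
  dZ1 <- dH1 * act$g(cache$Z1)
  dW_cce1 <- crossprod(cache$U, dZ1)
  dU <- dZ1 %*% t(params$W_cce1)
  dE <- dU[, seq_len(m), drop = FALSE]
  list(W_proj = crossprod(cache$FP, dE),
       W_dose = matrix(colSums(dU[, m + (1:2), drop = FALSE] * cache$dprime), 1L),
       W_time = matrix(colSums(dU[, m + (3:4), drop = FALSE] * cache$tprime), 1L),
       W_cce1 = dW_cce1,
       W_cce2 = dW_cce2)
}

#' Encode a chemical condition into the gene-aligned representation
#'
#' Runs the condition encoder for one condition and returns the length-Ngene
#' compound representation D.  The pre-MLP concatenation vector
#' `[projected fingerprint, d' * W_dose, t' * W_time]` is exposed as the
#' `"concat"` attribute so the encoder's additive structure can be inspected
#' and tested.
#'
#' @param cond A [chemical_condition()].
#' @param model A `csg2a_model` (holds the CCE parameters and encoder spec).
#' @return Numeric vector of length Ngene with attribute `"concat"`.
#' @export
encode_condition <- function(cond, model) {
  stopifnot(inherits(cond, "chemical_condition"), inherits(model, "csg2a_model"))
  st <- scale_dose_time(cond$dose_uM, cond$time_h)
  FP <- matrix(as.numeric(encode_structure(cond$smiles, model$config$encoder)),
               nrow = 1L)
  act <- activation_fns(model$config$activation)
  fw <- cce_forward(FP, st[[1L]], st[[2L]], model$params, act)
  stopifnot_finite(fw$D, "chemical condition encoder")
  structure(drop(fw$D), concat = drop(fw$cache$U))
}
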