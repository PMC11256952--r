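#' Pair treated samples with per-batch control profiles
#'
#' Pairs every treated sample with the element-wise mean of the vehicle
#' (e.g. DMSO) control profiles of its batch, the basal profile g0 against
#' which the chemical perturbation is modeled.  The mean is the
#' lowest-variance deterministic summary of replicate controls.
#'
#' @param treated Samples x genes matrix of treated profiles.
#' @param controls Samples x genes matrix of control profiles (same genes).
#' @param batch_of Named character vector mapping every sample id (treated
#'   and control) to its batch.
#' @param conditions Optional `data.frame` with one row per treated sample
#'   (in `rownames(treated)` order or keyed by a `sample_id` column) carrying
#'   `smiles`, `dose_uM`, `time_h`.
#' @return An object of class `csg2a_triples`: a list with `g0` (basal,
#'   treated-sample order), `gc` (treated profiles) and `conditions` (or
#'   `NULL`).  One row per treated sample.
#' @export
pair_with_controls <- function(treated, controls, batch_of, conditions = NULL) {
  if (!identical(colnames(treated), colnames(controls)))
    stop("treated and control matrices must share an identical gene ordering")
  t_ids <- rownames(treated); c_ids <- rownames(controls)
  missing <- setdiff(c(t_ids, c_ids), names(batch_of))
  if (length(missing) > 0L)
    stop("samples without batch assignment: ", paste(head(missing, 5L), collapse = ", "))
  t_batch <- batch_of[t_ids]; c_batch <- batch_of[c_ids]
  orphan <- unique(t_batch[!(t_batch %in% c_batch)])
  if (length(orphan) > 0L)
    stop("treated batch(es) with no control sample: ",
         paste(orphan, collapse = ", "))
  ctrl_mean <- vapply(split(c_ids, c_batch), function(ids)
    colMeans(controls[ids, , drop = FALSE]), numeric(ncol(controls)))
  g0 <- t(ctrl_mean)[t_batch, , drop = FALSE]
  dimnames(g0) <- dimnames(treated)
  if (!is.null(conditions)) {
    if ("sample_id" %in% names(conditions))
      conditions <- conditions[match(t_ids, conditions$sample_id), , drop = FALSE]
    if (nrow(conditions) != nrow(treated))
      stop("conditions must have one row per treated sample")
  }
  structure(list(g0 = g0, gc = treated, conditions = conditions),
            class = "csg2a_triples")
}

#' Assemble pretraining triples from matrices and a condition table
#'
#' Convenience constructor for the `(g0, gc, condition)` triple container
#' consumed by [pretrain()] when pairing has already been done.
#'
#' @param g0,gc Samples x genes matrices, same shape and gene order.
#' @param conditions `data.frame` with `smiles`, `dose_uM`, `time_h`, one row
#'   per sample.
#' @return A `csg2a_triples` object.
#' @export
as_triples <- function(g0, gc, conditions) {
  stopifnot(identical(dim(g0), dim(gc)),
            identical(colnames(g0), colnames(gc)),
            nrow(conditions) == nrow(g0))
  structure(list(g0 = g0, gc = gc, conditions = conditions),
            class = "csg2a_triples")
}
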