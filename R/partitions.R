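#' Cross-validation partition scheme
#'
#' Constructor for the four partitioning schemes used to evaluate drug
#' response models at increasing difficulty: `mixed` (record-level k-fold),
#' `cell_blind` (entire cell lines held out), `drug_blind` (entire compounds
#' held out) and `disjoint` (both held out simultaneously).
#'
#' @param name One of `"mixed"`, `"cell_blind"`, `"drug_blind"`, `"disjoint"`.
#' @param k Fold count (>= 2).
#' @param seed Integer seed; folds are deterministic given the seed.
#' @return A `partition_scheme` list.
#' @export
partition_scheme <- function(name = c("mixed", "cell_blind", "drug_blind",
                                      "disjoint"), k = 10L, seed = 0L) {
  name <- match.arg(name)
  if (k < 2L) stop("k must be >= 2")
  structure(list(name = name, k = as.integer(k), seed = as.integer(seed)),
            class = "partition_scheme")
}

split_into_folds <- function(ids, k) {
  # shuffle then deal round-robin: balanced groups, deterministic given RNG
  shuffled <- sample(ids)
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Build cross-validation folds under a partition scheme
#'
#' For `mixed`, records are split k-fold.  For `cell_blind`/`drug_blind`,
#' cell or compound identities are split into k groups and no entity appears
#' on both sides of any fold.  For `disjoint`, cells and drugs are each split
#' into k groups; fold f tests records whose cell AND drug are both in the
#' held-out groups, trains on records whose cell AND drug are both retained,
#' and drops records mixing the two (the only construction guaranteeing both
#' train and test purity).
#'
#' @param records `data.frame` of response records with columns `cell_id` and
#'   `compound_id` (see [read_response_table()]).
#' @param scheme A [partition_scheme()].
#' @return List of `k` folds, each `list(train = <indices>, test = <indices>)`,
#'   with the scheme attached as attribute `"scheme"`.
#' @export
make_partitions <- function(records, scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  n <- nrow(records); k <- scheme$k
  cells <- unique(records$cell_id); drugs <- unique(records$compound_id)
  if (scheme$name %in% c("cell_blind", "disjoint") && length(cells) < k)
    stop("cell_blind/disjoint needs >= k distinct cells (have ",
         length(cells), ", k = ", k, ")")
  if (scheme$name %in% c("drug_blind", "disjoint") && length(drugs) < k)
    stop("drug_blind/disjoint needs >= k distinct drugs (have ",
         length(drugs), ", k = ", k, ")")
  if (scheme$name == "mixed" && n < k) stop("fewer records than folds")
  folds <- with_seed(scheme$seed, {
    switch(scheme$name,
      mixed = {
        groups <- split_into_folds(seq_len(n), k)
        lapply(groups, function(test)
          list(train = setdiff(seq_len(n), test), test = sort(test)))
      },
      cell_blind = blind_folds(records$cell_id, cells, k, n),
      drug_blind = blind_folds(records$compound_id, drugs, k, n),
      disjoint = {
        cg <- split_into_folds(cells, k)
        dg <- split_into_folds(drugs, k)
        lapply(seq_len(k), function(f) {
          test_cell <- records$cell_id %in% cg[[f]]
          test_drug <- records$compound_id %in% dg[[f]]
          list(train = which(!test_cell & !test_drug),
               test = which(test_cell & test_drug))
        })
      })
  })
  folds <- unname(folds)
  attr(folds, "scheme") <- scheme
  folds
}

blind_folds <- function(entity_of, entities, k, n) {
  groups <- split_into_folds(entities, k)
  lapply(groups, function(held) {
    test <- which(entity_of %in% held)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Write or read folds as JSON
#'
#' Folds are stored with their scheme, seed and per-fold train/test index
#' arrays (1-based).
#'
#' @param folds Result of [make_partitions()].
#' @param path JSON path.
#' @return `path` (write) or the folds list (read).
#' @export
write_folds_json <- function(folds, path) {
  scheme <- attr(folds, "scheme")
  obj <- list(scheme = scheme$name, k = scheme$k, seed = scheme$seed,
              folds = lapply(folds, function(f)
                list(train = f$train, test = f$test)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_folds_json
#' @export
read_folds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(obj$k), function(f)
    list(train = as.integer(obj$folds$train[[f]]),
         test = as.integer(obj$folds$test[[f]])))
  attr(folds, "scheme") <- partition_scheme(obj$scheme, obj$k, obj$seed)
  folds
}
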