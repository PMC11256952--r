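#' Build a binary PPI prior adjacency from a STRING-style edge list
#'
#' Reads a whitespace- or tab-separated edge list with columns
#' `(protein1, protein2, combined_score)` (optional header) and builds the
#' binary, symmetric, zero-diagonal adjacency matrix used as the prior term
#' of the attention matrix.  An edge is kept iff its combined score is
#' strictly greater than `score_threshold` and both endpoints map into
#' `gene_ids`; self-edges are dropped and edges touching unmapped proteins are
#' skipped (a count is reported via `message`).
#'
#' @param edge_list_path Path to the edge list.
#' @param gene_ids Ordered gene universe the adjacency is aligned to.
#' @param score_threshold Integer score cutoff; strict (`> threshold`).
#'   Default 900, the high-confidence STRING cutoff.
#' @param id_map Optional named character vector mapping protein identifiers
#'   to gene identifiers; by default identifiers are used as-is.
#' @return `Ngene x Ngene` 0/1 matrix with `dimnames = list(gene_ids,
#'   gene_ids)` and attribute `threshold_used`.
#' @export
load_ppi_adjacency <- function(edge_list_path, gene_ids, score_threshold = 900,
                               id_map = NULL) {
  lines <- readLines(edge_list_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", edge_list_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) start <- 2L  # header
  A <- matrix(0, length(gene_ids), length(gene_ids),
              dimnames = list(gene_ids, gene_ids))
  n_unmapped <- 0L
  for (i in seq(start, length.out = length(fields) - start + 1L)) {
    f <- fields[[i]]
    score <- suppressWarnings(as.numeric(f[3L]))
    if (length(f) < 3L || is.na(score))
      stop("malformed edge list line ", i, " in ", edge_list_path, ": ", lines[i])
    a <- f[1L]; b <- f[2L]
    if (!is.null(id_map)) {
      a <- if (a %in% names(id_map)) unname(id_map[[a]]) else NA_character_
      b <- if (b %in% names(id_map)) unname(id_map[[b]]) else NA_character_
    }
    if (is.na(a) || is.na(b) || !(a %in% gene_ids) || !(b %in% gene_ids)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (score <= score_threshold || a == b) next
    A[a, b] <- 1
    A[b, a] <- 1
  }
  if (n_unmapped > 0L)
    message("load_ppi_adjacency: skipped ", n_unmapped,
            " edge(s) touching proteins outside the gene universe")
  if (sum(A) == 0) warning("no edges kept at combined score > ", score_threshold)
  attr(A, "threshold_used") <- score_threshold
  A
}
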