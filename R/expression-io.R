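#' Read an expression matrix from delimited text or GCT
#'
#' Reads a samples x genes expression matrix from a tab- or comma-separated
#' file with one header row of identifiers and one identifier column, or from
#' a GCT 1.2/1.3 file (genes in rows, as distributed for L1000-style data).
#' The returned matrix is always oriented samples x genes with sample ids as
#' row names and gene ids as column names.
#'
#' @param path Path to the input file.
#' @param orientation Either `"samples"` (samples in rows, the default for
#'   delimited files) or `"genes"` (genes in rows; the matrix is transposed
#'   after reading).  Ignored for GCT input, which is genes-in-rows by
#'   definition.
#' @return A numeric matrix, samples x genes, with `dimnames`.
#' @details Missing values and duplicated gene identifiers are rejected with
#'   an error naming the offending entries: downstream attention indices must
#'   map one-to-one onto gene identifiers, and silent imputation would
#'   corrupt the robust z-normalization.
#' @export
read_expression_matrix <- function(path, orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty expression file: ", path)
  if (startsWith(first, "#1.2") || startsWith(first, "#1.3")) {
    mat <- read_gct(path)
  } else {
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) == 0L) stop("empty expression file: ", path)
    mat <- as.matrix(df)
    if (!is.numeric(mat)) stop("non-numeric entries in expression matrix: ", path)
    if (orientation == "genes") mat <- t(mat)
  }
  check_expression_matrix(mat, path)
  mat
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file: ", path)
  version <- trimws(lines[1L])
  dims <- strsplit(trimws(lines[2L]), "\t")[[1L]]
  n_genes <- as.integer(dims[1L]); n_samples <- as.integer(dims[2L])
  if (version == "#1.3" && length(dims) >= 4L) {
    if (any(as.integer(dims[3:4]) > 0L))
      stop("GCT 1.3 row/column metadata are not supported: ", path)
  }
  header <- strsplit(lines[3L], "\t")[[1L]]
  sample_ids <- header[-(1:2)]
  body <- strsplit(lines[-(1:3)], "\t")
  body <- body[lengths(body) > 0L]
  if (length(body) != n_genes || length(sample_ids) != n_samples)
    stop("GCT declared dimensions (", n_genes, " x ", n_samples,
         ") do not match body (", length(body), " x ", length(sample_ids), ")")
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- vapply(body, function(x) as.numeric(x[-(1:2)]), numeric(n_samples))
  mat <- if (n_samples == 1L) matrix(vals, nrow = 1L) else vals  # samples x genes
  dimnames(mat) <- list(sample_ids, gene_ids)
  mat
}

check_expression_matrix <- function(mat, label = "matrix") {
  gene_ids <- colnames(mat)
  if (is.null(gene_ids) || is.null(rownames(mat)))
    stop("expression matrix must carry sample and gene identifiers: ", label)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0L)
    stop("duplicate gene identifiers in ", label, ": ",
         paste(head(dup, 5L), collapse = ", "))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("missing value in ", label, " at sample '", rownames(mat)[idx[1L]],
         "', gene '", gene_ids[idx[2L]], "'")
  }
  invisible(mat)
}

#' Write an expression matrix to delimited text or GCT 1.2
#'
#' @param mat Numeric matrix, samples x genes, with `dimnames`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, format = c("tsv", "csv", "gct")) {
  format <- match.arg(format)
  check_expression_matrix(mat, "matrix to write")
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(ncol(mat), nrow(mat), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", rownames(mat)), collapse = "\t"), con)
    body <- apply(t(mat), 1L, function(x)
      paste(x, collapse = "\t"))
    writeLines(paste(colnames(mat), "na", body, sep = "\t"), con)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Robust z-score normalization per gene
#'
#' Standardizes each gene (column) across samples with the median/MAD robust
#' z-score \eqn{z_i = (x_i - \mathrm{median}(X)) / (1.4826 \cdot \mathrm{MAD}(X))},
#' where MAD is the unscaled median absolute deviation from the median and the
#' factor 1.4826 makes the divisor a consistent estimate of the standard
#' deviation under normality.
#'
#' Genes with MAD of zero (constant across samples) cannot be scaled; their
#' outputs are set to 0 and their identifiers are reported in a warning and in
#' the `"zeroed_genes"` attribute of the result, so landmark subsets with
#' constant genes still load.
#'
#' @param mat Numeric matrix, samples x genes, at least two samples.
#' @return Matrix of the same shape in robust-z units.
#' @export
robust_zscore <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("robust_zscore needs a matrix with >= 2 samples")
  med <- apply(mat, 2L, stats::median)
  mad0 <- apply(mat, 2L, function(x) stats::median(abs(x - stats::median(x))))
  zeroed <- colnames(mat)[mad0 == 0]
  scale <- 1.4826 * mad0
  scale[mad0 == 0] <- 1
  z <- sweep(sweep(mat, 2L, med, "-"), 2L, scale, "/")
  if (length(zeroed) > 0L) {
    z[, mad0 == 0] <- 0
    warning("MAD is zero for ", length(zeroed), " gene(s); set to 0: ",
            paste(head(zeroed, 5L), collapse = ", "))
  }
  attr(z, "zeroed_genes") <- zeroed
  z
}

#' Re-index an expression matrix to a canonical gene ordering
#'
#' The gene ordering of the pretraining matrix is canonical for the lifetime
#' of a model (attention row/column i always refers to gene i of that
#' ordering).  Later matrices are re-indexed to it here.
#'
#' @param mat Samples x genes matrix.
#' @param gene_ids Canonical gene ordering.
#' @param impute Value used to fill genes absent from `mat` (in robust-z
#'   units).  When `NULL` (default) missing genes are an error.
#' @return Matrix with columns exactly `gene_ids`, in order.
#' @export
align_genes <- function(mat, gene_ids, impute = NULL) {
  missing <- setdiff(gene_ids, colnames(mat))
  if (length(missing) > 0L && is.null(impute))
    stop("matrix lacks ", length(missing), " canonical gene(s): ",
         paste(head(missing, 5L), collapse = ", "))
  out <- matrix(impute %||% 0, nrow = nrow(mat), ncol = length(gene_ids),
                dimnames = list(rownames(mat), gene_ids))
  present <- intersect(gene_ids, colnames(mat))
  out[, present] <- mat[, present, drop = FALSE]
  out
}

#' Read a drug-response table
#'
#' CSV with columns `cell_id`, `compound_id`, `smiles`, `log_ic50`
#' (natural-log IC50 as distributed by GDSC; lower = more sensitive).
#'
#' @param path CSV path.
#' @return A `data.frame` with those columns; non-finite `log_ic50` is an
#'   error.
#' @export
read_response_table <- function(path) {
  df <- utils::read.delim(path, sep = ",", stringsAsFactors = FALSE)
  needed <- c("cell_id", "compound_id", "smiles", "log_ic50")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L)
    stop("response table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$log_ic50)))
    stop("non-finite log_ic50 values in ", path)
  df[needed]
}

#' Read a compound condition table
#'
#' CSV with columns `compound_id`, `smiles`, `dose_uM`, `time_h`; one row per
#' treated sample or per compound.
#'
#' @param path CSV path.
#' @return A `data.frame` with those columns.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, sep = ",", stringsAsFactors = FALSE)
  needed <- c("compound_id", "smiles", "dose_uM", "time_h")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L)
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$dose_uM < 0) || any(df$time_h < 0))
    stop("negative dose or time in ", path)
  df
}
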