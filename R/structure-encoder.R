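# SMILES handling and the default structure encoder.
#
# The structure-embedding slot is pluggable: the default is a hashed circular
# substructure fingerprint (ECFP, radius 2 -> "ECFP4" in OpenBabel naming)
# folded to m bits, followed by a trainable bias-free linear projection that
# lives with the model parameters.  A custom encoder can be supplied as a
# function smiles -> numeric vector.

.fp_cache <- new.env(parent = emptyenv())

#' Canonicalize a SMILES string
#'
#' Chemically identical strings must encode identically, so every SMILES is
#' canonicalized (OpenBabel canonical SMILES) before fingerprinting.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!nzchar(s)) stop("empty SMILES string")
    key <- paste0("can:", s)
    if (!is.null(.fp_cache[[key]])) return(.fp_cache[[key]])
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
    out <- sub("\t.*$", "", trimws(out))
    if (!nzchar(out)) stop("unparseable SMILES: '", s, "'")
    .fp_cache[[key]] <- out
    out
  }, character(1L), USE.NAMES = FALSE)
}

#' Structure encoder specification
#'
#' @param type `"fingerprint"` (default) or `"custom"`.
#' @param bits Fingerprint length m after folding (fingerprint type).
#' @param radius Circular substructure radius (default 2).
#' @param fn For `type = "custom"`, a function `smiles -> numeric(bits)`.
#' @return A `structure_encoder` list.
#' @export
structure_encoder <- function(type = c("fingerprint", "custom"), bits = 128L,
                              radius = 2L, fn = NULL) {
  type <- match.arg(type)
  if (type == "custom" && !is.function(fn))
    stop("custom encoder needs a function `fn`")
  structure(list(type = type, bits = as.integer(bits),
                 radius = as.integer(radius), fn = fn,
                 name = if (type == "fingerprint")
                   paste0("ecfp", 2L * radius, "_", bits) else "custom"),
            class = "structure_encoder")
}

#' Encode a molecular structure as a deterministic embedding
#'
#' Default path: canonical SMILES -> circular fingerprint of the configured
#' radius (OpenBabel ECFP) -> fold to `bits` positions by OR-ing bit i of the
#' full fingerprint into position i mod bits.  Deterministic for a given
#' canonical SMILES; the trainable projection on top of this belongs to the
#' model, not to this function.
#'
#' @param smiles A single SMILES string.
#' @param encoder A [structure_encoder()] (default fingerprint, 128 bits,
#'   radius 2).
#' @return Numeric vector of length `encoder$bits` with attribute
#'   `encoder_name`.
#' @export
encode_structure <- function(smiles, encoder = structure_encoder()) {
  stopifnot(inherits(encoder, "structure_encoder"), length(smiles) == 1L)
  canon <- canonicalize_smiles(smiles)
  if (encoder$type == "custom") {
    v <- encoder$fn(canon)
    if (length(v) != encoder$bits) stop("custom encoder returned wrong length")
    return(structure(as.numeric(v), encoder_name = encoder$name))
  }
  key <- paste0("fp", encoder$radius, ":", encoder$bits, ":", canon)
  if (!is.null(.fp_cache[[key]]))
    return(structure(.fp_cache[[key]], encoder_name = encoder$name))
  mol <- ChemmineOB::forEachMol("SMILES", canon, identity)
  full <- as.numeric(ChemmineOB::fingerprint_OB(mol, paste0("ECFP", 2L * encoder$radius)))
  idx <- ((seq_along(full) - 1L) %% encoder$bits) + 1L
  folded <- as.numeric(tapply(full, idx, max))
  .fp_cache[[key]] <- folded
  structure(folded, encoder_name = encoder$name)
}

# batched fingerprints for a vector of SMILES -> B x bits matrix
fingerprint_matrix <- function(smiles, encoder) {
  unname(t(vapply(smiles, function(s) as.numeric(encode_structure(s, encoder)),
                  numeric(encoder$bits), USE.NAMES = FALSE)))
}
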