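#' Fingerprint encoding configuration
#'
#' Defaults reproduce the encoding used throughout the package for real
#' molecules: a 4096-bit circular substructure fingerprint (ECFP6, i.e. radius
#' 3) concatenated with the first 166 MACCS substructure key bits, for a total
#' of 4262 bits. Both lengths are overridable so that toy fingerprints (e.g.
#' the 512-bit synthetic compounds) flow through the same code paths.
#'
#' @param nCircularBits circular-fingerprint length (default 4096)
#' @param radius circular-fingerprint radius (default 3; informational -- the
#'   OpenBabel backend's ECFP6 corresponds to radius 3)
#' @param nSubstructureBits number of substructure-key bits appended
#'   (default 166)
#' @return a list of class `fingerprintConfig`
#' @export
fingerprintConfig <- function(nCircularBits = 4096L, radius = 3L,
                              nSubstructureBits = 166L) {
  stopifnot(nCircularBits >= 1L, nSubstructureBits >= 0L)
  structure(list(nCircularBits = as.integer(nCircularBits),
                 radius = as.integer(radius),
                 nSubstructureBits = as.integer(nSubstructureBits)),
            class = "fingerprintConfig")
}

# parse a batch of SMILES to OpenBabel molecule refs; errors name the id
.parseSmiles <- function(smiles, ids) {
  bad <- which(is.na(smiles) | !nzchar(smiles))
  if (length(bad))
    stop("unparsable SMILES for compound(s): ",
         paste(ids[bad], collapse = ", "))
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(mols) != length(smiles))
    stop("SMILES parsing failed for one of: ", paste(ids, collapse = ", "))
  mols
}

#' Encode SMILES as concatenated circular + substructure-key bit fingerprints
#'
#' Each molecule is encoded as `nCircularBits` circular-substructure bits
#' followed by `nSubstructureBits` MACCS key bits. Encoding is deterministic:
#' the same SMILES always yields the same bits.
#'
#' @param smiles character vector of SMILES strings
#' @param ids compound ids (used in error messages and as rownames); defaults
#'   to names of `smiles` or seq_along
#' @param config a [fingerprintConfig()]
#' @return integer 0/1 matrix with one row per compound,
#'   `nCircularBits + nSubstructureBits` columns
#' @examples
#' bits <- encodeFingerprint(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' dim(bits)  # 2 x 4262
#' @export
encodeFingerprint <- function(smiles, ids = NULL,
                              config = fingerprintConfig()) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  mols <- .parseSmiles(smiles, ids)
  circ <- ChemmineOB::fingerprint_OB(mols, "ECFP6")
  macc <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  circ <- matrix(as.integer(circ), nrow = length(smiles))
  macc <- matrix(as.integer(macc), nrow = length(smiles))
  nc <- config$nCircularBits
  ns <- config$nSubstructureBits
  if (ncol(circ) < nc)
    stop("backend circular fingerprint shorter than requested length")
  out <- cbind(circ[, seq_len(nc), drop = FALSE],
               macc[, seq_len(ns), drop = FALSE])
  rownames(out) <- ids
  storage.mode(out) <- "integer"
  out
}

#' Pack a bit fingerprint into bytes (MSB-first)
#'
#' Losslessly packs each successive 8 bits into one byte, padding the tail
#' with zero bits to a multiple of eight. A 4262-bit fingerprint packs into
#' `ceiling(4262/8) = 533` bytes. The first bit of the input becomes the most
#' significant bit of the first byte.
#'
#' @param bits integer 0/1 vector, or a 0/1 matrix with one fingerprint per
#'   row
#' @return integer byte vector (or matrix) with values in \[0, 255\]
#' @seealso [unpackFingerprint()] for the exact inverse
#' @export
packFingerprint <- function(bits) {
  if (is.matrix(bits)) {
    nbytes <- as.integer(ceiling(ncol(bits) / 8))
    res <- vapply(seq_len(nrow(bits)), function(i)
      packFingerprint(bits[i, ]), integer(nbytes))
    out <- if (nbytes == 1L) matrix(res, ncol = 1L) else t(res)
    storage.mode(out) <- "integer"
    rownames(out) <- rownames(bits)
    return(out)
  }
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint bits must be 0/1")
  n <- length(bits)
  npad <- ceiling(n / 8) * 8 - n
  b <- c(as.integer(bits), integer(npad))
  m <- matrix(b, nrow = 8)
  as.integer(colSums(m * bitwShiftL(1L, 7:0)))
}

#' Unpack bytes back to the original bit fingerprint
#'
#' @param bytes integer byte vector (values in \[0, 255\])
#' @param nbits number of meaningful leading bits to return
#' @return integer 0/1 vector of length `nbits`
#' @export
unpackFingerprint <- function(bytes, nbits) {
  stopifnot(nbits <= 8 * length(bytes))
  bits <- as.integer(
    vapply(bytes, function(b) as.integer(bitwAnd(b, bitwShiftL(1L, 7:0)) != 0L),
           integer(8)))
  bits[seq_len(nbits)]
}

#' Build a FingerprintSet from a library of bit fingerprints
#'
#' @param bits 0/1 matrix, one fingerprint per row, rownames = compound ids
#' @param ids optional compound ids overriding rownames
#' @return a [FingerprintSet-class]
#' @export
fingerprintSet <- function(bits, ids = rownames(bits)) {
  if (is.null(ids)) stop("compound ids required")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  packed <- packFingerprint(bits)
  if (!is.matrix(packed)) packed <- matrix(packed, nrow = 1)
  rownames(packed) <- ids
  new("FingerprintSet", bytes = packed, nbits = as.integer(ncol(bits)))
}

#' Encode a compound table into a FingerprintSet
#'
#' Reads `(compound_id, smiles)` pairs and returns packed fingerprints.
#'
#' @param compounds data frame with columns `compound_id` and `smiles`
#' @param config a [fingerprintConfig()]
#' @return a [FingerprintSet-class]
#' @export
encodeLibrary <- function(compounds, config = fingerprintConfig()) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  bits <- encodeFingerprint(compounds$smiles, ids = compounds$compound_id,
                            config = config)
  fingerprintSet(bits)
}

# popcount of an integer byte vector
.popcount <- function(bytes) sum(.popcount8[bytes + 1L])

#' Tanimoto similarity of packed fingerprints
#'
#' Computes `|A & B| / (|A| + |B| - |A & B|)` by popcount directly on packed
#' bytes. Because the packing is lossless and popcount is bit-order
#' invariant, this equals the Tanimoto similarity of the unpacked bit
#' vectors exactly. Two all-zero fingerprints are defined to have similarity
#' 0 (an empty molecule matches nothing).
#'
#' @param a,b integer byte vectors of equal length (packed fingerprints)
#' @return similarity in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("packed fingerprints differ in length")
  inter <- .popcount(bitwAnd(a, b))
  uni <- .popcount(a) + .popcount(b) - inter
  if (uni == 0) return(0)
  inter / uni
}

# all-vs-all (or cross) Tanimoto similarity from packed byte matrices.
# Unpacks to a 0/1 matrix and uses BLAS crossproducts; exact.
.tanimotoMatrix <- function(bytesA, nbits, bytesB = NULL) {
  unpack <- function(bytes) {
    n <- nrow(bytes)
    B <- matrix(0, n, ncol(bytes) * 8L)
    for (k in 0:7) {
      B[, seq(k + 1L, ncol(bytes) * 8L, by = 8L)] <-
        (bitwAnd(bytes, bitwShiftL(1L, 7L - k)) != 0L) + 0
    }
    B[, seq_len(nbits), drop = FALSE]
  }
  A <- unpack(bytesA)
  B <- if (is.null(bytesB)) A else unpack(bytesB)
  inter <- tcrossprod(A, B)
  pa <- rowSums(A)
  pb <- rowSums(B)
  uni <- outer(pa, pb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(bytesA),
                        rownames(if (is.null(bytesB)) bytesA else bytesB))
  sim
}

#' Write / read packed fingerprints as a portable text table
#'
#' Layout (version 1): a JSON header line holding `nbits` and the format
#' version, then one line per compound: `id<TAB>hex-encoded bytes`.
#'
#' @param fps a [FingerprintSet-class]
#' @param path output file
#' @return `writeFingerprints()` returns `path` invisibly;
#'   `readFingerprints()` returns a [FingerprintSet-class].
#' @export
writeFingerprints <- function(fps, path) {
  hdr <- jsonlite::toJSON(list(format = "csnn-fp", version = 1L,
                               nbits = fps@nbits), auto_unbox = TRUE)
  hex <- apply(fps@bytes, 1, function(r) paste(sprintf("%02x", r),
                                               collapse = ""))
  writeLines(c(as.character(hdr),
               paste(rownames(fps@bytes), hex, sep = "\t")), path)
  invisible(path)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "csnn-fp"))
    stop("not a csnn fingerprint file: ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, "", 1L)
  bytes <- t(vapply(body, function(x) {
    strtoi(substring(x[[2]], seq(1, nchar(x[[2]]), 2),
                     seq(2, nchar(x[[2]]), 2)), 16L)
  }, integer(ceiling(hdr$nbits / 8))))
  rownames(bytes) <- ids
  storage.mode(bytes) <- "integer"
  new("FingerprintSet", bytes = bytes, nbits = as.integer(hdr$nbits))
}
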