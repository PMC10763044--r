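#' Binary fingerprint
#'
#' A fingerprint is the set of set-bit indices of a fixed-length binary key
#' vector: 166 MACCS structural keys for a small molecule, or the `4^k`
#' possible k-mers for a miRNA sequence.
#'
#' @param bits Integer vector of 0-based set-bit indices.
#' @param length Total number of bits.
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(bits, length) {
  bits <- sort(unique(as.integer(bits)))
  length <- as.integer(length)
  if (any(bits < 0L | bits >= length)) stopf("bit indices must lie in [0, %d)", length)
  structure(list(bits = bits, length = length), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint: %d/%d bits set\n", length(x$bits), x$length))
  invisible(x)
}

#' MACCS structural-key fingerprints from SMILES
#'
#' Computes the standard 166-key MACCS fingerprint for each molecule via
#' OpenBabel (package \pkg{ChemmineOB}). Unparsable SMILES do not abort the
#' run: the molecule is dropped with a warning and reported in the
#' `rejects` component, mirroring pipeline semantics where a bad structure
#' should not crash a batch.
#'
#' @param sm_table Data.frame with columns `sm_id` and `smiles`
#'   (see [read_sm_table()]).
#' @return List with `fingerprints` (named list of 166-bit [fingerprint()]
#'   objects keyed by `sm_id`) and `rejects` (character vector of dropped
#'   `sm_id`s).
#' @export
maccs_fingerprints <- function(sm_table) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stopf("maccs_fingerprints() needs the suggested package 'ChemmineOB'")
  }
  fps <- list()
  rejects <- character(0)
  for (i in seq_len(nrow(sm_table))) {
    id <- sm_table$sm_id[[i]]
    row <- try(suppressWarnings(ChemmineOB::forEachMol(
      "SMILES", sm_table$smiles[[i]],
      function(m) ChemmineOB::fingerprint_OB(list(m), "MACCS")
    )), silent = TRUE)
    ok <- !inherits(row, "try-error") && is.numeric(row[[1]]) && sum(row[[1]]) > 0
    if (!ok) {
      warning(sprintf("dropping unparsable SMILES for %s", id), call. = FALSE)
      rejects <- c(rejects, id)
      next
    }
    # OpenBabel bit b (0-based) is MACCS key b+1; keys occupy 1..166.
    keys <- which(row[[1]][seq_len(167L)] == 1) - 1L
    keys <- keys[keys >= 1L]
    fps[[id]] <- fingerprint(keys - 1L, 166L)
  }
  list(fingerprints = fps, rejects = rejects)
}

#' k-mer presence fingerprint of a miRNA sequence
#'
#' Binary presence vector over all `4^k` k-mers of the U-normalized
#' sequence; the natural sequence analogue of a structural-key fingerprint.
#'
#' @param sequence RNA string over `A`, `C`, `G`, `U` (a `T` is accepted and
#'   read as `U`).
#' @param k k-mer size (default 4).
#' @return A [fingerprint()] of length `4^k`.
#' @export
kmer_fingerprint <- function(sequence, k = 4L) {
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  seq <- chartr("T", "U", toupper(sequence))
  n <- nchar(seq)
  if (n < k) stopf("sequence length %d is shorter than k = %d", n, k)
  code <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% names(code))) {
    stopf("invalid character '%s' in sequence", setdiff(chars, names(code))[[1]])
  }
  digits <- code[chars]
  idx <- vapply(seq_len(n - k + 1L), function(i) {
    sum(digits[i:(i + k - 1L)] * 4L^((k - 1L):0L))
  }, numeric(1))
  fingerprint(unique(as.integer(idx)), 4L^k)
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|A intersect B| / |A union B|`; 0 when both bit sets are empty.
#'
#' @param a,b [fingerprint()] objects of equal length.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$length != b$length) stopf("fingerprint lengths differ: %d vs %d", a$length, b$length)
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' Tanimoto self-similarity matrix
#'
#' Full symmetric matrix of pairwise Tanimoto coefficients over a set of
#' equal-length fingerprints. Deterministic; permuting the input only
#' permutes rows/columns.
#'
#' @param fps Named list of [fingerprint()] objects.
#' @return Symmetric numeric matrix with unit diagonal, dimnames the
#'   fingerprint ids.
#' @export
similarity_matrix <- function(fps) {
  if (length(fps) < 2L) stopf("need at least 2 fingerprints")
  lens <- unique(vapply(fps, function(f) f$length, integer(1)))
  if (length(lens) != 1L) stopf("mixed fingerprint lengths: %s", paste(lens, collapse = ", "))
  n <- length(fps)
  B <- matrix(0L, nrow = n, ncol = lens)
  for (i in seq_len(n)) B[i, fps[[i]]$bits + 1L] <- 1L
  inter <- B %*% t(B)
  pop <- diag(inter)
  uni <- outer(pop, pop, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- 1
  dimnames(S) <- list(names(fps), names(fps))
  S
}
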