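# Amino-acid alphabet and substitution scoring.

#' The amino-acid alphabet accepted by the pipeline
#'
#' The 20 standard amino-acid letters plus `X` (unknown residue). Ambiguity
#' codes (`B`, `Z`, `J`), selenocysteine/pyrrolysine (`U`, `O`) and gaps are
#' rejected at validation rather than silently remapped.
#'
#' @return Character vector of 21 single letters.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
    "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

# NCBI BLOSUM62 restricted to the 21-letter alphabet. The X row/column is
# the matrix's own (all -1), so X never counts as a positive (similar) pair.
.blosum62_values <- matrix(c(
  4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0, -1,
 -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1,
 -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3, -1,
 -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3, -1,
  0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -1,
 -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2, -1,
 -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2, -1,
  0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1,
 -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3, -1,
 -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -1,
 -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -1,
 -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2, -1,
 -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -1,
 -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -1,
 -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -1,
  1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2, -1,
  0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0, -1,
 -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -1,
 -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -1,
  0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -1,
 -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1
), nrow = 21, byrow = TRUE)

#' BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 log-odds scores over the 21-letter alphabet of
#' [aa_alphabet()], embedded as a constant so that no external data files are
#' needed. All `X` scores are -1, so an `X` can never contribute a positive
#' (similar) or identical column to alignment statistics.
#'
#' @return A symmetric 21 x 21 integer matrix with dimnames set to the
#'   alphabet and a `"name"` attribute equal to `"BLOSUM62"`.
#' @examples
#' m <- blosum62()
#' m["A", "A"]  # 4
#' m["I", "L"]  # 2
#' @export
blosum62 <- function() {
  m <- .blosum62_values
  dimnames(m) <- list(aa_alphabet(), aa_alphabet())
  attr(m, "name") <- "BLOSUM62"
  m
}

# Validate a substitution matrix: symmetric, covers the alphabet, positive
# diagonal for standard letters, non-positive X scores.
check_substitution_matrix <- function(matrix) {
  aa <- aa_alphabet()
  if (!all(aa %in% rownames(matrix)) || !all(aa %in% colnames(matrix))) {
    abort("substitution matrix must cover the 21-letter amino-acid alphabet")
  }
  m <- matrix[aa, aa]
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    abort("substitution matrix must be symmetric")
  }
  std <- setdiff(aa, "X")
  if (any(diag(m[std, std]) <= 0)) {
    abort("substitution matrix diagonal must be positive for standard letters")
  }
  if (any(m["X", ] > 0)) {
    abort("substitution matrix scores involving 'X' must be 0 or negative")
  }
  invisible(m)
}
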