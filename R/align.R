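# Affine-gap global pairwise alignment and position-equivalence maps.
#
# Alignment is true global (Needleman-Wunsch with affine penalties and
# penalized terminal gaps). A gap of length k costs gap_open +
# (k - 1) * gap_extend, the EMBOSS needle convention; Biostrings charges
# gapOpening + k * gapExtension, so the penalties are re-parameterized
# before the call.

#' Optimal global pairwise alignment with affine gap penalties
#'
#' Aligns two protein sequences end to end, maximizing the substitution
#' score minus affine gap costs (a gap of length *k* costs
#' `gap_open + (k - 1) * gap_extend`; terminal gaps are penalized). This is
#' the reference-anchored alignment used for identity gating, junction
#' location and catalytic-residue coordinate transfer.
#'
#' @param a,b Single sequence records (one-row tibbles from [aa_records()])
#'   or plain residue strings.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open Gap opening penalty, charged on the first gapped residue
#'   (default 10).
#' @param gap_extend Gap extension penalty per additional gapped residue
#'   (default 0.5).
#'
#' @return An object of class `pairwise_alignment`: a list with `id_a`,
#'   `id_b`, `row_a`, `row_b` (equal-length gapped strings), `score`,
#'   `gap_open`, `gap_extend`.
#' @examples
#' aln <- align_global("ARND", "ARND")
#' aln$score  # 21
#' @export
align_global <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5) {
  ra <- as_single_record(a, "seq_a")
  rb <- as_single_record(b, "seq_b")
  if (nchar(ra$residues) == 0 || nchar(rb$residues) == 0) {
    abort("align_global: both sequences must be non-empty")
  }
  m <- check_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ra$residues), Biostrings::AAString(rb$residues),
    substitutionMatrix = m, type = "global",
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend
  )
  out <- structure(list(
    id_a = ra$id, id_b = rb$id,
    row_a = as.character(Biostrings::alignedPattern(pa)),
    row_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    gap_open = gap_open, gap_extend = gap_extend
  ), class = "pairwise_alignment")
  stopifnot(nchar(out$row_a) == nchar(out$row_b),
            gsub("-", "", out$row_a, fixed = TRUE) == ra$residues,
            gsub("-", "", out$row_b, fixed = TRUE) == rb$residues)
  out
}

# Accept a one-row record tibble, a named or bare string.
as_single_record <- function(x, default_id) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("expected exactly one sequence record")
    return(list(id = x$id[1], residues = toupper(x$residues[1])))
  }
  if (is.character(x) && length(x) == 1) {
    id <- names(x) %||% default_id
    return(list(id = id, residues = toupper(unname(x))))
  }
  abort("expected a one-row record tibble or a single residue string")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s (score %.1f, gap %g/%g)\n",
              x$id_a, x$id_b, x$score, x$gap_open, x$gap_extend))
  cat(sprintf("identity %.1f%%, similarity %.1f%% over %d columns\n",
              100 * percent_identity(x), 100 * percent_similarity(x),
              nchar(x$row_a)))
  invisible(x)
}

aln_columns <- function(aln) {
  list(a = strsplit(aln$row_a, "", fixed = TRUE)[[1]],
       b = strsplit(aln$row_b, "", fixed = TRUE)[[1]])
}

#' Percent identity of a pairwise alignment
#'
#' Fraction of columns in which both rows carry the same standard residue.
#' `X` never counts as identical. By default the denominator is the full
#' alignment length including gapped columns (the EMBOSS needle
#' convention); `denominator = "aligned"` restricts it to columns where
#' both rows are non-gap, since published identity figures do not always
#' state their convention.
#'
#' @param aln A `pairwise_alignment`.
#' @param denominator `"alignment"` (all columns, default) or `"aligned"`
#'   (both-non-gap columns only).
#' @return A fraction in \[0, 1\].
#' @export
percent_identity <- function(aln, denominator = c("alignment", "aligned")) {
  denominator <- match.arg(denominator)
  cols <- aln_columns(aln)
  ident <- cols$a == cols$b & cols$a != "-" & cols$a != "X"
  denom <- if (denominator == "alignment") length(cols$a)
           else sum(cols$a != "-" & cols$b != "-")
  if (denom == 0) return(0)
  sum(ident) / denom
}

#' Percent similarity of a pairwise alignment
#'
#' Fraction of columns in which both residues are non-gap and their
#' substitution score is strictly positive. Under BLOSUM62 every identical
#' standard pair is also similar, and `X` (scores all -1) never is.
#'
#' @inheritParams percent_identity
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return A fraction in \[0, 1\].
#' @export
percent_similarity <- function(aln, matrix = blosum62(),
                               denominator = c("alignment", "aligned")) {
  denominator <- match.arg(denominator)
  cols <- aln_columns(aln)
  both <- cols$a != "-" & cols$b != "-"
  sim <- logical(length(cols$a))
  sim[both] <- matrix[cbind(cols$a[both], cols$b[both])] > 0
  denom <- if (denominator == "alignment") length(cols$a) else sum(both)
  if (denom == 0) return(0)
  sum(sim) / denom
}

#' Position-equivalence map of a pairwise alignment
#'
#' Extracts the aligned (non-gap/non-gap) columns as pairs of 1-based
#' sequence coordinates. This is the mechanism for transferring parent
#' residue numbering (e.g. "Arg105", "Lys240") onto a candidate: the
#' candidate position paired with a parent position is its aligned
#' equivalent.
#'
#' @param aln A `pairwise_alignment`.
#' @return A tibble with columns `pos_a` and `pos_b`, strictly increasing
#'   in both coordinates.
#' @examples
#' column_map(align_global("ARND", "ARKND"))
#' @export
column_map <- function(aln) {
  cols <- aln_columns(aln)
  pos_a <- cumsum(cols$a != "-")
  pos_b <- cumsum(cols$b != "-")
  both <- cols$a != "-" & cols$b != "-"
  tibble(pos_a = pos_a[both], pos_b = pos_b[both])
}
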