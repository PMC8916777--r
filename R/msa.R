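# Center-star multiple alignment and gap-column masking.
#
# The screen is reference-anchored: every candidate is already optimally
# aligned to the parent, so the multiple alignment is built by classic
# center-star merging of those pairwise alignments ("once a gap, always a
# gap"), with the parent as the center. Each row's induced pairwise
# alignment to the center preserves the residue correspondences of its
# optimal pairwise alignment.

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) <= 1)
  structure(list(ids = ids, rows = setNames(unname(rows), ids),
                 n_col = if (length(rows)) nchar(rows[[1]]) else 0L),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_col))
  invisible(x)
}

# Character matrix view (rows = sequences).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Center-star multiple sequence alignment
#'
#' Builds a multiple alignment by merging the optimal global pairwise
#' alignment of every sequence to a designated center sequence (the CylK
#' parent in the pipeline), inserting gaps so that all previously merged
#' rows stay consistent.
#'
#' @param records Tibble of sequence records (at least 2).
#' @param center_id Id of the center sequence; must be in `records`.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return A `multiple_alignment` whose first row is the center.
#' @export
center_star_msa <- function(records, center_id, matrix = blosum62(),
                            gap_open = 10, gap_extend = 0.5) {
  records <- validate_records(records)
  if (nrow(records) < 2) abort("center_star_msa: need at least 2 sequences")
  ci <- match(center_id, records$id)
  if (is.na(ci)) abort(paste0("center sequence not found: ", center_id))
  center <- records[ci, ]
  others <- records[-ci, , drop = FALSE]

  rows <- list(strsplit(center$residues, "", fixed = TRUE)[[1]])
  ids <- center$id
  for (k in seq_len(nrow(others))) {
    aln <- align_global(center, others[k, ], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
    p <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]  # center, freshly gapped
    q <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
    master <- rows[[1]]
    i <- 1L; j <- 1L
    keep_master <- integer(0)  # source: >0 master col, -j new col, 0 gap-in-old
    new_row <- character(0)
    while (i <= length(master) || j <= length(p)) {
      if (i <= length(master) && master[i] == "-") {
        keep_master <- c(keep_master, i); new_row <- c(new_row, "-"); i <- i + 1L
      } else if (j <= length(p) && p[j] == "-") {
        keep_master <- c(keep_master, 0L); new_row <- c(new_row, q[j]); j <- j + 1L
      } else if (i <= length(master) && j <= length(p)) {
        # both carry the same center residue
        keep_master <- c(keep_master, i); new_row <- c(new_row, q[j])
        i <- i + 1L; j <- j + 1L
      } else {
        abort("center_star_msa: inconsistent center rows during merge")
      }
    }
    rows <- lapply(rows, function(r) {
      out <- rep("-", length(keep_master))
      out[keep_master > 0] <- r[keep_master[keep_master > 0]]
      out
    })
    rows[[length(rows) + 1L]] <- new_row
    ids <- c(ids, others$id[k])
  }
  msa <- new_msa(ids, vapply(rows, paste, character(1), collapse = ""))
  stopifnot(all(gsub("-", "", msa$rows, fixed = TRUE) ==
                  records$residues[match(msa$ids, records$id)]))
  msa
}

#' Remove gap-dominated alignment columns
#'
#' Drops exactly the columns whose gap fraction is greater than or equal to
#' `threshold` (a column with gaps in 90% of sequences is removed at the
#' default), leaving row order unchanged.
#'
#' @param msa A `multiple_alignment`.
#' @param threshold Gap-fraction cutoff, inclusive (default 0.90).
#' @return The masked `multiple_alignment`, with attributes `n_removed` and
#'   `removed_columns`.
#' @export
mask_gap_columns <- function(msa, threshold = 0.90) {
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  drop <- gap_frac >= threshold
  if (all(drop)) abort("empty alignment after masking")
  kept <- m[, !drop, drop = FALSE]
  out <- new_msa(msa$ids, apply(kept, 1, paste, collapse = ""))
  attr(out, "n_removed") <- sum(drop)
  attr(out, "removed_columns") <- which(drop)
  out
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa A `multiple_alignment`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(msa$ids)) {
    writeLines(paste0(">", msa$ids[i]), con)
    writeLines(wrap_residues(msa$rows[[i]], width), con)
  }
  invisible(path)
}

#' Read a multiple alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return A `multiple_alignment`.
#' @export
read_msa_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  is_header <- startsWith(lines, ">")
  if (length(lines) == 0 || !is_header[1]) {
    abort("aligned FASTA parse error: no '>' header at start")
  }
  grp <- cumsum(is_header)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  rows <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste, character(1), collapse = "")
  rows <- toupper(unname(rows))
  if (length(unique(nchar(rows))) > 1) {
    abort("aligned FASTA rows have unequal lengths")
  }
  new_msa(ids, rows)
}
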