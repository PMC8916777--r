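# Sequence records and FASTA I/O.
#
# A sequence collection is an ordinary tibble with columns id, description,
# organism_id and residues, so it composes with dplyr verbs; constructors
# and readers enforce the record invariants (non-empty uppercase residues
# over the 21-letter alphabet, unique ids).

#' Build a validated tibble of protein sequence records
#'
#' @param id Character vector of unique, accession-like identifiers.
#' @param residues Character vector of residue strings; uppercased on entry.
#' @param description Free-text descriptions (recycled; default empty).
#' @param organism_id Organism/genome identifiers (recycled; default empty).
#'
#' @return A tibble with columns `id`, `description`, `organism_id`,
#'   `residues`, one row per sequence.
#' @examples
#' aa_records(c("s1", "s2"), c("ARND", "MKV"))
#' @export
aa_records <- function(id, residues, description = "", organism_id = "") {
  recs <- tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    organism_id = rep_len(as.character(organism_id), length(id)),
    residues = toupper(as.character(residues))
  )
  validate_records(recs)
}

#' Validate a tibble of sequence records
#'
#' Checks that residues are non-empty, uppercase, restricted to the
#' 21-letter alphabet, and that ids are unique. Errors name the offending
#' record and residue position.
#'
#' @param records A tibble as returned by [aa_records()] or [read_fasta()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  if (!"description" %in% names(records)) records$description <- ""
  if (!"organism_id" %in% names(records)) records$organism_id <- ""
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(records$residues)) || any(nchar(records$residues) == 0)) {
    bad <- records$id[is.na(records$residues) | nchar(records$residues) == 0]
    abort(paste0("empty residue string for record(s): ", paste(bad, collapse = ", ")))
  }
  allowed <- aa_alphabet()
  for (i in seq_len(nrow(records))) {
    letters_i <- strsplit(records$residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!(letters_i %in% allowed))
    if (length(bad) > 0) {
      abort(sprintf(
        "record '%s': disallowed residue letter '%s' at position %d",
        records$id[i], letters_i[bad[1]], bad[1]))
    }
  }
  as_tibble(records[, c("id", "description", "organism_id", "residues")])
}

#' Read protein sequences from a FASTA file
#'
#' The id is the first whitespace-delimited token of the header (GenBank
#' convention); the remainder becomes the description. Residues are
#' uppercased and a single terminal `*` (stop) is stripped before
#' validation. Malformed input produces an error naming the line; residues
#' outside the 21-letter alphabet produce an error naming the record and
#' position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of sequence records (see [aa_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(aa_records(character(), character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(sprintf("FASTA parse error at line 1: residues before any '>' header"))
  }
  grp <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste, character(1), collapse = "")
  # headers with no body at all
  body_count <- tabulate(grp[!is_header], nbins = max(grp))
  if (any(body_count == 0)) {
    bad_line <- which(is_header)[which(body_count == 0)[1]]
    abort(sprintf("FASTA parse error at line %d: header '%s' has no sequence",
                  bad_line, id[which(body_count == 0)[1]]))
  }
  seqs <- toupper(unname(seqs))
  seqs <- sub("\\*$", "", seqs)
  aa_records(id = id, residues = seqs, description = description)
}

#' Write sequence records to a FASTA file
#'
#' Headers are `>id description` (description omitted when empty); sequence
#' bodies are wrapped at `width` columns. `read_fasta()` of the output
#' reproduces ids, descriptions and residues exactly.
#'
#' @param records Tibble of sequence records.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  records <- validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i])) {
      paste0(">", records$id[i], " ", records$description[i])
    } else {
      paste0(">", records$id[i])
    }
    writeLines(header, con)
    writeLines(wrap_residues(records$residues[i], width), con)
  }
  invisible(path)
}

wrap_residues <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Remove exact duplicate sequences
#'
#' Retains the first occurrence of each exact residue string, preserving
#' input order, so that independent searches against several parents can be
#' merged into a nonredundant candidate list. The number of removed records
#' is attached as attribute `n_removed`.
#'
#' @param records Tibble of sequence records.
#' @return The deduplicated tibble with attribute `n_removed`.
#' @examples
#' r <- aa_records(c("a", "b"), c("ARND", "ARND"))
#' nrow(dedupe_sequences(r))  # 1
#' @export
dedupe_sequences <- function(records) {
  records <- validate_records(records)
  keep <- !duplicated(records$residues)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Convert a records tibble to a named Biostrings AAStringSet for alignment.
as_aastringset <- function(records) {
  x <- Biostrings::AAStringSet(records$residues)
  names(x) <- records$id
  x
}
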