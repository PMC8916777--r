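# The homolog screen: identity gate, dual-domain architecture filter,
# catalytic-residue equivalence mapping.

#' Configuration for the homolog screen
#'
#' Collects every threshold of the screen with its published default: the
#' identity gate (candidates must exceed 24% identity to a parent), the
#' inter-domain junction (parent Lys240 or its aligned equivalent), the
#' minimum N-terminal domain length (135 residues before the junction), the
#' two core catalytic positions (Arg105 and Tyr473, required jointly for
#' alkyl chloride activation), and the extended set of active-site
#' positions surveyed across characterized relatives.
#'
#' All thresholds follow strict/inclusive semantics as stated: identity is
#' compared with strict `>`, the domain length with `>=`.
#'
#' @param identity_threshold Identity fraction a candidate must exceed
#'   (default 0.24).
#' @param junction_parent_pos 1-based parent position defining the
#'   N/C-domain junction (default 240).
#' @param min_n_domain_len Minimum number of candidate residues strictly
#'   before the junction (default 135).
#' @param key_positions Named character vector: expected residue letter per
#'   parent position; both must be present for `has_core_pair`
#'   (default `c("105" = "R", "473" = "Y")`).
#' @param extended_positions Named character vector of additional
#'   active-site positions to flag (defaults to the surveyed set).
#' @param matrix,gap_open,gap_extend Alignment parameters passed to
#'   [align_global()].
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(identity_threshold = 0.24,
                          junction_parent_pos = 240,
                          min_n_domain_len = 135,
                          key_positions = c("105" = "R", "473" = "Y"),
                          extended_positions = c(
                            "78" = "K", "96" = "D", "265" = "S", "266" = "S",
                            "267" = "T", "318" = "S", "324" = "S", "334" = "N",
                            "374" = "E", "377" = "K", "379" = "T", "438" = "L",
                            "440" = "D", "499" = "F", "502" = "D", "504" = "E",
                            "558" = "L", "559" = "D", "562" = "D", "616" = "T",
                            "618" = "T"),
                          matrix = blosum62(), gap_open = 10,
                          gap_extend = 0.5) {
  stopifnot(identity_threshold > 0, identity_threshold < 1,
            junction_parent_pos >= 1, min_n_domain_len >= 0)
  all_pos <- c(names(key_positions), names(extended_positions))
  if (anyDuplicated(all_pos)) abort("screen_config: positions must be unique")
  structure(list(
    identity_threshold = identity_threshold,
    junction_parent_pos = as.integer(junction_parent_pos),
    min_n_domain_len = as.integer(min_n_domain_len),
    key_positions = key_positions,
    extended_positions = extended_positions,
    matrix = matrix, gap_open = gap_open, gap_extend = gap_extend
  ), class = "screen_config")
}

screen_align <- function(candidate, parent, config) {
  align_global(candidate, parent, matrix = config$matrix,
               gap_open = config$gap_open, gap_extend = config$gap_extend)
}

#' Identity gate against a set of parent sequences
#'
#' Aligns a candidate to every parent and takes the best identity; the gate
#' passes on strict `> identity_threshold`, so a candidate at exactly the
#' threshold fails.
#'
#' @param candidate One sequence record or residue string.
#' @param parents Tibble of parent records (e.g. CylK and BrtB).
#' @param config A [screen_config()].
#' @return A one-row tibble: `best_parent_id`, `identity`,
#'   `passes_identity`.
#' @export
screen_identity <- function(candidate, parents, config = screen_config()) {
  stopifnot(nrow(parents) >= 1)
  ids <- vapply(seq_len(nrow(parents)), function(i) {
    percent_identity(screen_align(candidate, parents[i, ], config))
  }, numeric(1))
  best <- which.max(ids)
  tibble(best_parent_id = parents$id[best],
         identity = ids[best],
         passes_identity = ids[best] > config$identity_threshold)
}

#' Locate the N/C-domain junction on a candidate
#'
#' The junction is the candidate position aligned to the parent junction
#' residue (Lys240 by default) in the optimal global alignment. If that
#' parent position falls opposite a gap, the nearest aligned parent
#' position below it is used instead, keeping the junction inside the
#' N-terminal domain; `NA` if no parent position at or below the junction
#' aligns.
#'
#' @param candidate,parent Sequence records or residue strings; `parent`
#'   carries the residue numbering (the CylK parent).
#' @param config A [screen_config()].
#' @param aln Optionally, a precomputed parent-anchored alignment with the
#'   parent as row A.
#' @return Integer candidate position, or `NA_integer_`.
#' @export
locate_junction <- function(candidate, parent, config = screen_config(),
                            aln = NULL) {
  if (is.null(aln)) aln <- screen_align(parent, candidate, config)
  cmap <- column_map(aln)  # pos_a = parent, pos_b = candidate
  hit <- cmap$pos_b[cmap$pos_a == config$junction_parent_pos]
  if (length(hit) == 1) return(as.integer(hit))
  below <- cmap$pos_b[cmap$pos_a < config$junction_parent_pos]
  if (length(below) == 0) return(NA_integer_)
  as.integer(max(below))
}

#' Dual-domain architecture filter
#'
#' A candidate retains both domains when the junction can be located and at
#' least `min_n_domain_len` candidate residues lie strictly before it
#' (`n_domain_len = junction - 1`).
#'
#' @inheritParams locate_junction
#' @return A one-row tibble: `junction_pos`, `n_domain_len`,
#'   `passes_domain`.
#' @export
domain_filter <- function(candidate, parent, config = screen_config(),
                          aln = NULL) {
  j <- locate_junction(candidate, parent, config, aln = aln)
  n_dom <- if (is.na(j)) NA_integer_ else j - 1L
  tibble(junction_pos = j,
         n_domain_len = n_dom,
         passes_domain = !is.na(j) && n_dom >= config$min_n_domain_len)
}

#' Flag catalytic residues at aligned-equivalent positions
#'
#' For every configured parent position with its expected residue, reports
#' whether the candidate carries that residue at the aligned equivalent
#' (`"present"`), a different residue (`"absent"`), or a gap (`"gap"`, when
#' the parent position is unaligned). A gap counts as not-present for the
#' core pair. `has_core_pair` is `TRUE` when every key position (Arg105 and
#' Tyr473 by default) is present.
#'
#' @inheritParams locate_junction
#' @return A list with `flags` (tibble: `parent_pos`, `expected`,
#'   `candidate_pos`, `observed`, `state`) and `has_core_pair`.
#' @export
detect_key_residues <- function(candidate, parent, config = screen_config(),
                                aln = NULL) {
  if (is.null(aln)) aln <- screen_align(parent, candidate, config)
  cmap <- column_map(aln)
  cand_res <- strsplit(gsub("-", "", aln$row_b, fixed = TRUE), "",
                       fixed = TRUE)[[1]]
  spec <- c(config$key_positions, config$extended_positions)
  pos <- as.integer(names(spec))
  mapped <- cmap$pos_b[match(pos, cmap$pos_a)]
  observed <- ifelse(is.na(mapped), NA_character_, cand_res[mapped])
  state <- dplyr::case_when(
    is.na(mapped) ~ "gap",
    observed == unname(spec) ~ "present",
    TRUE ~ "absent"
  )
  flags <- tibble(parent_pos = pos, expected = unname(spec),
                  candidate_pos = mapped, observed = observed, state = state)
  key <- as.integer(names(config$key_positions))
  list(flags = flags,
       has_core_pair = all(state[match(key, pos)] == "present"))
}

#' Run the full homolog screen on a candidate cohort
#'
#' Deduplicates the candidates, then for each one applies the identity gate
#' (best identity over all parents), the dual-domain filter and the
#' catalytic-residue flags. Junction location and residue numbering always
#' use the first parent record, which must therefore be the CylK reference
#' the position numbering is defined on.
#'
#' @param candidates Tibble of candidate sequence records.
#' @param parents Tibble of parent records, numbering parent first.
#' @param config A [screen_config()].
#' @return A tibble of class `halide_screen`, one row per unique candidate
#'   in input order, with columns `candidate_id`, `best_parent_id`,
#'   `identity`, `passes_identity`, `junction_pos`, `n_domain_len`,
#'   `passes_domain`, `has_core_pair`, one `res_<pos>` column per
#'   configured position coded `P`/`A`/`G`, and a `residue_flags`
#'   list-column of full flag tibbles.
#' @export
run_screen <- function(candidates, parents, config = screen_config()) {
  candidates <- validate_records(candidates)
  parents <- validate_records(parents)
  n_input <- nrow(candidates)
  candidates <- dedupe_sequences(candidates)
  numbering_parent <- parents[1, ]

  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    gate <- screen_identity(cand, parents, config)
    aln <- screen_align(numbering_parent, cand, config)
    dom <- domain_filter(cand, numbering_parent, config, aln = aln)
    res <- detect_key_residues(cand, numbering_parent, config, aln = aln)
    wide <- setNames(substr(toupper(res$flags$state), 1, 1),
                     paste0("res_", res$flags$parent_pos))
    dplyr::bind_cols(
      tibble(candidate_id = cand$id),
      gate, dom,
      tibble(has_core_pair = res$has_core_pair),
      as_tibble(as.list(wide)),
      tibble(residue_flags = list(res$flags))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(candidate_id = character(), best_parent_id = character(),
                  identity = numeric(), passes_identity = logical(),
                  junction_pos = integer(), n_domain_len = integer(),
                  passes_domain = logical(), has_core_pair = logical(),
                  residue_flags = list())
  }
  structure(out,
            class = c("halide_screen", class(out)),
            config = config,
            n_input = n_input,
            n_removed = attr(candidates, "n_removed"))
}
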