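# broom-style tidiers for screen and pipeline results.

#' Tidy a homolog-screen result
#'
#' Returns the per-candidate verdict table without list-columns, ready for
#' joining or export.
#'
#' @param x A `halide_screen` from [run_screen()].
#' @param ... Unused.
#' @return A tibble, one row per unique candidate.
#' @export
tidy.halide_screen <- function(x, ...) {
  as_tibble(flatten_calls(x))
}

#' One-row summary of a homolog-screen result
#'
#' @param x A `halide_screen` from [run_screen()].
#' @param ... Unused.
#' @return A one-row tibble with the cohort counts and the thresholds
#'   that produced them.
#' @export
glance.halide_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_candidates = attr(x, "n_input"),
    n_after_dedupe = nrow(x),
    n_pass_identity = sum(x$passes_identity),
    n_pass_domain = sum(x$passes_identity & x$passes_domain),
    n_core_pair = sum(x$passes_identity & x$passes_domain & x$has_core_pair),
    identity_threshold = cfg$identity_threshold,
    min_n_domain_len = cfg$min_n_domain_len
  )
}

#' Tidy a pairwise alignment
#'
#' @param x A `pairwise_alignment` from [align_global()].
#' @param ... Unused.
#' @return A one-row tibble with score, identity and similarity under both
#'   denominator conventions, and gap counts.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(
    id_a = x$id_a, id_b = x$id_b, score = x$score,
    n_columns = nchar(x$row_a),
    identity = percent_identity(x),
    similarity = percent_similarity(x),
    identity_aligned_cols = percent_identity(x, denominator = "aligned"),
    similarity_aligned_cols = percent_similarity(x, denominator = "aligned"),
    n_gaps_a = nchar(gsub("[^-]", "", x$row_a)),
    n_gaps_b = nchar(gsub("[^-]", "", x$row_b))
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `halide_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return The pipeline's cohort-summary tibble.
#' @export
glance.halide_pipeline <- function(x, ...) {
  x$summary
}
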