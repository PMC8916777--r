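# End-to-end orchestration: screen -> neighborhood -> tree -> report.

#' Pipeline configuration
#'
#' Collects file paths and per-stage configurations. Every screening
#' threshold lives in [screen_config()] / [neighborhood_config()] with its
#' published default; nothing is hard-coded in stage logic.
#'
#' @param candidates_fasta,parents_fasta Paths to candidate and parent
#'   FASTA files (numbering parent first in the parents file).
#' @param out_dir Output directory (created if needed).
#' @param genes_tsv Optional path to a gene-annotation TSV; `NULL` skips
#'   the genomic-context stage gracefully.
#' @param screen A [screen_config()].
#' @param neighborhood A [neighborhood_config()].
#' @param mask_threshold Gap-column masking threshold (default 0.90).
#' @param bootstrap_n Bootstrap replicates for the tree (default 100).
#' @param seed Integer seed controlling all pipeline randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(candidates_fasta, parents_fasta, out_dir,
                            genes_tsv = NULL,
                            screen = screen_config(),
                            neighborhood = neighborhood_config(),
                            mask_threshold = 0.90, bootstrap_n = 100,
                            seed = 1) {
  structure(list(candidates_fasta = candidates_fasta,
                 parents_fasta = parents_fasta, genes_tsv = genes_tsv,
                 out_dir = out_dir, screen = screen,
                 neighborhood = neighborhood,
                 mask_threshold = mask_threshold,
                 bootstrap_n = bootstrap_n, seed = seed),
            class = "pipeline_config")
}

# calls tibble without list-columns, for TSV export
flatten_calls <- function(calls) {
  calls[, !vapply(calls, is.list, logical(1)), drop = FALSE]
}

#' Run the full genome-mining pipeline
#'
#' Reads candidates and parents, runs the homolog screen, joins genomic
#' context when a gene table is supplied, builds a masked center-star
#' alignment of the candidates passing both gates, reconstructs a
#' neighbor-joining tree with bootstrap supports, and writes all stage
#' artifacts (`calls.tsv`, `context.tsv`, `msa.fasta`, `tree.nwk`,
#' `tips.tsv`, `summary.tsv`, `run.log`) to the output directory. The run
#' log records every threshold and one machine-parsable line per excluded
#' candidate. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `halide_pipeline`: a list with `summary`
#'   (one-row tibble of cohort counts), `calls`, `context`, `msa`,
#'   `tree`, `tips`, `config` and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  scr <- config$screen
  say("stage=config identity_threshold=%g junction=%d min_n_domain=%d mask=%g halogenase_window=%d mar_window=%d bootstrap_n=%d seed=%d",
      scr$identity_threshold, scr$junction_parent_pos, scr$min_n_domain_len,
      config$mask_threshold, config$neighborhood$halogenase_window,
      config$neighborhood$mar_window, config$bootstrap_n, config$seed)

  candidates <- with_stage("read_candidates", read_fasta(config$candidates_fasta))
  parents <- with_stage("read_parents", read_fasta(config$parents_fasta))
  say("stage=input n_candidates=%d n_parents=%d", nrow(candidates),
      nrow(parents))

  calls <- with_stage("screen", run_screen(candidates, parents, scr))
  n_dupes <- attr(calls, "n_removed") %||% 0L
  say("stage=dedupe n_removed=%d", n_dupes)
  for (i in seq_len(nrow(calls))) {
    if (!calls$passes_identity[i]) {
      say("exclude id=%s reason=FAIL_IDENTITY identity=%.4f",
          calls$candidate_id[i], calls$identity[i])
    } else if (!calls$passes_domain[i]) {
      say("exclude id=%s reason=FAIL_DOMAIN n_domain_len=%s",
          calls$candidate_id[i], calls$n_domain_len[i])
    }
  }
  readr::write_tsv(flatten_calls(calls),
                   file.path(config$out_dir, "calls.tsv"))

  context <- NULL
  if (!is.null(config$genes_tsv)) {
    genes <- with_stage("read_genes", read_gene_table(config$genes_tsv))
    context <- with_stage("neighborhood",
                          summarize_cohort(calls, genes,
                                           config$neighborhood))
    ctx_calls <- bind_rows(
      mutate(context$halogenase_calls[[1]], partner_family = "cylC_like"),
      mutate(context$mar_calls[[1]], partner_family = "cylI_like"))
    readr::write_tsv(ctx_calls, file.path(config$out_dir, "context.tsv"))
    for (id in attr(context, "no_context_ids")) {
      say("exclude id=%s reason=NO_GENOMIC_CONTEXT", id)
    }
  } else {
    say("stage=neighborhood skipped=no_gene_table")
    genes <- NULL
  }

  passing <- calls[calls$passes_identity & calls$passes_domain, ,
                   drop = FALSE]
  numbering_parent <- parents[1, ]
  msa <- NULL; masked <- NULL; tree <- NULL; tips <- NULL
  if (nrow(passing) >= 3) {
    keep <- candidates[candidates$id %in% passing$candidate_id, ,
                       drop = FALSE]
    keep <- dedupe_sequences(keep)
    msa_in <- bind_rows(numbering_parent, keep)
    msa <- with_stage("msa", center_star_msa(
      msa_in, numbering_parent$id, matrix = scr$matrix,
      gap_open = scr$gap_open, gap_extend = scr$gap_extend))
    masked <- with_stage("mask",
                         mask_gap_columns(msa, config$mask_threshold))
    say("stage=mask n_columns=%d n_removed=%d", masked$n_col,
        attr(masked, "n_removed"))
    write_msa_fasta(masked, file.path(config$out_dir, "msa.fasta"))
    tree <- with_stage("tree", bootstrap_support(
      masked, n_replicates = config$bootstrap_n, seed = config$seed))
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))

    tips <- tibble(tip = tree$tip.label) |>
      left_join(select(calls, tip = "candidate_id", "has_core_pair"),
                by = "tip")
    if (!is.null(genes)) {
      ctx_of <- function(id, fam, win) {
        if (!id %in% genes$gene_id) return(NA)
        colocalize(id, genes, fam, win)$clustered
      }
      tips$clustered_halogenase <- vapply(
        tips$tip, ctx_of, logical(1), fam = "cylC_like",
        win = config$neighborhood$halogenase_window)
      tips$clustered_mar <- vapply(
        tips$tip, ctx_of, logical(1), fam = "cylI_like",
        win = config$neighborhood$mar_window)
    } else {
      tips$clustered_halogenase <- NA
      tips$clustered_mar <- NA
    }
    readr::write_tsv(tips, file.path(config$out_dir, "tips.tsv"))
  } else {
    say("stage=tree skipped=fewer_than_3_passing_candidates")
  }

  summary <- tibble(
    n_candidates = attr(calls, "n_input"),
    n_after_dedupe = nrow(calls),
    n_pass_identity = sum(calls$passes_identity),
    n_pass_domain = sum(calls$passes_identity & calls$passes_domain),
    n_core_pair = sum(calls$passes_identity & calls$passes_domain &
                        calls$has_core_pair),
    n_core_pair_organisms = if (!is.null(context))
      context$n_core_pair_organisms else NA_integer_,
    n_with_genome_halogenase = if (!is.null(context))
      context$n_with_genome_halogenase else NA_integer_,
    n_halogenase_genes = if (!is.null(context))
      context$n_halogenase_genes else NA_integer_,
    n_clustered_halogenase = if (!is.null(context))
      context$n_clustered_halogenase else NA_integer_,
    n_mar_genes = if (!is.null(context)) context$n_mar_genes else NA_integer_,
    n_clustered_mar = if (!is.null(context))
      context$n_clustered_mar else NA_integer_
  ) |>
    mutate(
      frac_pass_identity = .data$n_pass_identity / .data$n_after_dedupe,
      frac_core_pair_with_halogenase =
        .data$n_with_genome_halogenase / .data$n_core_pair_organisms,
      frac_clustered_halogenase =
        .data$n_clustered_halogenase / .data$n_halogenase_genes,
      frac_clustered_mar = .data$n_clustered_mar / .data$n_mar_genes
    )
  readr::write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  say("stage=summary n_candidates=%d n_pass_identity=%d n_pass_domain=%d n_core_pair=%d",
      summary$n_candidates, summary$n_pass_identity, summary$n_pass_domain,
      summary$n_core_pair)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  structure(list(summary = summary, calls = calls, context = context,
                 msa = masked, tree = tree, tips = tips, config = config,
                 log = log_lines),
            class = "halide_pipeline")
}

# run an expression as a named stage, prefixing errors with the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "': ", conditionMessage(e)))
  })
}

#' Write a synthetic cohort to pipeline input files
#'
#' Convenience for exercising [run_pipeline()] on a
#' [make_screen_cohort()] result: writes `candidates.fasta`,
#' `parents.fasta` and `genes.tsv` into a directory.
#'
#' @param cohort A [make_screen_cohort()] result.
#' @param dir Output directory.
#' @return Named list of the three file paths.
#' @export
write_cohort_inputs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    candidates_fasta = file.path(dir, "candidates.fasta"),
    parents_fasta = file.path(dir, "parents.fasta"),
    genes_tsv = file.path(dir, "genes.tsv"))
  write_fasta(cohort$candidates, paths$candidates_fasta)
  write_fasta(cohort$parents, paths$parents_fasta)
  readr::write_tsv(cohort$genes, paths$genes_tsv)
  paths
}

#' @export
print.halide_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Genome-mining pipeline run\n")
  cat(sprintf("  candidates: %d (%d unique)\n", s$n_candidates,
              s$n_after_dedupe))
  cat(sprintf("  pass identity gate: %d  pass both domains: %d  core pair: %d\n",
              s$n_pass_identity, s$n_pass_domain, s$n_core_pair))
  if (!is.na(s$n_core_pair_organisms)) {
    cat(sprintf("  core-pair organisms with partner halogenase: %d of %d\n",
                s$n_with_genome_halogenase, s$n_core_pair_organisms))
    cat(sprintf("  clustered halogenases: %d of %d; clustered MAR synthases: %d of %d\n",
                s$n_clustered_halogenase, s$n_halogenase_genes,
                s$n_clustered_mar, s$n_mar_genes))
  }
  invisible(x)
}
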