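# Gene-neighborhood co-localization of candidate alkyl-halide-activating
# genes with partner halogenases and monoalkylresorcinol synthases.
#
# Distance is ordinal ("genes away"): the absolute difference of gene
# indices on the same contig; genes on different contigs have no distance.
# Both windows are strict upper bounds.

gene_families <- function() {
  c("cylK_like", "cylC_like", "fe2og_halogenase", "other_halogenase",
    "cylI_like", "dar_like", "other")
}

#' Configuration for neighborhood co-localization
#'
#' @param halogenase_window Strict upper bound on the gene distance for a
#'   halogenase partner to count as clustered (default 18: "fewer than 18
#'   genes away").
#' @param mar_window Strict upper bound for monoalkylresorcinol-synthase
#'   partners (default 12).
#' @return An object of class `neighborhood_config`.
#' @export
neighborhood_config <- function(halogenase_window = 18, mar_window = 12) {
  stopifnot(halogenase_window >= 1, mar_window >= 1)
  structure(list(halogenase_window = as.integer(halogenase_window),
                 mar_window = as.integer(mar_window)),
            class = "neighborhood_config")
}

#' Validate a gene-annotation table
#'
#' @param genes A data frame with columns `genome_id`, `contig_id`,
#'   `gene_index` (1-based ordinal position on its contig), `gene_id`,
#'   `family_label` (one of the recognized families).
#' @return The validated tibble.
#' @export
validate_gene_table <- function(genes) {
  need <- c("genome_id", "contig_id", "gene_index", "gene_id", "family_label")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  genes <- as_tibble(genes)
  genes$gene_index <- as.integer(genes$gene_index)
  if (any(genes$gene_index < 1, na.rm = TRUE)) {
    abort("gene_index must be >= 1")
  }
  bad_fam <- setdiff(unique(genes$family_label), gene_families())
  if (length(bad_fam) > 0) {
    abort(paste0("unrecognized family_label(s): ",
                 paste(bad_fam, collapse = ", ")))
  }
  key <- paste(genes$genome_id, genes$contig_id, genes$gene_index, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (genome_id, contig_id, gene_index) in gene table")
  }
  genes[, need]
}

#' Read a gene-annotation TSV
#'
#' Tab-separated with a header row and the columns of
#' [validate_gene_table()].
#'
#' @param path Path to the TSV file.
#' @return A validated gene-table tibble.
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_table(genes)
}

#' Derive a gene table from GFF3 gene features
#'
#' Convenience adapter: reads a GFF3 file, keeps features of the given
#' type, and assigns `gene_index` by sorting features within each
#' sequence region by start coordinate. The family label is taken from the
#' GFF attribute named by `family_attr` when present, otherwise `"other"`.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier to assign to all records.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param family_attr Attribute key carrying the family label (default
#'   `"family"`).
#' @return A validated gene-table tibble.
#' @export
read_gff_genes <- function(path, genome_id, feature_type = "gene",
                           family_attr = "family") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) == 9
  if (!all(ok)) {
    abort(sprintf("GFF3 parse error at line %d: expected 9 tab-separated fields",
                  which(!ok)[1]))
  }
  f <- do.call(rbind, fields)
  keep <- f[, 3] == feature_type
  f <- f[keep, , drop = FALSE]
  attr_field <- f[, 9]
  get_attr <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  tbl <- tibble(
    genome_id = genome_id,
    contig_id = f[, 1],
    start = as.integer(f[, 4]),
    gene_id = get_attr(attr_field, "ID"),
    family_label = get_attr(attr_field, family_attr)
  )
  tbl$family_label[is.na(tbl$family_label)] <- "other"
  tbl$gene_id[is.na(tbl$gene_id)] <- paste0("gene", seq_len(nrow(tbl)))[is.na(tbl$gene_id)]
  tbl <- tbl |>
    group_by(.data$contig_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(gene_index = dplyr::row_number()) |>
    ungroup() |>
    select("genome_id", "contig_id", "gene_index", "gene_id", "family_label")
  validate_gene_table(tbl)
}

#' Ordinal gene distance between two gene records
#'
#' @param a,b One-row gene records.
#' @return `|gene_index(a) - gene_index(b)|` when the genes share a genome
#'   and contig; `NA_integer_` otherwise.
#' @export
gene_distance <- function(a, b) {
  if (a$genome_id[1] != b$genome_id[1] || a$contig_id[1] != b$contig_id[1]) {
    return(NA_integer_)
  }
  abs(a$gene_index[1] - b$gene_index[1])
}

#' Co-localization of one candidate gene with a partner family
#'
#' Finds the nearest gene of `family` on the same contig as the candidate
#' gene; the pair is clustered when its ordinal distance is strictly below
#' `window`. Whether the genome encodes the family anywhere at all is
#' reported separately.
#'
#' @param cylk_gene_id Gene id of the candidate (must be in `genes`).
#' @param genes A validated gene table.
#' @param family Partner family label (e.g. `"cylC_like"`).
#' @param window Strict upper bound on the clustered distance.
#' @return A one-row tibble: `cylk_gene_id`, `partner_family`,
#'   `partner_gene_id`, `gene_distance`, `clustered`,
#'   `genome_has_partner`.
#' @export
colocalize <- function(cylk_gene_id, genes, family, window) {
  genes <- validate_gene_table(genes)
  self <- genes[genes$gene_id == cylk_gene_id, , drop = FALSE]
  if (nrow(self) == 0) {
    abort(paste0("gene id not found in gene table: ", cylk_gene_id))
  }
  self <- self[1, ]
  fam <- genes[genes$family_label == family & genes$gene_id != cylk_gene_id, ,
               drop = FALSE]
  in_genome <- fam[fam$genome_id == self$genome_id, , drop = FALSE]
  on_contig <- in_genome[in_genome$contig_id == self$contig_id, , drop = FALSE]
  if (nrow(on_contig) > 0) {
    d <- abs(on_contig$gene_index - self$gene_index)
    best <- which.min(d)
    partner_id <- on_contig$gene_id[best]
    dist <- as.integer(d[best])
  } else {
    partner_id <- NA_character_
    dist <- NA_integer_
  }
  tibble(cylk_gene_id = cylk_gene_id, partner_family = family,
         partner_gene_id = partner_id, gene_distance = dist,
         clustered = !is.na(dist) && dist < window,
         genome_has_partner = nrow(in_genome) > 0)
}

#' Cohort-level co-localization and co-occurrence summary
#'
#' Joins homolog-screen verdicts to genomic context. Candidate sequence ids
#' are matched to `gene_id`s in the gene table; candidates without a gene
#' record are counted as having no genomic context and excluded from the
#' clustering and co-occurrence denominators but retained in
#' sequence-level counts.
#'
#' Reported quantities: organisms contributing a core-pair candidate
#' (carrying both key catalytic residues); of those, organisms whose
#' genome also encodes a halogenase partner; halogenase partner genes
#' within the halogenase window of a candidate gene (out of all such genes
#' in candidate-bearing genomes); and likewise monoalkylresorcinol-synthase
#' genes within the MAR window.
#'
#' @param calls A `halide_screen` tibble from [run_screen()].
#' @param genes A validated gene table covering the candidates' genomes.
#' @param config A [neighborhood_config()].
#' @param halogenase_family,mar_family Partner family labels.
#' @return A one-row tibble of class `cohort_context`: counts and
#'   fractions, plus list-columns `halogenase_calls` and `mar_calls` with
#'   the underlying per-gene co-localization calls.
#' @export
summarize_cohort <- function(calls, genes, config = neighborhood_config(),
                             halogenase_family = "cylC_like",
                             mar_family = "cylI_like") {
  genes <- validate_gene_table(genes)
  core <- calls[calls$has_core_pair %in% TRUE, , drop = FALSE]
  idx <- match(core$candidate_id, genes$gene_id)
  no_context <- core$candidate_id[is.na(idx)]
  core_genes <- genes[idx[!is.na(idx)], , drop = FALSE]
  core_organisms <- unique(core_genes$genome_id)

  # organism-level co-occurrence: does the genome encode the halogenase family?
  halo_genomes <- unique(genes$genome_id[genes$family_label == halogenase_family])
  n_cooccur <- sum(core_organisms %in% halo_genomes)

  # gene-level clustering: partner genes in candidate-bearing genomes,
  # scored against the nearest candidate gene on their contig
  cand_genes <- genes[genes$family_label == "cylK_like" &
                        genes$gene_id %in% calls$candidate_id, , drop = FALSE]
  partner_calls <- function(family, window) {
    fam <- genes[genes$family_label == family &
                   genes$genome_id %in% unique(cand_genes$genome_id), ,
                 drop = FALSE]
    purrr::map_dfr(seq_len(nrow(fam)), function(i) {
      g <- fam[i, ]
      near <- cand_genes[cand_genes$genome_id == g$genome_id &
                           cand_genes$contig_id == g$contig_id, , drop = FALSE]
      d <- if (nrow(near) > 0) min(abs(near$gene_index - g$gene_index))
           else NA_integer_
      tibble(partner_gene_id = g$gene_id, genome_id = g$genome_id,
             gene_distance = as.integer(d),
             clustered = !is.na(d) && d < window)
    })
  }
  halo <- partner_calls(halogenase_family, config$halogenase_window)
  mar <- partner_calls(mar_family, config$mar_window)

  # per-candidate MAR clustering among core-pair candidates (second
  # counting basis: candidates with a clustered MAR synthase)
  core_ids <- core_genes$gene_id
  n_core_with_mar <- sum(vapply(core_ids, function(gid) {
    colocalize(gid, genes, mar_family, config$mar_window)$clustered
  }, logical(1)))

  out <- tibble(
    n_core_pair_candidates = nrow(core),
    n_core_pair_no_context = length(no_context),
    n_core_pair_organisms = length(core_organisms),
    n_with_genome_halogenase = n_cooccur,
    frac_with_genome_halogenase =
      if (length(core_organisms) > 0) n_cooccur / length(core_organisms)
      else NA_real_,
    n_halogenase_genes = nrow(halo),
    n_clustered_halogenase = sum(halo$clustered),
    n_mar_genes = nrow(mar),
    n_clustered_mar = sum(mar$clustered),
    n_core_candidates_with_clustered_mar = n_core_with_mar,
    halogenase_calls = list(halo),
    mar_calls = list(mar)
  )
  structure(out, class = c("cohort_context", class(out)), config = config,
            no_context_ids = no_context)
}
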