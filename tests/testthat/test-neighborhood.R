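toy_genes <- function() {
  tibble::tibble(
    genome_id = c("g1", "g1", "g1", "g1", "g1", "g2"),
    contig_id = c("c1", "c1", "c1", "c2", "c1", "c1"),
    gene_index = c(5L, 6L, 28L, 3L, 10L, 1L),
    gene_id = c("k1", "h1", "h2", "h3", "m1", "k2"),
    family_label = c("cylK_like", "cylC_like", "cylC_like", "cylC_like",
                     "cylI_like", "cylK_like")
  )
}

test_that("gene distance is ordinal and contig-bound", {
  g <- toy_genes()
  expect_equal(gene_distance(g[1, ], g[2, ]), 1L)
  expect_equal(gene_distance(g[1, ], g[3, ]), 23L)
  expect_true(is.na(gene_distance(g[1, ], g[4, ])))   # different contig
  expect_true(is.na(gene_distance(g[1, ], g[6, ])))   # different genome
})

test_that("clustering windows are strict upper bounds", {
  g <- toy_genes()
  # adjacent partner clusters
  call <- colocalize("k1", g, "cylC_like", window = 18)
  expect_equal(call$partner_gene_id, "h1")
  expect_equal(call$gene_distance, 1L)
  expect_true(call$clustered)

  # distance exactly 18 is NOT clustered ("fewer than 18")
  g18 <- g[g$gene_id != "h1", ]
  g18$gene_index[g18$gene_id == "h2"] <- 23L  # |5 - 23| = 18
  call18 <- colocalize("k1", g18, "cylC_like", window = 18)
  expect_equal(call18$gene_distance, 18L)
  expect_false(call18$clustered)
  expect_true(call18$genome_has_partner)

  # distance exactly 12 is NOT clustered for the MAR window
  gm <- g
  gm$gene_index[gm$gene_id == "m1"] <- 17L
  callm <- colocalize("k1", gm, "cylI_like", window = 12)
  expect_equal(callm$gene_distance, 12L)
  expect_false(callm$clustered)

  # partner on another contig: not clustered, but genome has the family
  only_off <- g[g$gene_id %in% c("k1", "h3"), ]
  call_off <- colocalize("k1", only_off, "cylC_like", window = 18)
  expect_true(is.na(call_off$gene_distance))
  expect_false(call_off$clustered)
  expect_true(call_off$genome_has_partner)

  expect_error(colocalize("nope", g, "cylC_like", 18), "not found")
})

test_that("planted partner distances classify exactly by the windows", {
  taxa <- sprintf("tx%02d", 1:5)
  spec <- tibble::tibble(taxon = taxa, family = "cylC_like",
                         distance = c(2L, 10L, 17L, 18L, 25L))
  nb <- emit_neighborhoods(taxa, spec, seed = 3)
  clustered <- vapply(taxa, function(tx) {
    colocalize(tx, nb$genes, "cylC_like", 18)$clustered
  }, logical(1))
  expect_equal(unname(clustered), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # recomputed distances equal the planted ones
  d <- vapply(taxa, function(tx) {
    colocalize(tx, nb$genes, "cylC_like", 18)$gene_distance
  }, integer(1))
  expect_equal(unname(d), spec$distance)
})

test_that("clustered partner counts are monotone in window size", {
  taxa <- sprintf("w%02d", 1:30)
  spec <- tibble::tibble(taxon = taxa, family = "cylC_like",
                         distance = as.integer(1:30))
  nb <- emit_neighborhoods(taxa, spec, seed = 4)
  n_clustered <- function(win) {
    sum(vapply(taxa, function(tx) {
      colocalize(tx, nb$genes, "cylC_like", win)$clustered
    }, logical(1)))
  }
  counts <- vapply(c(1, 5, 12, 18, 31), n_clustered, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts, c(0, 4, 11, 17, 30))
})

test_that("cohort summary counts organisms and clustered partners from truth", {
  # 10 core-pair organisms; 8 get a halogenase (5 clustered), plus MAR
  taxa <- sprintf("o%02d", 1:10)
  spec <- dplyr::bind_rows(
    tibble::tibble(taxon = taxa[1:5], family = "cylC_like",
                   distance = c(1L, 5L, 10L, 17L, 2L)),       # clustered
    tibble::tibble(taxon = taxa[6:8], family = "cylC_like",
                   distance = c(20L, 25L, 30L)),              # present, far
    tibble::tibble(taxon = taxa[1:4], family = "cylI_like",
                   distance = c(3L, 11L, 12L, 20L))           # 2 clustered
  )
  nb <- emit_neighborhoods(taxa, spec, seed = 5)
  calls <- tibble::tibble(candidate_id = taxa, passes_identity = TRUE,
                          passes_domain = TRUE, has_core_pair = TRUE)
  ctx <- summarize_cohort(calls, nb$genes, neighborhood_config())
  expect_equal(ctx$n_core_pair_organisms, 10)
  expect_equal(ctx$n_with_genome_halogenase, 8)
  expect_equal(ctx$n_halogenase_genes, 8)
  expect_equal(ctx$n_clustered_halogenase, 5)
  expect_equal(ctx$n_mar_genes, 4)
  expect_equal(ctx$n_clustered_mar, 2)
  expect_equal(ctx$n_core_candidates_with_clustered_mar, 2)
  # clustered implies the genome encodes the partner
  halo <- ctx$halogenase_calls[[1]]
  expect_true(all(!halo$clustered | halo$genome_id %in% nb$genes$genome_id))

  # permutation invariance of the totals
  shuffled <- nb$genes[withr::with_seed(8, sample.int(nrow(nb$genes))), ]
  ctx2 <- summarize_cohort(calls, shuffled, neighborhood_config())
  expect_equal(ctx2$n_clustered_halogenase, ctx$n_clustered_halogenase)
  expect_equal(ctx2$n_clustered_mar, ctx$n_clustered_mar)

  # candidates without genomic context are excluded from clustering counts
  calls2 <- dplyr::bind_rows(calls, tibble::tibble(
    candidate_id = "orphan", passes_identity = TRUE, passes_domain = TRUE,
    has_core_pair = TRUE))
  ctx3 <- summarize_cohort(calls2, nb$genes, neighborhood_config())
  expect_equal(ctx3$n_core_pair_no_context, 1)
  expect_equal(ctx3$n_core_pair_organisms, 10)
  expect_equal(ctx3$n_core_pair_candidates, 11)
})

test_that("gene tables validate and round trip through TSV", {
  g <- toy_genes()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(g, path)
  back <- read_gene_table(path)
  expect_equal(as.data.frame(back), as.data.frame(g))
  bad <- g
  bad$family_label[1] <- "mystery"
  expect_error(validate_gene_table(bad), "mystery")
  dup <- dplyr::bind_rows(g, g[1, ])
  expect_error(validate_gene_table(dup), "duplicate")
})

test_that("GFF3 adapter assigns ordinal indices by start coordinate", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctgA\tsrc\tgene\t500\t900\t.\t+\t.\tID=gB;family=cylC_like",
    "ctgA\tsrc\tgene\t100\t400\t.\t+\t.\tID=gA;family=cylK_like",
    "ctgA\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=mA",
    "ctgB\tsrc\tgene\t50\t80\t.\t-\t.\tID=gC"
  ), path)
  g <- read_gff_genes(path, genome_id = "gen1")
  expect_equal(nrow(g), 3)
  expect_equal(g$gene_index[g$gene_id == "gA"], 1L)
  expect_equal(g$gene_index[g$gene_id == "gB"], 2L)
  expect_equal(g$family_label[g$gene_id == "gC"], "other")
})
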