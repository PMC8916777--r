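# Synthetic protein families, planted catalytic features and genome
# neighborhoods with exact ground truth.
#
# The generator is deliberately simple: uniform replacement substitutions
# (a site substitutes along a branch of length b with probability
# 1 - exp(-b), the replacement drawn uniformly from the other 19 standard
# letters) and single-site indels, so the site-level homology map between
# every taxon and the root is exact and serves as the oracle for alignment
# and screening tests.

std_letters <- function() setdiff(aa_alphabet(), "X")

#' Simulate a random tree by sequential random attachment
#'
#' Starts from two tips joined at the root and attaches each further tip
#' to a uniformly chosen existing edge. Branch lengths are drawn
#' independently from an exponential distribution with the given mean.
#'
#' @param n_taxa Number of tips (>= 2); labels `t1..tn`.
#' @param mean_branch_length Mean of the exponential branch-length
#'   distribution (expected substitutions per site; default 0.1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_taxa, mean_branch_length = 0.1, seed = NULL) {
  stopifnot(n_taxa >= 2, mean_branch_length > 0)
  run <- function() {
    # adjacency as parent/child pairs over symbolic ids
    parent <- c("R", "R")
    child <- c("t1", "t2")
    next_internal <- 1L
    for (k in seq_len(n_taxa - 2) + 2L) {
      e <- sample.int(length(parent), 1)
      w <- paste0("n", next_internal); next_internal <- next_internal + 1L
      old_child <- child[e]
      child[e] <- w
      parent <- c(parent, w, w)
      child <- c(child, old_child, paste0("t", k))
    }
    len <- stats::rexp(length(parent), rate = 1 / mean_branch_length)
    # recursive Newick construction
    kids <- split(seq_along(parent), parent)
    as_nwk <- function(node) {
      if (!node %in% names(kids)) return(node)
      parts <- vapply(kids[[node]], function(e) {
        sprintf("%s:%.15g", as_nwk(child[e]), len[e])
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    ape::read.tree(text = paste0(as_nwk("R"), ";"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Evolve one sequence along one branch. state = list(res, hom) where hom
# holds the root-site id of each current position (NA for insertions).
evolve_branch <- function(state, b, indel_rate) {
  res <- state$res; hom <- state$hom
  if (b > 0 && length(res) > 0) {
    p_sub <- 1 - exp(-b)
    hit <- which(stats::runif(length(res)) < p_sub)
    for (i in hit) {
      res[i] <- sample(setdiff(std_letters(), res[i]), 1)
    }
    n_events <- stats::rpois(1, indel_rate * b * length(res))
    for (e in seq_len(n_events)) {
      if (length(res) <= 1) break
      if (stats::runif(1) < 0.5) {  # deletion of one site
        i <- sample.int(length(res), 1)
        res <- res[-i]; hom <- hom[-i]
      } else {                      # insertion of one novel site
        i <- sample.int(length(res) + 1, 1)
        res <- append(res, sample(std_letters(), 1), after = i - 1)
        hom <- append(hom, NA_integer_, after = i - 1)
      }
    }
  }
  list(res = res, hom = hom)
}

#' Evolve a protein family down a tree with an exact homology map
#'
#' @param root_seq Root residue string (the synthetic parent).
#' @param tree A `phylo` tree whose tips name the taxa.
#' @param indel_rate Single-site indel events per site per unit branch
#'   length (default 0).
#' @param seed Optional integer seed.
#' @return A list with `records` (tibble of tip sequences,
#'   `organism_id = "g_<tip>"`) and `manifest`, a list holding the tree,
#'   the root sequence and `maps`: per tip, an integer vector giving the
#'   tip position of every root site (`NA` where deleted).
#' @export
evolve_family <- function(root_seq, tree, indel_rate = 0, seed = NULL) {
  root_seq <- toupper(root_seq)
  run <- function() {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    states <- vector("list", n_tip + tree$Nnode)
    states[[root]] <- list(res = strsplit(root_seq, "", fixed = TRUE)[[1]],
                           hom = seq_len(nchar(root_seq)))
    # preorder over edges (ape cladewise order is parent-before-child)
    edges <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(edges$edge))) {
      p <- edges$edge[e, 1]; ch <- edges$edge[e, 2]
      states[[ch]] <- evolve_branch(states[[p]], edges$edge.length[e],
                                    indel_rate)
    }
    maps <- lapply(seq_len(n_tip), function(i) {
      hom <- states[[i]]$hom
      m <- rep(NA_integer_, nchar(root_seq))
      m[hom[!is.na(hom)]] <- which(!is.na(hom))
      m
    })
    names(maps) <- tree$tip.label
    records <- aa_records(
      id = tree$tip.label,
      residues = vapply(seq_len(n_tip),
                        function(i) paste(states[[i]]$res, collapse = ""),
                        character(1)),
      organism_id = paste0("g_", tree$tip.label)
    )
    list(records = records,
         manifest = list(tree = tree, root_seq = root_seq, maps = maps))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plant catalytic-residue states and domain truncations
#'
#' Applies controlled edits to an evolved family so that downstream
#' verdicts have known truth: designated taxa receive the expected residue
#' at the homology-mapped image of each parent position ("present"),
#' remaining taxa optionally receive a contrasting residue ("absent"), and
#' a designated subset loses its entire N-terminal domain. Positions lost
#' to deletions are recorded as "gap", not an error.
#'
#' @param records,manifest Output of [evolve_family()].
#' @param plant_spec Tibble with columns `position` (root coordinate),
#'   `residue` (letter planted in members), `taxa` (list-column of member
#'   tip ids) and optionally `off_residue` (letter planted in
#'   non-members; `NA` leaves them untouched).
#' @param truncate_taxa Character vector of tip ids whose N-terminal
#'   domain (root sites `1..n_domain_len`) is deleted.
#' @param n_domain_len Length of the N-terminal block in root coordinates
#'   (default 240).
#' @return A list with updated `records`, `manifest` (maps adjusted for
#'   truncations), and `truth`: a tibble per taxon x planted position with
#'   the planted `state` (`present`/`absent`/`gap`) plus `has_n_domain`.
#' @export
plant_features <- function(records, manifest, plant_spec,
                           truncate_taxa = character(0),
                           n_domain_len = 240) {
  res_list <- setNames(strsplit(records$residues, "", fixed = TRUE),
                       records$id)
  maps <- manifest$maps

  # truncate first, so N-domain plants in truncated taxa report "gap"
  for (tx in truncate_taxa) {
    map <- maps[[tx]]
    c_sites <- which(!is.na(map) & seq_along(map) > n_domain_len)
    k <- if (length(c_sites) == 0) 0L else map[c_sites[1]] - 1L
    if (k > 0) {
      res_list[[tx]] <- res_list[[tx]][-seq_len(k)]
      map <- map - k
      map[map < 1] <- NA_integer_
    }
    map[seq_len(min(n_domain_len, length(map)))] <- NA_integer_
    maps[[tx]] <- map
  }

  truth <- list()
  for (r in seq_len(nrow(plant_spec))) {
    pos <- plant_spec$position[r]
    letter <- plant_spec$residue[r]
    members <- plant_spec$taxa[[r]]
    off <- if ("off_residue" %in% names(plant_spec))
      plant_spec$off_residue[r] else NA_character_
    for (tx in records$id) {
      at <- maps[[tx]][pos]
      is_member <- tx %in% members
      if (is.na(at)) {
        state <- "gap"
      } else if (is_member) {
        res_list[[tx]][at] <- letter
        state <- "present"
      } else if (!is.na(off)) {
        res_list[[tx]][at] <- off
        state <- "absent"
      } else {
        state <- if (res_list[[tx]][at] == letter) "present" else "absent"
      }
      truth[[length(truth) + 1L]] <-
        tibble(taxon = tx, position = pos, expected = letter, state = state)
    }
  }
  records$residues <- vapply(res_list[records$id], paste, character(1),
                             collapse = "", USE.NAMES = FALSE)
  manifest$maps <- maps
  truth_tbl <- bind_rows(truth) |>
    mutate(has_n_domain = !(.data$taxon %in% truncate_taxa))
  list(records = validate_records(records), manifest = manifest,
       truth = truth_tbl)
}

#' Emit synthetic genome neighborhoods with planted partner distances
#'
#' Builds one single-contig gene table per genome: a `cylK_like` gene
#' whose id equals the taxon id (linking it to the candidate sequence), a
#' partner gene at exactly each specified ordinal distance, and `other`
#' filler genes elsewhere. The contig is extended automatically when a
#' distance exceeds its span.
#'
#' @param taxa Character vector of taxon ids (one genome each,
#'   `genome_id = "g_<taxon>"`).
#' @param partner_spec Tibble with columns `taxon`, `family`, `distance`
#'   (>= 1): partner genes to place.
#' @param contig_genes Baseline number of genes per contig (default 40).
#' @param seed Optional integer seed (placement of the candidate gene is
#'   random).
#' @return A list with `genes` (validated gene table) and `planted`
#'   (tibble of the planted distances).
#' @export
emit_neighborhoods <- function(taxa, partner_spec = NULL, contig_genes = 40,
                               seed = NULL) {
  if (is.null(partner_spec)) {
    partner_spec <- tibble(taxon = character(), family = character(),
                           distance = integer())
  }
  stopifnot(all(partner_spec$distance >= 1))
  run <- function() {
    rows <- list()
    for (tx in taxa) {
      spec <- partner_spec[partner_spec$taxon == tx, , drop = FALSE]
      dmax <- max(c(0, spec$distance))
      span <- max(contig_genes, 2 * dmax + 2)
      # keep room on both sides so every planted distance is placeable
      cylk_at <- if (dmax > 0) sample(seq(dmax + 1, span - dmax), 1)
                 else sample.int(span, 1)
      used <- cylk_at
      g <- tibble(genome_id = paste0("g_", tx), contig_id = "contig1",
                  gene_index = cylk_at, gene_id = tx,
                  family_label = "cylK_like")
      for (s in seq_len(nrow(spec))) {
        at <- cylk_at + spec$distance[s]          # place downstream
        if (at %in% used) at <- cylk_at - spec$distance[s]
        if (at < 1 || at %in% used) {
          abort("emit_neighborhoods: cannot place partner at planted distance")
        }
        used <- c(used, at)
        g <- bind_rows(g, tibble(
          genome_id = paste0("g_", tx), contig_id = "contig1",
          gene_index = as.integer(at),
          gene_id = paste0(tx, "_", spec$family[s], "_", s),
          family_label = spec$family[s]))
      }
      span <- max(span, max(used))
      filler_at <- setdiff(seq_len(span), used)
      g <- bind_rows(g, tibble(
        genome_id = paste0("g_", tx), contig_id = "contig1",
        gene_index = as.integer(filler_at),
        gene_id = paste0(tx, "_f", filler_at), family_label = "other"))
      rows[[tx]] <- g
    }
    genes <- validate_gene_table(bind_rows(rows))
    list(genes = genes, planted = partner_spec)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build the standard fully ground-truthed screening cohort
#'
#' Simulates the cohort used throughout the test suite and documentation:
#' a synthetic CylK-like parent (660 residues: a 240-residue N-terminal
#' block followed by a 420-residue C-terminal block, carrying the expected
#' residue at every surveyed catalytic position), a family of homologs
#' evolved from it at moderate divergence, of which a subset loses the
#' N-terminal domain; explicit planting of the core catalytic pair
#' (Arg105/Tyr473) in a designated clade and of contrasting residues
#' elsewhere; a divergent second synthetic parent (BrtB-like, evolved far
#' enough to sit near 30% identity); unrelated random sequences; and
#' genome neighborhoods with partner halogenase and MAR-synthase genes at
#' planted ordinal distances. All randomness flows through one stream
#' seeded once, in a fixed order (root sequence, tree, family, second
#' parent, plants, unrelated sequences, neighborhoods).
#'
#' @param seed Integer seed.
#' @param n_homolog Intact homologs (default 20).
#' @param n_truncated N-domain-truncated homologs (default 20).
#' @param n_unrelated Unrelated random sequences (default 20).
#' @param mean_branch_length Mean per-branch divergence (default 0.02;
#'   sequential-attachment trees are ~20 edges deep at this size, so
#'   root-to-tip divergence is ~0.2-0.6 expected substitutions per site
#'   and family identity to the parent spans roughly 50-95%).
#' @param indel_rate Indel events per site per unit branch (default 0.005).
#' @param n_domain_len,c_domain_len Domain block lengths (defaults 240 and
#'   420).
#' @return A list: `candidates`, `parents` (records tibbles, numbering
#'   parent first), `genes` (gene table), `truth` (per-taxon tibble with
#'   `is_homolog`, `has_n_domain`, `has_core_pair`, partner distances),
#'   `manifest` (evolution manifest), `planted_partners`.
#' @export
make_screen_cohort <- function(seed, n_homolog = 20, n_truncated = 20,
                               n_unrelated = 20, mean_branch_length = 0.02,
                               indel_rate = 0.005, n_domain_len = 240,
                               c_domain_len = 420) {
  cfg <- screen_config()
  key_spec <- c(cfg$key_positions, cfg$extended_positions)
  withr::with_seed(seed, {
    L <- n_domain_len + c_domain_len
    root <- sample(std_letters(), L, replace = TRUE)
    root[as.integer(names(key_spec))] <- unname(key_spec)
    root_seq <- paste(root, collapse = "")

    n_fam <- n_homolog + n_truncated
    tree <- simulate_tree(n_fam, mean_branch_length)
    fam <- evolve_family(root_seq, tree, indel_rate = indel_rate)

    # second parent: one long branch from the root, aiming near the
    # identity of the divergent reference pair (exp(-1.2) ~ 0.30)
    brtb_state <- evolve_branch(
      list(res = root, hom = seq_len(L)), b = 1.2, indel_rate = indel_rate)
    brtb_seq <- paste(brtb_state$res, collapse = "")

    # choose truncated taxa and the core-pair clade
    taxa <- tree$tip.label
    truncated <- sample(taxa, n_truncated)
    intact <- setdiff(taxa, truncated)
    core_members <- c(sample(intact, ceiling(length(intact) * 0.6)),
                      sample(truncated, floor(n_truncated * 0.4)))
    plant_spec <- tibble(
      position = c(105L, 473L),
      residue = c("R", "Y"),
      off_residue = c("Q", "F"),
      taxa = list(core_members, core_members)
    )
    planted <- plant_features(fam$records, fam$manifest, plant_spec,
                              truncate_taxa = truncated,
                              n_domain_len = n_domain_len)

    unrelated <- aa_records(
      id = sprintf("UNREL_%02d", seq_len(n_unrelated)),
      residues = vapply(seq_len(n_unrelated), function(i) {
        paste(sample(std_letters(), L, replace = TRUE), collapse = "")
      }, character(1)),
      organism_id = ""
    )

    candidates <- bind_rows(planted$records, unrelated)

    # neighborhoods: homolog genomes get partners at planted distances
    partner_spec <- bind_rows(lapply(taxa, function(tx) {
      out <- list()
      if (stats::runif(1) < 0.8) {
        out[[1]] <- tibble(taxon = tx, family = "cylC_like",
                           distance = sample(1:30, 1))
      }
      if (stats::runif(1) < 0.5) {
        out[[2]] <- tibble(taxon = tx, family = "cylI_like",
                           distance = sample(1:30, 1))
      }
      bind_rows(out)
    }))
    nb <- emit_neighborhoods(taxa, partner_spec)

    core_state <- planted$truth |>
      group_by(.data$taxon) |>
      summarise(has_core_pair = all(.data$state == "present"),
                .groups = "drop")
    truth <- tibble(taxon = candidates$id) |>
      mutate(is_homolog = .data$taxon %in% taxa,
             has_n_domain = !(.data$taxon %in% truncated) &
               .data$is_homolog) |>
      left_join(core_state, by = "taxon") |>
      # residue truth is defined only for family members; an unrelated
      # sequence can align R/Y at the key positions by chance
      mutate(has_core_pair = dplyr::if_else(
        .data$is_homolog, dplyr::coalesce(.data$has_core_pair, FALSE),
        NA))

    parents <- aa_records(
      id = c("CYLK_SYN", "BRTB_SYN"),
      residues = c(root_seq, brtb_seq),
      description = c("synthetic CylK-like numbering parent",
                      "synthetic divergent BrtB-like parent")
    )

    list(candidates = candidates, parents = parents, genes = nb$genes,
         truth = truth, manifest = planted$manifest,
         planted_partners = nb$planted,
         plant_truth = planted$truth)
  })
}
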