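# Distance estimation, neighbor joining, bootstrap support, Newick I/O.
#
# The family tree is a descriptive scaffold onto which residue and
# co-localization annotations are mapped, so a distance-based
# neighbor-joining reconstruction with nonparametric bootstrap is used:
# it is exact on additive distances and fully reproducible.

#' Kimura-corrected protein distance matrix from a multiple alignment
#'
#' For each sequence pair, the mismatch fraction *p* is computed over the
#' columns where both rows are non-gap, then corrected for multiple hits
#' with Kimura's formula `d = -ln(1 - p - p^2/5)` (expected substitutions
#' per site). Saturated pairs, where the corrected value is undefined
#' (`1 - p - p^2/5 <= 0`), receive the ceiling `max_distance`.
#'
#' @param msa A `multiple_alignment` (typically after
#'   [mask_gap_columns()]).
#' @param max_distance Ceiling applied to saturated pairs (default 10).
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   ids as dimnames.
#' @export
protein_distance <- function(msa, max_distance = 10) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared)) {
        abort(sprintf("no shared non-gap columns between '%s' and '%s'",
                      msa$ids[i], msa$ids[j]))
      }
      p <- mean(m[i, shared] != m[j, shared])
      d[i, j] <- d[j, i] <- kimura_distance(p, max_distance)
    }
  }
  d
}

# Kimura (1983) correction for protein p-distances.
kimura_distance <- function(p, max_distance = 10) {
  arg <- 1 - p - p^2 / 5
  if (arg <= 0) max_distance else min(-log(arg), max_distance)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion is joined, with branch lengths from the usual rate-corrected
#' formulas (negative estimates clamped to zero). On an additive distance
#' matrix, the tree's path-length metric reproduces the input exactly. Ties
#' in Q are broken deterministically in favor of the lowest-index pair.
#' The result is unrooted, represented with a trifurcating root.
#'
#' @param d Symmetric numeric distance matrix with ids as dimnames (at
#'   least 3 taxa).
#' @return An [ape::read.tree()]-style `phylo` object.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) abort("neighbor_joining: need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    abort("neighbor_joining: distance matrix must be symmetric")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  # each active cluster carries its Newick substring
  nwk <- labels
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    hit <- which(q == min(q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- hit[[1]]; j <- hit[[2]]
    li <- max(0, d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- max(0, d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_nwk <- sprintf("(%s:%.15g,%s:%.15g)", nwk[i], li, nwk[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    d <- d2
    nwk <- c(nwk[keep], new_nwk)
  }
  la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  str <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nwk[1], la, nwk[2], lb, nwk[3], lc)
  ape::read.tree(text = str)
}

# Nontrivial bipartitions of an unrooted tree as canonical string keys.
# Each key is the sorted tip set on the side NOT containing the anchor tip
# (the alphabetically first label), so keys are rooting-invariant.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# Bipartition key for each internal node (NA where trivial), aligned with
# node numbering Ntip+1 .. Ntip+Nnode.
node_bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  vapply(seq_along(parts), function(k) {
    side <- tips[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      paste(sort(side), collapse = "|")
    } else NA_character_
  }, character(1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Nonparametric bootstrap: alignment columns are resampled with
#' replacement `n_replicates` times; distances and the NJ tree are rebuilt
#' per replicate; the support of each internal edge of the tree built from
#' the full alignment is the percentage of replicate trees containing the
#' same bipartition. A single seed controls the whole resampling stream,
#' with replicates drawn in order, so results are reproducible.
#'
#' @param msa A masked `multiple_alignment` with at least 4 sequences.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling stream.
#' @param max_distance Saturation ceiling passed to [protein_distance()].
#' @return The NJ tree from the full alignment, with integer supports in
#'   \[0, 100\] as `node.label` on internal nodes (empty at the root and
#'   other trivial splits).
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              max_distance = 10) {
  stopifnot(n_replicates >= 1)
  base <- neighbor_joining(protein_distance(msa, max_distance))
  keys <- node_bipartition_keys(base)
  counts <- setNames(integer(sum(!is.na(keys))), keys[!is.na(keys)])
  m <- msa_matrix(msa)
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- new_msa(msa$ids, apply(m[, cols, drop = FALSE], 1,
                                        paste, collapse = ""))
      rep_tree <- neighbor_joining(protein_distance(rep_msa, max_distance))
      seen <- tree_bipartitions(rep_tree)
      hits <- names(counts) %in% seen
      counts[hits] <- counts[hits] + 1L
    }
  })
  support <- as.integer(round(100 * counts / n_replicates))
  base$node.label <- ifelse(is.na(keys), "",
                            as.character(support[match(keys, names(counts))]))
  base
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with full precision and bootstrap supports as
#' internal node labels (FigTree-compatible).
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a tree in Newick format
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum((strsplit(txt, "", fixed = TRUE)[[1]] == "(") -
                    (strsplit(txt, "", fixed = TRUE)[[1]] == ")"))
  if (length(depth) > 0 && (any(depth < 0) || tail(depth, 1) != 0)) {
    off <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    abort(sprintf("Newick parse error near character %d: unbalanced parentheses",
                  off))
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree)) abort("Newick parse error: could not read tree")
  tree
}
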