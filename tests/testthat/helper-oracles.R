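# Shared fixtures and independent oracles.

# Brute-force enumeration of all global alignments with affine penalties
# (gap of length k costs open + (k-1)*ext; terminal gaps penalized).
# Independent of the dynamic-programming engine under test.
brute_force_score <- function(a, b, matrix = blosum62(), open = 10,
                              ext = 0.5) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A); lb <- length(B)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > la && j > lb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= la && j <= lb) rec(i + 1L, j + 1L, sc + matrix[A[i], B[j]], 1L)
    if (i <= la) rec(i + 1L, j, sc - (if (last == 2L) ext else open), 2L)
    if (j <= lb) rec(i, j + 1L, sc - (if (last == 3L) ext else open), 3L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix: the generating-tree oracle for NJ.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Canonical bipartition keys via phangorn, independent of the package's
# own bipartition code.
phangorn_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  sp <- phangorn::as.splits(ape::unroot(tree))
  keys <- vapply(seq_along(sp), function(k) {
    side <- tips[sp[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      paste(sort(side), collapse = "|")
    } else NA_character_
  }, character(1))
  unique(keys[!is.na(keys)])
}

# The standard ground-truthed cohort (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

std_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- make_screen_cohort(seed = 1)
  }
  .fixture_env$cohort
}

std_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    co <- std_cohort()
    .fixture_env$calls <- run_screen(co$candidates, co$parents,
                                     screen_config())
  }
  .fixture_env$calls
}

# A small low-divergence family reused by alignment/MSA tests.
small_family <- function() {
  if (is.null(.fixture_env$family)) {
    .fixture_env$family <- withr::with_seed(11, {
      root <- paste(sample(setdiff(aa_alphabet(), "X"), 400, TRUE),
                    collapse = "")
      tree <- simulate_tree(6, mean_branch_length = 0.03)
      evolve_family(root, tree, indel_rate = 0.01)
    })
  }
  .fixture_env$family
}
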