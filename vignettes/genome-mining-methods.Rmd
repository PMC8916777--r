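---
title: "Methods: mining genomes for CylK-like alkyl-halide-activating enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining genomes for CylK-like alkyl-halide-activating enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halideminer)
```

# The model

CylK is a calcium-dependent beta-propeller/beta-sandwich enzyme that
forms C–C bonds by activating a secondary alkyl chloride — a Friedel–Crafts
alkylation of a resorcinol nucleophile. Functional members of the family
need two structural elements at once:

* an N-terminal beta-propeller domain, which in known macrocyclizing
  members precedes a junction near parent residue Lys240, and
* a catalytic arginine/tyrosine pair (parent numbering Arg105 in the
  propeller, Tyr473 in the sandwich) that binds the halide leaving group.

`halideminer` encodes this as a two-gate screen over candidate protein
sequences plus a genomic-context layer, and ships a calibrated synthetic
data generator so that every stage can be checked against a planted truth.

# The screen

Candidates are compared with up to two parent sequences (a CylK-like
numbering parent and a divergent second parent) by global alignment.

1. **Identity gate.** A candidate passes when its percent identity to the
   *best-matching* parent is strictly greater than 0.24. Identity is the
   number of identical aligned residue pairs divided by the full
   alignment length (gap columns included); an `"aligned"` denominator
   that excludes gap columns is available as an option. `X` never counts
   as identical or similar.
2. **Domain gate.** The junction is the candidate position aligned to
   parent position 240; when 240 itself is gapped, the nearest aligned
   parent position before 240 is used. The N-domain length is
   `junction - 1` candidate residues and must be at least 135.
3. **Key residues.** Positions are read through the alignment to the
   numbering parent: Arg105 and Tyr473 define the core pair
   (`has_core_pair`), and a wider panel of conserved positions
   (78 K, 96 D, 265 S, 266 S, 267 T, 318 S, 324 S, 334 N, 374 E, 377 K,
   379 T, 438 L, 440 D, 499 F, 502 D, 504 E, 558 L, 559 D, 562 D, 616 T,
   618 T) is reported per candidate as `present` / `absent` / `gap`.

Threshold semantics are deliberate and tested: identity is a strict
`>` (0.24 exactly fails), domain length is an inclusive `>=`.

# Pairwise alignment

Needleman–Wunsch global alignment with BLOSUM62 and affine gaps, scored
with the convention that a gap of length $k$ costs
$\mathrm{open} + (k-1)\,\mathrm{extend}$, defaults
$\mathrm{open} = 10$, $\mathrm{extend} = 0.5$. The dynamic programming is
delegated to Biostrings, with the penalty parameters re-mapped to that
convention; the BLOSUM62 matrix (20 amino acids plus `X`) is embedded in
the package so scoring does not depend on external data files. The test
suite verifies optimality of the returned score against brute-force
enumeration of all gapped alignments on small random pairs. When several
alignments share the optimal score, the traceback order of the underlying
engine decides which one is returned; only the score, not the tie choice,
is part of the package contract.

```{r align-example}
aln <- align_global(c(a = "MKVLWAYARND"), c(b = "MKVLAYARD"))
tidy(aln)
```

# Genomic context

Gene tables (one row per gene: genome, contig, ordinal index, id, family
label) come from TSV or GFF3. For each screened candidate, `colocalize()`
finds the nearest same-contig gene of a partner family; the ordinal
distance must be **strictly** below the window to count as clustered —
fewer than 18 genes for halogenases (`cylC_like`), fewer than 12 for
mono/acyltransferase-reductase synthase partners (`cylI_like`).
`summarize_cohort()` aggregates to organism- and gene-level counts.

# Alignment, masking, tree

Passing candidates are aligned by center-star progressive alignment
anchored on the numbering parent ("once a gap, always a gap" merging of
pairwise alignments). Columns whose gap fraction is at least 0.90 are
masked out. Distances are Kimura-corrected protein distances,

$$ d = -\ln\!\left(1 - p - \tfrac{p^2}{5}\right), $$

with $p$ the proportion of differing residues over shared non-gap
columns, and a saturation ceiling of 10 when the argument of the
logarithm is non-positive. The formula above is applied exactly as
written; it is a 20-state approximation, and on data simulated under the
package's uniform-replacement model it carries a small (+0.01-scale)
upward bias at moderate divergence, which the tests bound explicitly.

Trees come from the package's own neighbor-joining implementation
(Saitou–Nei $Q$-matrix, lowest-index tie-breaking, negative branch
lengths clamped to zero, trifurcating root). On additive matrices the
reconstruction is exact; tests require the path metric back to within
$10^{-9}$ on hundreds of random cases and cross-check topology against an
independent implementation. Bootstrap supports resample alignment columns
with replacement, one replicate at a time under a fixed seed, and label
internal nodes with the percentage of replicates containing the same
bipartition (bipartitions keyed canonically by the side *not* containing
the alphabetically first tip).

# Synthetic data and calibration

`make_screen_cohort(seed)` builds a standard 60-candidate cohort: 20
intact homologs, 20 N-terminally truncated homologs, and 20 unrelated
random sequences, evolved along a sequential random-attachment tree with
exponential branch lengths (default mean 0.02 substitutions/site).
Substitutions occur per site with probability $1 - e^{-b}$, replacements
uniform over the other 19 letters; single-site indels are
Poisson(indel rate × branch length × sequence length). The generator
keeps exact residue-level homology maps, so planted features (Arg105/
Tyr473 on chosen taxa, off-residues elsewhere, truncations, partner genes
at chosen ordinal distances) yield a ground truth the screen can be
scored against with zero tolerance.

Defaults were calibrated once, before the acceptance checks were frozen:
the sequential-attachment topology is deep (root-to-tip paths of ~20
edges), so the default branch-length mean is 0.02 to keep intact
homologs inside the detection range of the identity gate. The generator
is a deliberately simple null model: uniform replacement, no rate
heterogeneity, no profile structure. It is a truth oracle for the
pipeline's bookkeeping, not a realistic protein evolution model.

```{r cohort, eval = FALSE}
co <- make_screen_cohort(seed = 1)
calls <- run_screen(co$candidates, co$parents, screen_config())
glance(calls)
```

# Problem sizes and costs

The intended scale is cohorts of tens to a few hundred candidates of
~400–700 residues. The screen is quadratic in sequence length per
pairwise alignment (~0.1 s per pair); neighbor joining is cubic in the
number of tips and instantaneous below a few hundred tips; bootstrap
cost is linear in replicates. The full 60-candidate pipeline with 100
bootstrap replicates runs in well under a minute.

# Limitations

* The center-star MSA is a heuristic; it is exact for indel-free
  families and adequate for the shallow divergences the screen accepts,
  but it is not a substitute for a profile aligner at high divergence.
* Ordinal gene distance ignores strand and intergenic spans.
* The published reference parent pair is not redistributed with the
  package; the corresponding acceptance check requires the user to
  supply those sequences and fails (honestly) otherwise.
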