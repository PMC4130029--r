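---
title: "Alignment-free similarity by shared k-mer counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free similarity by shared k-mer counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersim)
```

## The method

Progressive multiple-alignment tools and tree builders need an all-pairs
similarity estimate before any alignment exists. Alignment-based scoring
is O(n²) per pair; k-mer counting gets a useful estimate in O(n). A
sequence X of length L~X~ over an alphabet of r symbols has
L~X~ − k + 1 windows of length k; counting the occurrences n~X~(τ) of
every k-tuple τ gives a count vector, conceptually dense over all
r^k^ tuples, and dividing by the window count gives a frequency vector.
Two sequences are then scored by the fraction of k-mer occurrences they
share:

$$F(X,Y) \;=\; \frac{\sum_\tau \min\left[n_X(\tau),\, n_Y(\tau)\right]}
                    {\min(L_X, L_Y) - k + 1}$$

F lies in [0, 1]: identical sequences score 1, sequences with no k-mer
in common score 0, and normalizing by the *shorter* sequence's window
count keeps a short fragment of a long sequence from being penalized
for the length difference.

For proteins, counting can be done after translating residues into a
*compressed alphabet*: a partition of the 20 amino acids into classes
of biochemically interchangeable residues (SE-V(10) for instance groups
{A,S,T}, {D,E,N}, {I,L,M,V}, {K,Q,R}, {F,Y} and leaves C, G, H, P, W
alone). Substitutions within a class — the most common kind between
homologs — then no longer break a shared k-mer, so related pairs score
higher and the method stays informative at larger evolutionary
distances:

```{r}
s1 <- "SAANILVGENLVCKVADFGLARL"   # three aligned kinase-domain fragments
s2 <- "AARNILVGENYICKVADFGLARL"
s3 <- "AARNVLIGEDNVAKICDFGLARV"
conserved_window_count(c(s1, s2, s3), 1, "identity-protein")  # 12 columns
conserved_window_count(c(s1, s2, s3), 1, "se-v10")            # 19 columns
kmer_similarity(s1, s2, 3, "identity-protein")
kmer_similarity(s1, s2, 3, "se-v10")
```

Coarsening the alphabet can only merge tuples, and the shared-count
numerator is superadditive under merging, so for any pair F under a
compressed alphabet is ≥ F under the plain 20-letter alphabet. The test
suite checks this dominance property on hundreds of simulated pairs.

## Parameters

* **k** (word length, default 3): larger k demands longer runs of
  exact (class-level) identity, so it sharpens specificity but decays
  faster with divergence. k = 3 with SE-V(10) is the package default
  for proteins; for nucleotides the default is k = 3 over the plain
  {A,C,G,T} alphabet. k up to ~6 over 20 letters is practical because
  counting is sparse (only tuples that occur are stored); the dense
  r^k^ vector exists only as a brute-force oracle in the tests.
* **alphabet**: `identity-protein`, `identity-dna`, or one of eleven
  built-in compressed alphabets (`se-b14`, `se-b10`, `se-v10`,
  `li-a10`, `li-b10`, `solis-d10`, `solis-g10`, `murphy10`, `se-b8`,
  `se-b6`, `dayhoff6`). Each is validated at construction as a true
  partition of the 20 residues; each class is represented by its
  alphabetically first member, a display convention the scores are
  invariant to. User partitions load from a `NAME: CLASS,CLASS,...`
  text file via `read_alphabet_config()`.
* **n_workers / backend**: worker count and execution mode for the
  master–worker matrix build (below).

## Degenerate inputs and numerical choices

Symbols outside the alphabet's base set (X, B, Z, gaps, ...) pass
through translation untouched and are excluded at exactly one place:
any counting window containing such a symbol is skipped and tallied in
`skipped_windows`. The denominator of F still uses the raw sequence
lengths, so unknown residues can only lower a score, never inflate it.
If the shorter sequence of a pair is shorter than k the denominator is
undefined; the pair scores 0 with a warning rather than an error, so a
batch matrix run never aborts on one short sequence. Every F is an
integer numerator divided by an integer denominator, computed in one
division at the end — which is what makes "bit-identical" a meaningful
claim across execution modes.

## The triangular matrix and the master–worker scheme

F is symmetric, so only the strict lower triangle is computed: entry
(i, j) for 1 ≤ j < i ≤ n, n(n−1)/2 values. The parallel scheme is
static cyclic row distribution: row i goes to worker
((i − 1) mod p) + 1, so with 7 rows and 3 workers the first worker owns
rows 1, 4, 7. All n rows are assigned (row 1 simply carries zero
pairs; the diagonal is never stored). Because row i costs i − 1 pairs,
dealing rows cyclically balances load to within n entries between any
two workers without dynamic scheduling. Each worker packs its rows —
ascending, each row's columns ascending — into one flat result vector,
the single message it returns; the master unpacks the vectors by
position into the matrix. Determinism is structural: every value is
computed by the same code path and placed by index, so the result is
identical for any worker count, backend, and arrival order.

```{r}
fam <- generate_family(12, 80, 0.2, alphabet = "identity-protein", seed = 1)
m_seq <- compute_matrix_sequential(fam, 3, "se-v10")
m_par <- compute_matrix_parallel(fam, 3, "se-v10", n_workers = 4)
identical(m_seq$values, m_par$values)
```

Two backends share the contract: `"serial"` runs the workers in a loop
in-process (the default, and what the tests exercise), `"process"`
forks one child per worker via `parallel::mclapply`. The scheme was
designed for message-passing clusters, and the one-vector-per-worker
contract is exactly what an MPI backend would need; implementing one
is out of scope here.

## The synthetic generator

`generate_family()` draws a uniform-random ancestor and derives each
member by independent per-residue substitution at a given rate, with
the replacement drawn uniformly from the other residues. It emulates a
family of ungapped homologs at a controlled divergence — the one knob
the similarity score actually responds to — and is seeded, so every
simulated dataset in the tests is reproducible. It deliberately omits
indels, substitution-matrix bias, rate heterogeneity and phylogenetic
structure; passing tests therefore demonstrate the *counting and
scheduling machinery* on divergence-controlled input, not biological
realism of the score itself, which rests on the compressed alphabets.

## Problem sizes in the tests

The test suite runs the full pipeline at sizes where the independent
oracles are affordable: dense-enumeration cross-checks at r ≤ 20,
k ≤ 3 on hundreds of random sequences, matrix equality on a
50-sequence × 120-residue family across worker counts 1–7, and
dominance of compressed-alphabet similarity on 200 simulated pairs.
These sizes exercise every code path (the machinery is size-oblivious);
production use scales to thousands of sequences since each pair is
O(n) time and the matrix is O(n²) in pairs, embarrassingly parallel by
construction.

## Known limitations

Counting is strand-naive (no reverse-complement matching for DNA).
F is a similarity, not a metric distance, and no significance model is
attached to it. Guide-tree construction and the alignment itself are
downstream of this package's scope.
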