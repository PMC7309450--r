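---
title: "Methods: canonical k-mer cosine distance for assembled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical k-mer cosine distance for assembled metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each sample is a set of assembled contigs. Its signature is the sparse
vector of **canonical k-mer counts**: every length-k window over
{A, C, G, T} contributes one count to the key
$\min(w, \mathrm{rc}(w))$, where sequences are ordered by their 2-bit
encoding (A = 0, C = 1, G = 2, T = 3, leftmost base most significant; the
numeric order equals lexicographic order). Pooling each k-mer with its
reverse complement makes the profile independent of the strand on which a
contig happened to be assembled — the property that matters most for
assemblies, where strand is arbitrary.

Two conventions exist for "counting both strands": incrementing the single
canonical key (as done here), or incrementing both $w$ and $\mathrm{rc}(w)$.
For **odd k** these give cosine-identical results: no odd-length k-mer is
its own reverse complement, so the double-counting variant produces exactly
twice the canonical vector, and cosine distance is invariant to positive
scaling. For even k, a palindromic window ($w = \mathrm{rc}(w)$) is counted
once under one key; odd k is therefore the supported default, and the
analyses use $k \in \{15, 17, 19, 21\}$ with 21 as the package default
(the value at which k-mer matches become representative of content rather
than chance for this read/contig regime).

Samples are compared by the cosine distance between their full count
vectors,
$$ d(\mathbf p, \mathbf q) \;=\; 1 -
   \frac{\mathbf p \cdot \mathbf q}{\lVert\mathbf p\rVert_2\,
   \lVert\mathbf q\rVert_2} \;\in\; [0, 1], $$
with the dot product taken over the intersection of the two key sets. The
full vector is always used — no sketching, no minimum-count threshold —
because resolution between *similar* samples is exactly what subsetting
destroys. Raw counts are stored rather than frequencies: cosine distance is
scale-invariant, so normalisation would only add rounding.

## Counting implementation

Counting is a rolling 2-bit update in C++ (one pass per contig): the
forward and reverse-complement codes of the current window are both
maintained in 64-bit integers and the smaller is the counter key. Any
non-ACGT character resets the window ("skip on N"), so a window containing
N contributes nothing; `total` is the number of counted windows. Lowercase
input is folded to uppercase, and IUPAC ambiguity codes other than ACGT are
treated as N — input conventions chosen here, since ambiguous bases are
rare in assemblies and a fractional-attribution scheme would buy little.

Canonical codes cross into R as doubles, which represent integers exactly
up to $2^{53}$; **k is therefore capped at 26** ($2k \le 52$ bits). All
analyses here use $k \le 21$. A naive string-dictionary counter (hash of
`min(window, rc(window))` strings) lives in the test suite as an
independent oracle; the encoded counter must reproduce it exactly on
hundreds of random contig sets, and strand invariance is asserted exactly,
not approximately.

Two numerical details in the distance itself: the norm product is computed
as $\sqrt{(\sum p_i^2)(\sum q_i^2)}$, and count vectors with identical
support and exactly proportional counts short-circuit to distance 0, so
self-distance and fwd/rc-distance are exactly zero rather than
$O(10^{-16})$; the general result is clamped to $[0, 1]$ against rounding
drift.

## Distance matrix, trees, ordination

The pairwise matrix is computed on the upper triangle and mirrored;
serialisation (labelled TSV, or relaxed PHYLIP with whitespace-free labels
up to 64 characters) uses fixed 6-decimal rendering and `\n` endings, so
identical inputs yield byte-identical files. Six decimals is far below any
biologically meaningful difference at this scale while keeping files
readable; readers re-validate symmetry (tolerance $10^{-9}$), zero
diagonal, and clamp entries within $10^{-6}$ outside $[0, 1]$ with a
warning.

**Neighbour joining** uses the standard Saitou–Nei agglomeration as
implemented in `ape::nj()`, consistent on additive matrices (verified in
the tests against hand-derived 3- and 4-taxon solutions and random
tree-generated matrices, path lengths reproduced within $10^{-9}$). The
tree is left unrooted with a trifurcation at the last join. Cosine matrices
are generally not additive, so negative branch lengths can occur; by
default each is clamped to zero with the deficit moved onto a sibling
branch, preserving total tree length — a common convention, made explicit
here because no single standard exists; `clamp_negative = FALSE` keeps raw
values. Newick output uses fixed-precision branch lengths (default 6
decimals) and quotes labels only when they contain structural characters.

**PCoA** is classical metric scaling: Gower double-centering
$B = -\tfrac12 J D^{(2)} J$ and a symmetric eigendecomposition (via
`stats::cmdscale`), coordinates $= v_j\sqrt{\lambda_j}$. Because cosine
distances need not be Euclidean, negative eigenvalues can appear; they are
excluded from the coordinates and from the proportion-explained denominator
(the sum of positive eigenvalues), and their magnitudes are reported as a
diagnostic. No Cailliez or Lingoes correction is applied — the embedding is
used for visualisation, not inference, and a correction would distort the
variance fractions reported on the axes. Axis signs are fixed by forcing
the largest-magnitude coordinate on each axis positive, so plots are
reproducible across BLAS implementations.

## Group comparisons

Distance distributions are compared with the two-sided Mann–Whitney
rank-sum test. For a group pair $(g_1, g_2)$ the default feed is
**between-group distances vs the pooled within-group distances** of the two
groups; an alternative mode compares two between-group distance sets
against each other. Both are exposed (and must be chosen explicitly in the
CLI) because either reading is defensible for "differences between groups";
between-vs-within is the default as the more direct question — are groups
farther apart than they are wide?

The p-value is exact (from the null permutation distribution of $U$, via
`pwilcox`) when $n_1 + n_2 \le 12$ and the pooled values are tie-free;
otherwise the normal approximation with tie correction and continuity
correction is used. The test suite checks the exact route against full
enumeration of rank assignments, and calibration under the null
(rejection rate at $\alpha = 0.05$ within $[0.03, 0.07]$ over 2000
replicates). Distances sharing a sample are statistically dependent, so
these p-values are descriptive rather than strictly valid significance
statements; they are reported without a dependence correction, as is
conventional for this style of analysis, and no multiple-testing adjustment
is applied across group pairs by default (Benjamini–Hochberg is available
via `adjust = "BH"`). Stars follow the usual ladder with `***` for
p < 0.001. Each side of every comparison is summarised as mean ± SEM
(sd/$\sqrt n$, $n-1$ denominator, SEM = 0 for a single value).

The rank-sum route is gated in practice on non-normality of distance data;
`normality_test()` implements the D'Agostino–Pearson omnibus statistic
(skewness deviate after D'Agostino's Johnson-$S_U$ transform, kurtosis
deviate after Anscombe–Glynn, $K^2 = Z_s^2 + Z_k^2 \sim \chi^2_2$),
requiring $n \ge 8$. This particular omnibus test is the package's choice
among the many normality tests; it is validated against frozen reference
values and for null uniformity of its p-values.

## The simulator

`simulate_dataset()` generates the structure the analyses assume: groups of
samples drawn from shared source material with small divergence.
`n_sources` uniform-ACGT source genomes are drawn once; each sample's
contigs pick a source by the group's mixture weights, excise a random
substring, apply independent base substitutions (each hit base becomes one
of the other three, uniformly), and flip to the reverse strand with
probability ½. The defaults — 2 sources × 200 kb, 2 groups × 5 samples
with disjoint single-source mixtures, 50 contigs of 1–5 kb, substitution
rate 0.01 — are the package's standing study conditions: large enough that
k = 15–21 profiles contain $\sim 10^5$ k-mers per sample, small enough to
run in seconds, with a substitution rate at the low end of strain-level
divergence so that group separation is present but not trivial.
Determinism is strict: per-sample RNG substreams are derived from
(seed, sample index), so adding a sample never changes earlier ones, and
identical configs give byte-identical FASTA output.

What the simulator does **not** emulate: real genome composition (uniform
base frequencies, no repeats or GC structure), abundance variation,
indels or rearrangements, sequencing error profiles, chimeric or
mis-assembled contigs, and shared taxa between groups beyond what mixture
weights express. Passing tests therefore demonstrate the pipeline's
mathematical properties (strand invariance, counting correctness, tree and
ordination consistency, test calibration) and its qualitative behaviour on
grouped data — not performance on any real microbiome.

## Validation scale

The checked-in validation uses problem sizes chosen to exercise every code
path while keeping a full run in tens of seconds: counting oracles on
200 random contig sets at $k \in \{3, 5, 7, 15\}$; 50 random additive
matrices for NJ consistency; 2- and 3-dimensional point sets for exact
PCoA recovery; 2000 null replicates for rank-sum calibration; and five
seeded replicates of the default two-group simulation for the end-to-end
clade-separation check at k = 15. The acceptance script runs the same
pipeline at k = 21 under a caller-supplied seed.

## Known limitations

* Even k is supported but palindromic windows collapse to one key; use odd
  k for strict strand invariance.
* k is capped at 26 by the double-precision code representation.
* Cosine distance saturates at 1 for k-mer-disjoint samples, so very
  distant groups compress against the upper bound (visible in the
  simulator's disjoint-source defaults at k = 21).
* Rank-sum p-values on pairwise distances inherit the dependence caveat
  above.
* Profiles of many large samples are held in memory simultaneously when
  building the matrix; at k ≤ 21 and assembly sizes in the hundreds of Mb
  this is a few GB, but no out-of-core path is provided.
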