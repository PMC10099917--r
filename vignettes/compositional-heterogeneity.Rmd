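---
title: "Measuring compositional heterogeneity with RCFV and its size-normalized family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring compositional heterogeneity with RCFV and its size-normalized family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcfv)
```

## The model and its assumptions

Most substitution models used in phylogenetics assume stationarity: state
frequencies are a property of the whole alignment, constant across the
tree. A taxon whose composition deviates strongly from the alignment-wide
average violates this assumption, and such violations are a documented
cause of artefactual groupings. RCFV measures exactly the quantity those
models care about — deviation of each taxon's relative state frequencies
`μ_ij` from the dataset mean `μ̄_j`:

$$RCFV = \sum_{i=1}^{n}\sum_{j=1}^{c} \frac{|\mu_{ij} - \bar\mu_j|}{n}$$

with character-specific (fix `j`) and taxon-specific (fix `i`) components
that sum exactly to the total. A large tsRCFV flags a taxon for removal; a
skewed csRCFV profile suggests recoding or masking instead.

Two conventions in this package deserve explicit statement, because the
metric's definition leaves them open when data are incomplete:

* **`μ_ij` uses the per-taxon non-missing cell count as denominator**, not
  the column count `p`. Gaps and ambiguity codes carry no compositional
  information; excluding them lets the observed residues govern the
  estimate and is what makes the metric robust to missing data. With
  complete data this reduces to `O_ij / p`.
* **`μ̄_j` is the unweighted mean of per-taxon frequencies**, not the
  pooled residue frequency. The two coincide for complete data but differ
  when effective lengths vary; the unweighted mean keeps every taxon's
  vote equal, which matches the per-taxon framing of the metric. A pooled
  alternative would down-weight gappy taxa; we do not offer it.

Missing data is defined broadly: `-`, `?`, `.` and all IUPAC ambiguity
letters (N, R, Y, S, W, K, M, B, D, H, V for nucleotides; X, B, Z, J and
the stop character `*` for amino acids). An ambiguous residue is treated
as absent rather than as a fractional count over its compatible states;
fractional-count semantics would perturb `μ_ij` slightly but would also
make the counts non-integer and the duplication identities approximate.
Input is case-insensitive and RNA `U` is canonicalized to `T`, so the
nucleotide alphabet always has exactly 4 states.

## Why normalize, and the constants

On perfectly homogeneous data RCFV is not zero: each `μ_ij` is a
binomial-type estimate whose deviation from the mean scales like
$\sqrt{f_j(1-f_j)/L_i}$, so the expected raw RCFV falls as sequences
lengthen. The package's `predict_single_change()` exposes the analytic
core of this size dependence: one substitution in a complete `n × p`
alignment moves the affected taxon's deviation terms by `(n−1)/(np)` and
every other taxon's by `1/(np)`. Both factors vanish as `p` grows; the
affected-taxon factor approaches `1/p` from below as `n` grows; and with
`c` states only 2 of the `c` per-state terms are touched at all, which is
why the alphabet size also modulates the effect.

The normalized family divides each raw metric by a fixed size constant:
`p^{-0.5} · n^{0.01} · c · 100` for the total, `p^{-0.5} · n^{-1} · c ·
100` for tsRCFV, and `p^{-0.5} · 100` for csRCFV. These exponents are
published constants and are applied exactly as printed — including the
exponent 0.01, which we implement literally rather than second-guessing
it as a rounded fit coefficient — and this package deliberately does not
refit them. `c` is always the *nominal* state count of the alphabet in
use (4, 20, or the group count for recodings such as purine/pyrimidine),
never the number of states observed: the normalization depends on how
many states are possible, not on which happened to occur. Likewise `p` is
the full column count of the scored (sub)alignment, including columns
that are missing in some taxa. One consequence users should expect:
duplicating every column leaves raw RCFV unchanged but multiplies nRCFV
by exactly √2, because the normalization credits the doubled evidence.
Another: the normalized metrics are no longer additive, so per-state or
per-taxon *shares* only make sense on the raw scale
(`rcfv_contribution()`).

## The homogeneous simulator and the bias study

`simulate_homogeneous()` draws every cell i.i.d. from one stationary
state-frequency vector. This is a deliberate simplification: it emulates
the *compositional* null (every taxon has identical expected composition)
without any tree, branch lengths or rate variation. For studying how
alignment dimensions bias a composition metric, the i.i.d. design is
equivalent in expectation to tree-based simulation under a homogeneous
model and orders of magnitude cheaper. What it does not emulate:
phylogenetic correlation between taxa, site-rate heterogeneity, and the
clustering of values ("two optima") that tree structure induces in
simulated metric distributions. Conclusions about those features of real
data cannot be drawn from these tests; conclusions about size bias can.

`run_bias_study()` crosses taxon counts with column counts. Defaults in
the tests and acceptance script use p ∈ {900, 4500, 9000} and
n ∈ {50, 150} with 100 replicates per cell — a grid spanning a 10× length
range and a 3× depth range that runs in well under a minute — and
seed-split replicates (`seed + replicate index`) so every cell is
independently reproducible. On this grid mean raw RCFV falls roughly as
`p^{-1/2}` (about 0.046 at p = 900 down to 0.014 at p = 9000 for uniform
DNA) while mean nRCFV is constant to within ~1%, which is the package's
own demonstration that the normalization does its job. For uniform
4-state composition the expectation is flat in `p` *exactly*, since
E[RCFV] ∝ p^{-1/2} cancels the `p^{-0.5}` in the constant; residual
variation across `n` comes from the √(1−1/n) factor in the deviation
spread against the `n^{0.01}` in the constant, and stays well inside a
±10% band.

## Mimic pairs and what missing data does (and does not) do

`mimic_pair()` replicates a template alignment: cells are drawn i.i.d.
from each taxon's own observed composition, with the template's missing
mask either copied verbatim (gapped) or ignored (ungapped). Per-taxon
rather than pooled composition is used so the pair differs *only* by the
mask. `apply_missingness()` builds templates with an exact count of
uniformly placed missing cells, never leaving a taxon empty.

A limitation worth understanding before interpreting mimic studies on
*homogeneous* templates: there the metric is pure sampling noise, so the
gapped replicate (effective length `(1−f)·p` per taxon, plus the
template-composition noise it inherits) systematically exceeds the
ungapped one, by approximately `1 − sqrt(1 − f/2)` in relative terms —
about 4.7% at 18% missing, 7% at 28% and 9.5% at 38% in the packaged
study. The *level* of this gap is in the single-digit percent range, and
missingness introduces no compositional bias (the gapped metric stays
centred on the no-missing expectation at the reduced effective length);
but its *trend* with the missing fraction is real and deterministic for
noise-dominated data. On real alignments, where genuine heterogeneity
dominates sampling noise, the gap is expected to be flat across
missing-data levels; a flat trend should not be demanded of homogeneous
simulations. The acceptance suite states the no-trend expectation in its
strict form and we report the measured slope rather than adjusting the
study until it passes.

## Partition scoring and sextile comparison

`score_partitions()` scores each gene with its own dimensions: `n` counts
only taxa with at least one observed residue in that gene, `p` is the
gene's length. `assign_quantiles()` sorts ascending by the chosen metric
and splits into `k` bins (default sextiles) as equally as possible,
remainder to the earliest bins, ties broken lexicographically by gene
name. The published empirical sextile sizes for a 638-gene dataset
(107, 106, 106, 104, 109, 106) are not reproducible by any equal-count
rule, implying value-based boundaries or an unstated tie policy; rather
than guess, we document our deterministic rule (638 → 107, 107, 106, 106,
106, 106) and keep full precision internally, rounding only in
Table-style reports (round-half-even to integer percent).
`compare_selections()` reports, per bin, the percentage of one metric's
genes not selected by the other, the summed alignment lengths under each
selection, and a cross-tabulation of where the non-shared genes land —
the apparatus needed to see that raw RCFV systematically favours long
genes in the "clean" bins.

## Numerical choices and degenerate inputs

* Frequencies are exact integer counts divided by integer effective
  lengths; all deviation sums are plain double-precision accumulations.
  Identities (component sums, duplication invariance) are asserted at
  1e-10–1e-12, which comfortably absorbs float reordering.
* Group frequencies are computed as sums of member-state frequencies (not
  recomputed from summed counts), so collapsing conserves mass exactly.
* A taxon with zero observed cells is an error when tabulating a single
  alignment, but is silently excluded from a gene's `n` when scoring
  partitions — the two contexts have different contracts.
* No minimum-coverage filter is applied to gappy taxa by default; every
  taxon participates with its renormalized frequency vector.
* Degenerate simulation frequencies (a single state with probability 1)
  are permitted with a warning; the resulting alignment has RCFV exactly 0.
* `apply_missingness()` resamples its mask (up to 1000 times) rather than
  biasing cell selection when a draw would empty a taxon.

## Known limitations

* RCFV-family values come with no significance test; they rank and
  quantify, and any thresholding is the user's responsibility.
* The i.i.d. simulator cannot reproduce tree-induced features of metric
  distributions (see above).
* Sliding-window or site-wise profiles, codon alphabets and NEXUS input
  are out of scope.
* The PHYLIP reader accepts the relaxed dialect (whitespace-delimited
  names, sequential or interleaved); pathological files whose taxon names
  are themselves valid sequence fragments on wrapped sequential layouts
  are resolved in favour of the sequential reading.
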