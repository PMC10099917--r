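# nrcfv

Compositional heterogeneity — taxa whose nucleotide or amino-acid
proportions differ systematically from the rest of an alignment — violates
the stationarity assumption of the substitution models used in phylogenetic
reconstruction and is a well-known source of artefacts such as long-branch
attraction and composition-driven groupings. `nrcfv` is an R package for
phylogeneticists who want to screen alignments, genes and taxa for this
problem *before* committing to expensive tree inference.

## The metrics

For an alignment with `n` taxa, `p` columns and `c` possible character
states, let `μ_ij` be the relative frequency of state `j` in taxon `i`
(computed over that taxon's non-missing cells) and `μ̄_j` the mean of
`μ_ij` over taxa. The Relative Composition Frequency Variability is

    RCFV    = Σ_i Σ_j |μ_ij − μ̄_j| / n
    csRCFV_j = Σ_i |μ_ij − μ̄_j| / n      (character-specific component)
    tsRCFV_i = Σ_j |μ_ij − μ̄_j| / n      (taxon-specific component)

The components decompose the total exactly, so a state's or taxon's share
of the heterogeneity is a simple ratio. Raw RCFV, however, is biased by
alignment size: on perfectly homogeneous data it is pure sampling noise
that shrinks as sequences lengthen, so long genes look "cleaner" than
short ones for no biological reason. The size-normalized family removes
this:

    nRCFV    = RCFV    / (p^−0.5 · n^0.01 · c · 100)
    ntsRCFV  = tsRCFV  / (p^−0.5 · n^−1  · c · 100)
    ncsRCFV  = csRCFV  / (p^−0.5 · 100)

The normalized values are comparable across alignments of different
length, depth and alphabet (4-state nucleotide, 20-state amino acid, or
any recoding such as purine/pyrimidine), at the price of no longer being
additive decompositions.

The package also provides: FASTA and relaxed PHYLIP I/O with explicit
missing-data semantics (gaps, `?`, `.` and IUPAC ambiguity codes are all
treated as missing), a seeded i.i.d. simulator of compositionally
homogeneous alignments with a grid "bias study" driver, gapped/ungapped
mimic-pair generation for missing-data experiments, and per-gene scoring
with quantile (sextile) binning and selection comparison for supermatrix
curation.

## Worked example

```r
library(nrcfv)
aln <- read_alignment("four_taxa.fasta")   # 4 taxa x 20 columns, DNA
mr  <- normalize_all(rcfv_metrics(aln, groups = state_group_presets(dna_alphabet())))
mr
#> <RCFV metrics: n = 4 taxa, p = 20 columns, c = 4 states>
#>   RCFV  = 0.134028
#>   nRCFV = 0.00147785
#>   csRCFV range: [0.0215278, 0.0486111]; tsRCFV range: [0.0145833, 0.0493056]

round(mr$ts_rcfv, 5)
#>    frog    newt     eel    carp
#> 0.01458 0.03681 0.04931 0.03333

round(rcfv_contribution(mr)$states, 2)
#>     A     C     G     T
#> 36.27 22.80 16.06 24.87
```

The total RCFV of 0.134 says that, averaged over taxa, per-taxon state
frequencies deviate from the dataset mean by 0.134 summed over the four
states. `eel` carries the largest taxon-specific share (its tsRCFV of
0.049 is ~37% of the total — it is A-rich where the others are not), and
state A contributes 36% of the heterogeneity. nRCFV rescales the total so
it can be compared against genes of other lengths; here the two cells
containing `-` and `?` were simply excluded from the affected taxa's
frequency denominators.

Command-line equivalent (writes `summary.tsv`, `taxa.tsv`, `states.tsv`
and a JSON mirror):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "nrcfv", package = "nrcfv"))') \
    compute --input four_taxa.fasta --out report/
```

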