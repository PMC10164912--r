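# glycoPSSM

Position-specific scoring matrices for predicting O-GlcNAc glycosylation
sites.

O-GlcNAc transferase (OGT) is the single enzyme that attaches
N-acetylglucosamine to serine/threonine hydroxyls of nuclear and
cytoplasmic proteins, mostly inside intrinsically disordered regions
(IDRs). Its sequence specificity has resisted motif-style description:
substrates appear to be selected partly by an amino-acid *compositional*
bias over an extended region (~19 residues on each side of the modified
S/T), plausibly read out by OGT's tetratricopeptide-repeat superhelix
rather than by the catalytic site alone. glycoPSSM implements a predictor
built on that idea, together with the training procedure, the dataset
diagnostics used to characterize positive and negative peptide sets, and a
synthetic benchmark that makes the whole pipeline testable without any
external data.

## The model

A candidate site is an S/T-centered peptide window of odd length L
(default L = 39). A scoring matrix `M[a, j]` assigns a value to amino acid
`a` at offset `j ∈ {−(L−1)/2, …, −1, +1, …, +(L−1)/2}`; the center offset
is excluded, as are tryptophan and cysteine (too rare to train), giving an
18 × 38 table at the default length. A window `w` scores

```
S(w) = Σ_{j ≠ 0} M[w_j, j]
```

with W, C, unknown residues (X) and terminal padding contributing 0. A
site is called positive at a threshold `t` when `S(w) ≥ t`; the bundled
low/medium/high defaults are 123, 148, 160.

The matrix is trained by randomized hill climbing against the **matrix
assessment score (MAS)**. With `P`, `N` the medians and `Pstd`, `Nstd` the
sample standard deviations of the positive- and negative-set scores:

```
MAS = (P − Pstd − N − Nstd) / P
```

Each iteration perturbs one uniformly chosen matrix cell by ±step and
keeps the change iff MAS strictly increases. A `variant = "literal"`
objective (`+Nstd`) is available for comparison; the methods vignette
(`vignettes/methods.Rmd`) discusses both readings and the objective's
degenerate directions.

Because the positive training sets in the field are database-derived while
negative sets are scarce, the package also ships the diagnostics used to
characterize such datasets: positional amino-acid frequency matrices,
whole-set compositional-bias tests (exact binomial upper tail against a
background composition, computed in log space), confusion-matrix
evaluation against known site lists, and a Pearson utility for comparing
predicted site counts with observed glycosylation stoichiometries.

## Worked example

Train on synthetic peptide sets with a planted compositional bias
(positive-like windows enriched in A/V/T/I/L/M/P, depleted in
G/Q/N/D/E/R; negative-like reversed), then inspect what was learned:

```r
library(glycoPSSM)

specs <- planted_specs()                       # +50% relative enrichment
pos <- generate_set(specs$positive, 200, 39, seed = 1, label = "positive")
neg <- generate_set(specs$negative, 200, 39, seed = 2, label = "negative")

fit <- optimize_matrix(pos, neg,
                       optimizer_config(seed = 3, iterations = 20000,
                                        report_every = 500))
fit
#> <matrix_optimization> 20000 iterations, 1619 accepted
#>   MAS: -0.2123127 -> 873.5013

mas(score_set(fit$matrix, pos), score_set(fit$matrix, neg))
#> <mas_report> MAS = 873.5013 (gap)
#>   P = 0.02239807 (sd 4.377803), N = -28.62926 (sd 4.709115)
```

The positive and negative score distributions end up separated by about
six standard deviations. The learned per-residue direction (mean learned
matrix row, centered) recovers the planted bias — all seven enriched
residues come out positive, all six depleted residues negative:

```r
learned <- fit$matrix - fit$initial_matrix
round(sort(rowMeans(learned) - mean(learned)), 2)
#>     N     E     D     G     R     Q     F     S     Y     K     H     L     A
#> -1.49 -1.09 -0.99 -0.96 -0.91 -0.64 -0.33 -0.14 -0.01  0.22  0.33  0.49  0.67
#>     M     V     I     T     P
#>  0.75  0.75  0.96  1.04  1.36
```

Prediction on a protein record then works site by site (here with
thresholds on the synthetic score scale; use the defaults 123/148/160
with a matrix trained to that scale):

```r
p <- protein_record("demo", paste0(strrep("AVTILMP", 4), "S",
                                   strrep("AVTILMP", 4)))
predict_sites(fit$matrix, p, prediction_thresholds(-10, 0, 10))[1:3, ]
#>   parent_id center_position center_residue    score call_low call_medium call_high
#> 1      demo               3              T 13.12718     TRUE        TRUE      TRUE
#> 2      demo              10              T 16.51848     TRUE        TRUE      TRUE
#> 3      demo              17              T 19.53785     TRUE        TRUE      TRUE
```

Real-data workflows start from FASTA (`read_fasta()`, `slice_region()`),
known-site lists (`windows_from_site_list()`), published point-mutation
lists (`parse_mutations()`, `apply_mutations()`, `fus_mutation_sets()`)
and the bundled region registry (`fixture_regions()`, which records
accessions and residue spans — e.g. TAF15 1–210, CFTR 654–838, DDX4
1–236, FMRP 445–632, SARA 766–822 for the experimentally verified
negative set — and accepts user-supplied sequences via
`registry_sequences()`).

## Command line

A thin wrapper (`inst/exec/glycopssm`) exposes the same pipeline as
subcommands:

```sh
glycopssm simulate --preset positive --n 500 --seed 1 --out pos.tsv
glycopssm simulate --preset negative --n 500 --seed 2 --out neg.tsv
glycopssm train --pos pos.tsv --neg neg.tsv --seed 3 \
    --iterations 50000 --out-matrix matrix.tsv --out-trajectory traj.tsv
glycopssm predict matrix.tsv proteins.fasta --out predictions.tsv
glycopssm evaluate predictions.tsv known_sites.txt --level high
glycopssm stats pos.tsv --freq freq.tsv
glycopssm extract proteins.fasta --length 39 --out windows.tsv
```

Data outputs never contain timestamps; identical inputs and seeds give
byte-identical files.

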