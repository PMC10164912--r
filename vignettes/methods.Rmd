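---
title: "Methods: compositional scoring matrices for O-GlcNAc site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional scoring matrices for O-GlcNAc site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPSSM)
```

## The prediction problem

O-GlcNAc transferase (OGT) glycosylates serine and threonine residues of
intrinsically disordered protein regions with broad, poorly understood
specificity. Short-motif descriptions fail for most known substrates, and
negative training data are scarce: the absence of a site from a mass
spectrometry study is weak evidence that the site cannot be modified. The
modeling premise of this package is that a useful part of OGT specificity
is *compositional* — which amino acids surround a candidate site over an
extended window — rather than strictly positional. The predictor is
therefore a position-specific scoring matrix (PSSM) over a long window,
trained to separate known glycosylation sites from an experimentally
verified set of unglycosylated peptides, and most of its signal is
expected to be (and, in the bundled diagnostics, is measured as)
consistent across window positions.

## Windows and scoring

A candidate site is represented as an S/T-centered window of odd length
$L$. The default $L = 39$ (19 flanking residues per side) follows the
observation that compositional trends around real sites persist across
the longest windows examined and that some substrates need extended
regions for efficient glycosylation. Windows overlapping a terminus are
padded with `-` rather than discarded; consequently every S/T in a
sequence yields exactly one window, a property the test suite asserts for
arbitrary sequences.

The scoring matrix assigns a real value to each of 18 amino acids (the
canonical 20 minus W and C, judged too rare to estimate) at each non-center
offset, so the default table is $18 \times 38$. The window score is the
plain sum of matrix entries for the flanking residues. Four symbols score
exactly zero by construction: W and C (no matrix row), X (unknown
residue) and the pad `-`. X and `-` are kept distinct so that reports can
distinguish "unknown residue" from "no residue". The center residue is
never scored — the matrix has no offset-0 column — so any S-versus-T
preference can only be expressed through neighbors.

Thresholded calls use `score >= threshold`; the bundled low/medium/high
defaults are 123, 148 and 160 on the scale of the originally published
trained matrix. The comparison direction is a documented convention (the
boundary case is not specified by the underlying description).

## The training objective and its pathologies

Training maximizes the matrix assessment score. With $P$, $N$ the medians
and $P_{std}$, $N_{std}$ the sample (n−1) standard deviations of the
positive- and negative-set scores:

$$\mathrm{MAS} = \frac{P - P_{std} - N - N_{std}}{P}$$

This is the gap between the lower edge of the positive distribution and
the upper edge of the negative one, normalized by the positive median.
The source formula renders ambiguously (the sign of $N_{std}$ can be read
either way); we adopt the $-N_{std}$ form because rewarding a *wider*
negative distribution would contradict the stated goal of separating the
two sets. The literal $+N_{std}$ reading is implemented behind
`variant = "literal"` for comparison. Medians of even-length lists are
the mean of the middle two; a singleton list has standard deviation 0;
both conventions are asserted in tests.

The optimizer is deliberately minimal, matching the described procedure:
per iteration, one uniformly chosen cell is perturbed by $\pm$`step_size`
(equal probability) and the change is kept iff MAS strictly increases
(ties are rejected). A fixed iteration budget is the stopping rule. One
seeded generator drives initialization, cell choice and sign, so a seed
plus identical data reproduces the trained matrix bit for bit.

Two degeneracies of this objective matter in practice and shaped the
implementation:

1. **The all-zero start is absorbing.** From a zero matrix every window
   scores 0, so $P = 0$ and MAS is undefined; moreover a single-cell
   perturbation shifts only the handful of windows carrying that residue
   at that offset, which cannot move either median off zero. Under
   strict-improvement acceptance no move is ever accepted. The package
   therefore defaults to `init = "uniform"` — arbitrary positive starting
   scores drawn from $U(0, \texttt{init\_range})$, which keep $P > 0$ as
   the normalized objective requires — and retains `init = "zero"` only
   as an explicit null (a test asserts its zero-acceptance behavior).
   Proposals that would drive $P \le 0$ are treated as invalid and
   rejected.

2. **A gauge direction.** Adding a constant $c$ to every cell of one
   offset column shifts both score distributions identically (whenever
   that offset holds scorable residues), leaving the MAS *numerator*
   invariant while changing the denominator $P$. Hill climbing therefore
   drifts the whole matrix downward, shrinking $P$ toward $0^{+}$ and
   inflating MAS without adding any separation information. The
   separation content of a trained matrix lives in its column-centered
   component. For this reason the recovery benchmark (below) measures the
   learned direction on centered learned row means,
   `rowMeans(M - M0) - mean(M - M0)`, and users comparing trained
   matrices should do likewise. Absolute MAS values from long runs are
   large and scale-dependent; the score *medians* and held-out confusion
   metrics are the interpretable summaries.

Scores are maintained incrementally (a one-cell change only touches the
windows with that residue at that offset), so 50,000 iterations on
500-window sets run in seconds on one core.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `length` | 39 | window length, residues; odd, ≥ 3 |
| `iterations` | 100,000 | proposal steps (50,000 used in the benchmark) |
| `step_size` | 1 | cell perturbation magnitude (score units) |
| `init`, `init_range` | uniform, 1 | starting matrix: $U(0, 1)$ per cell |
| `variant` | gap | MAS reading ($-N_{std}$) |
| thresholds | 123/148/160 | low/medium/high call cutoffs (score units) |

Multiplying `init_range` and `step_size` by the same positive constant
scales the entire trained matrix by that constant and leaves MAS and the
acceptance sequence unchanged (asserted exactly in tests), so the
absolute scale of these two parameters is a unit choice, not a model
choice.

## The synthetic generator and what passing tests mean

`generate_set()` draws flanking residues i.i.d. from a 20-residue
composition spec and the center uniformly from {S, T}. `planted_specs()`
builds a positive-like spec with A, V, T, I, L, M, P multiplied by
$1 + e$ and G, Q, N, D, E, R by $1/(1 + e)$ (renormalized; default
$e = 0.5$, i.e. +50% relative), and a negative-like spec with the factors
swapped — the qualitative direction that separates real substrate
datasets from experimentally unglycosylated IDR peptides. The
i.i.d.-flank design is intentional: the planted signal is purely
compositional, so position-free generation is the correct null structure
for asking whether the trainer recovers a compositional bias. The +50%
magnitude is an artifact choice giving comfortable statistical power at
500 windows per set; it is configurable.

`recovery_benchmark()` runs the full pipeline at those conditions
(500 + 500 windows, $L = 39$, 50,000 iterations, step 1, uniform init)
and reports the fraction of the 13 planted residues whose centered
learned row mean has the planted sign, along with initial/final MAS and
the trained score medians. The acceptance suite requires sign agreement
≥ 80% and a strict MAS increase.

What passing does *not* show: real peptide data have positional structure
near the modification site (e.g. proline preferences at small offsets and
threonine runs C-terminal to the site), long-range correlations,
redundant overlapping windows, and database-composition artifacts; none
of these are emulated. The benchmark validates the optimizer and scoring
machinery, not biological accuracy. Conversely, real training sets are
small and biased — the experimentally verified negative sets available in
this field are on the order of a hundred peptides from a handful of IDRs
— so matrices retrained on real data should be interpreted with the
diagnostics (`positional_frequency()`, `compositional_bias()`) at hand.

## Dataset diagnostics

*Positional frequencies* count, per offset (including 0), each canonical
residue among non-pad, non-X occupants; columns with at least one
scorable residue sum to 1.

*Compositional bias* is the exact binomial upper tail: for residue $a$
with pooled count $k$ out of $n$ residues and background frequency $f_a$,
$p_{bias} = \Pr(X \ge k)$, $X \sim \mathrm{Bin}(n, f_a)$, computed via
`pbinom(..., log.p = TRUE)` so that magnitudes down to $10^{-264}$ and
below are exact (tests compare against direct summation at representable
scales, to $10^{-10}$ relative). Counts are pooled over region sequences
rather than overlapping windows, to avoid redundancy inflating the
counts. No windowed lowest-probability-subsequence search is performed
and no multiple-testing correction is applied — reported values are raw
single-residue tail probabilities, suitable for order-of-magnitude
comparison.

*Evaluation* is a confusion table over a protein's S/T positions
(predicted vs known positives; everything else a true negative), with
sensitivity, specificity, accuracy and precision kept as exact ratios and
additionally rounded to whole percent for display. Ratios with a zero
denominator are reported as `NA`, not 0.

## Numerical and interface conventions

- Coordinates are 1-based inclusive everywhere; mutation tokens
  ("G34A") and window centers use the parent protein's numbering when a
  record is a sliced region.
- Matrix TSV files carry one signed-offset header row and 18 rows in
  fixed alphabetical residue order; values are written at full double
  precision (`%.17g`) so write-then-read is the identity. Readers accept
  any row order and drop an offset-0 column with a warning.
- Degenerate inputs fail loudly and early: empty sequences, non-canonical
  residues other than X, even window lengths, non-S/T centers, mixed
  window lengths in a set, wild-type mismatches and duplicate positions
  in mutation lists, empty score vectors, $P = 0$ in `mas()`.
- Data outputs never embed timestamps; identical inputs and seeds give
  byte-identical files (asserted for the CLI).

## Problem sizes

The test suite trains on 60-window sets of length 9 for fast optimizer
checks, and runs the full 500 + 500 / $L=39$ / 50,000-iteration benchmark
(plus one convergence-robustness pair and one spec-swap pair at reduced
size) once; the whole suite completes in well under a minute on one core.
`scripts/acceptance.R` repeats the benchmark and a 500 + 500 held-out
evaluation from scratch at the seed given on the command line.

## Known limitations

- Retraining cannot be expected to reproduce any previously published
  matrix cell-for-cell: the published procedure's seed, step size and
  iteration count are unstated, and the objective's gauge direction means
  even equivalent classifiers can differ by large column offsets. Only
  the centered structure is comparable.
- The predictor is structure-agnostic: sites inside transiently folded
  segments will be over-called, since secondary structure that blocks
  glycosylation is invisible to a composition score.
- The bundled region registry records accessions and residue spans only;
  sequences must be supplied by the user, and the Lamin A isoform
  numbering used by published site tables is left unresolved.
- `pearson()` assumes approximately bivariate-normal inputs for its
  p-value; with the small construct counts it is typically applied to,
  treat p-values as descriptive.
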