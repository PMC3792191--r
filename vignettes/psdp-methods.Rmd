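---
title: "Position-specific dipeptide propensities for S-nitrosylation site prediction: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific dipeptide propensities for S-nitrosylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snopair)
```

## The model

`snopair` treats S-nitrosylation site prediction as peptide-window
classification. Each cysteine is represented by its 21-mer context
(flank length $\xi = 10$ on each side; termini padded with the dummy
residue `Z`, the 21st alphabet member). The statistical object at the core
is the pair of **position-specific dipeptide propensity matrices**:

$$Z^0_{ij} = F^+_0(D_i \mid j) - F^-_0(D_i \mid j), \qquad
  Z^1_{ij} = F^+_1(D_i \mid j) - F^-_1(D_i \mid j),$$

where $F^\pm_g(D_i \mid j)$ is the frequency with which ordered residue
pair $D_i$ ($i = 1,\dots,441$, lexicographic over the 21-letter alphabet)
starts at subsite $j$ in the positive / negative training windows, for
adjacent pairs ($g = 0$, 20 subsites) and next-nearest pairs ($g = 1$,
19 subsites). A window maps to the $\Omega = 20 + 19 = 39$ vector $\psi$
obtained by looking up, for each subsite, the propensity of the pair the
window actually carries there. Each class is summarized by its norm (mean
feature vector), and a query takes the label of the nearer norm in
Euclidean distance.

The model's assumptions are worth stating plainly. It assumes the
discriminative signal lives in *local, position-anchored pair composition*:
pairs are counted per subsite, so a motif shifted by two positions
contributes to different cells. It assumes training windows are i.i.d.
given class (each peptide counts once, with no weighting by parent
protein — proteins contributing many sites influence the matrices
proportionally). And because features are propensity lookups, positive-class
windows trend toward positive components; this sign structure is what makes
the nearest-norm rule meaningful.

### The decision-rule direction

One design question was genuinely open: with distances
$d_+ = \mathbb{D}(P, \mathbb{P}^+)$ and $d_- = \mathbb{D}(P, \mathbb{P}^-)$
defined as Euclidean distances to the class norms, the only decision rule
consistent with that geometry assigns SNO when $d_+ < d_-$ (nearest norm),
and that is the package default. The opposite, farther-from-norm direction
is preserved behind `rule = "literal"` in `predict()` purely for
auditability: on any dataset with real class signal it inverts every
non-tie call, and comparing the two directions is a quick sanity check that
a trained model's sign structure is as expected.

Exact ties $d_+ = d_-$ are resolved by a seeded uniform draw and flagged in
the output (`tie = TRUE`). Ties essentially occur only in degenerate models
(identical classes); the seed is a required, logged parameter so runs
reproduce bit-identically, and the draw is made on a local RNG stream so it
never perturbs the caller's random state.

## Tunable parameters

* `xi` (flank length, residues; default 10). All dimension arithmetic —
  441 × 20 and 441 × 19 matrices, $\Omega = 39$ — is derived from `xi`, so
  other odd window sizes work end to end; 10 is the default because it is
  the standard context size for this modification and what the benchmark
  protocol uses.
* `pseudocount` (default 0). By construction an unseen pair has frequency
  exactly 0; additive smoothing is exposed for experimentation but off by
  default, because the propensity *difference* already handles absent pairs
  gracefully (both classes contribute 0).
* `threshold` of the redundancy filter (identity fraction, default 0.40).
  Identity between two windows is the fraction of the 21 positions with
  identical residues — windows are fixed-length and center-aligned, so no
  gapped alignment is warranted. The filter is a greedy first-kept pass in
  input order, deterministic for a fixed input. Whether pad positions count
  toward identity is debatable; they do by default (a position is a
  position), and `count_pad = FALSE` excludes them.
* `k`, `repeats` of cross-validation (defaults 10 and 50). Folds are
  stratified by class by default; with the 1:1 class balance the protocol
  uses, stratification is nearly a no-op but protects against unlucky
  splits on small data. Per repeat, the k held-out folds' predictions are
  pooled into one confusion table before computing metrics — with balanced
  folds this coincides with per-fold averaging in expectation, and it is
  better behaved for MCC, whose per-fold values are unstable at small fold
  sizes. Per-repeat seeds are `seed + repeat − 1` and are logged in the
  result.
* `min_protein_length_warning` (default 50 residues). Whole-protein
  prediction warns — but proceeds — on shorter input, since fragments lack
  the flanking context the encoding expects.

## The synthetic benchmark generator

There is no redistributable training corpus in the package, so the
generator is the testbed for the whole pipeline. It emulates exactly the
statistical structure the encoding assumes: class-dependent,
position-specific residue composition over the 21-letter alphabet. Negative
windows draw every non-center position i.i.d. from a background
distribution (uniform by default; a natural-abundance preset exists);
positive windows are identical except at the biased positions (default
8, 9, 12, 13 — the two pairs flanking the central cysteine, so both the
adjacent-pair and the next-nearest-pair matrices see signal), where the
planted residue is emitted with probability
$e + (1 - e)\,b(\text{residue})$ for effect size $e$. At $e = 0$ the
classes are exchangeable (a null benchmark: cross-validated accuracy must
sit at 50 % within sampling error); at $e = 1$ they are fully separable.
Signal is planted marginally per position rather than directly on pairs:
this is simpler to specify and still induces pair-level signal at every
subsite overlapping a biased position.

Protein mode emits whole sequences with designated, well-separated
cysteines, a subset of them SNO sites whose flanking context follows the
positive rule; incidental background cysteines become unannotated non-SNO
sites, as in real whole-protein evaluation.

What the generator does *not* emulate: real SNO motif biology, residue
autocorrelation along the chain, homology between windows (every window is
independent), or the class imbalance of real proteomes. Passing tests
therefore demonstrate that the machinery is correct and that planted
position-specific signal of a given strength is recovered — not that any
particular accuracy will be achieved on biological data.

## Numerical and serialization choices

* Frequencies and propensities are double precision; raw counts are
  retained in `pair_freq` objects so exact rational recomputation is
  possible in tests.
* Metrics: the MCC is computed with the product of marginals in double
  precision (counts can be large; the product overflows integer range).
  With an empty marginal the MCC is reported as 0 with a
  `mcc_degenerate` flag — a common convention, made explicit. Sensitivity
  is `NA` (missing, not 0) when no positives were evaluated, likewise
  specificity, distinguishing "nothing to measure" from "all missed". The
  conventional and error-fraction formulations are implemented separately
  and agree to $10^{-13}$ over random confusion tables.
* Model files are JSON; numeric arrays are stored as `%.17g` strings
  because standard JSON number emission does not round-trip IEEE doubles
  bit-identically, and the package guarantees that a saved-and-reloaded
  model reproduces every prediction exactly (`save → load → save` is
  byte-identical).
* Non-standard FASTA letters (B, J, O, U, X) are rejected by default with
  a clear error; `map_nonstandard = TRUE` maps them to the pad symbol.
  Silent coercion would corrupt pair frequencies, so it is opt-in.
* Annotated SNO positions that do not fall on a cysteine raise an error
  rather than being guessed around (they usually indicate an isoform or
  coordinate mismatch the user must resolve).

## Problem sizes

The test suite and acceptance script run on synthetic data sized to make
their statistical assertions meaningful while staying quick: 400 windows
per class for signal-recovery checks (10-fold CV, 10 repeats; the null
band is ±3 standard errors of a binomial proportion at $n = 800$),
5,000 residues for the background goodness-of-fit test, 10,000 random
tables for the metric-equivalence bound, and ≤ 20-window datasets for the
brute-force oracle comparisons at $10^{-12}$.

## Known limitations

* The redundancy filter is a documented stand-in for whatever screening
  produced the published benchmark; greedy first-kept filtering at a 40 %
  positional identity threshold is deterministic and defensible but not a
  claim of equivalence to the original procedure.
* Nearest-norm classification is a linear, prototype-based rule; it cannot
  express interactions between subsites, and no probability calibration or
  threshold tuning is provided (distances are reported so users can rank).
* Pairs containing the pad symbol are tallied like any other pair, so for
  sites very close to a terminus the propensities partially encode
  "position relative to the terminus" rather than residue chemistry.
* Repeated cross-validation re-randomizes fold assignment only; it does not
  re-sample the negative pool, so its dispersion understates variability
  under negative-set re-selection.
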