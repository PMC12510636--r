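---
title: "Methods: profiling quinone/dehydrogenase co-conservation"
author: "respiromap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling quinone/dehydrogenase co-conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respiromap)
```

## The scientific question

Bacteria run aerobic respiration with one of two chemically distinct
quinone pools — low-potential naphthoquinones (NQ: menaquinone and its
relatives) or the high-potential benzoquinone ubiquinone (UQ) — and oxidise
NADH with either the proton-pumping complex-I-type dehydrogenase (NDH-1,
the *nuo* operon) or the non-pumping single-subunit NDH-2 (*ndh*). If the
quinone chemistry constrains which dehydrogenase is useful, the two traits
should co-occur non-randomly across genomes. `respiromap` implements the
comparative-genomics machinery to ask that question: build sensitive
profile models for marker genes of each pathway, search proteomes, call
pathway presence per species, and tabulate the quinone x dehydrogenase
joint distribution. Two ancillary computations used in the same line of
work are included: growth-rate and cumulative-cell-division bookkeeping for
adaptive laboratory evolution (ALE) trajectories with a monotone fitness
fit, and the binding-enthalpy difference used to compare protein-DNA
docking results.

## Marker panel and pathway calling

Thirteen representative genes stand in for five pathway variants:

| pathway variant | markers |
|---|---|
| classical NQ biosynthesis | menB, menC, menF |
| futalosine NQ biosynthesis | mqnA, mqnC, mqnD |
| UQ biosynthesis | ubiA, ubiC, ubiG |
| NDH-1 | nuoA, nuoE, nuoJ |
| NDH-2 | ndh |

A pathway variant is called present in a species when **all** of its
markers are found (`pathwayScheme("all")`). Three genes per variant were
chosen as joint evidence, so requiring all of them is the natural reading;
`at_least_k` is exposed for sensitivity analysis, and
`ruleSensitivitySweep()` recomputes the headline statistics under every
combination of presence rule, genome-to-species collapse rule and
denominator convention, so a reader can see how much the conclusions move
with the configuration. NQ presence is the union of the classical and
futalosine routes. The two headline statistics are the fraction of
NQ-pathway species that also carry NDH-2 (exclusively or together with
NDH-1), and the fraction of species in which NDH-2 coexists with UQ. The
denominator of the second is genuinely ambiguous in survey summaries; the
package defaults to all analysed species and always reports the NDH-2- and
UQ-conditioned versions alongside (`frac_ndh2_with_uq_by`).

## Profile HMMs

The search engine is a glocal profile hidden Markov model: the model is
traversed begin to end, while unmodelled sequence flanks are absorbed by
flanking states that emit the background composition. Match states carry
position-specific emission distributions; a shared insert distribution and
affine match/insert/delete transitions handle indels.

**Construction.** Alignment columns with gap fraction below 0.5 become
match states. Emissions are observed counts plus background-proportional
pseudocounts (weight 1 by default); transitions are observed state-path
counts plus a match-favouring prior (M->M 0.9, M->I and M->D 0.05 each).
Seed sets are first de-redundified by greedy clustering at 50% identity so
heavily sequenced taxa do not dominate the emission estimates.

**Scoring.** `forwardBits()` is the full forward log-odds in bits:
log2 of the sequence probability under the profile (summed over all
alignments) divided by the i.i.d. background probability.
`viterbiBits()` is the single-best-path analogue and also returns the
argmax alignment. The flank self-loop probability is length-calibrated to
n/(n+2) so that flank transit costs stay O(1) bits regardless of sequence
length. Scores are computed in probability space with per-row rescaling
(and a flush-to-zero floor 1e-280 below the row maximum, far beyond any
tolerance used); both algorithms are verified against exhaustive state-path
enumeration on all tiny profiles in the test suite, at 1e-9 relative
tolerance.

**E-values.** The null score distribution of each profile is estimated
from 2,000 random background-composition sequences and summarised by a
Gumbel fit; `E(S) = dbSize * P(score >= S)`. The fit is maximum likelihood
with method-of-moments initialisation, **tail-censored**: only the top 25%
of null scores enter as exact observations, the rest through the censoring
probability. This choice is deliberate: the bulk of a forward-score null is
narrower than a Gumbel, and a full-sample fit overestimates tail mass by
nearly an order of magnitude at the 1% level, whereas the censored fit is
calibration-consistent — among fresh null sequences the fraction with
`E <= x * dbSize` matches x within binomial error for x down to 0.01, which
the test suite checks at n = 2000.

**Filtering.** A hit is retained when its E-value is at or below the
gene-specific cutoff *and* its bit score is at or above 100 bits; both
thresholds are inclusive ("minimum bit score 100" reads as >= 100). The
default per-gene E-value cutoff is 1e-10; real per-gene cutoffs can be
loaded from a two-column table with `readThresholds()`. Profiles do not
compete: a sequence may satisfy two profiles (it is then reported for both,
with a warning), and only the best hit per (genome, gene) is kept.

## Synthetic data with planted truth

Because genuine proteome surveys are not reproducible at desk scale, every
stage is exercised on generated data whose ground truth is known exactly.

* **Families** (`generateFamily()`): a master sequence drawn from the
  Robinson-Robinson background, members mutated independently under a
  20-state Jukes-Cantor-like substitution model — `divergence` is the
  expected number of substitutions per site, replacement uniform over the
  other 19 residues — plus single-residue indels at a small per-site rate.
  Indels are recorded as they happen, so the exact alignment is returned
  with the sequences; at divergence 0.2 the expected residue identity to
  the master is 1/20 + (19/20) exp(-20 x 0.2/19) = 82%, and the test suite
  confirms the generated families match this closed form. Master lengths
  default to the typical lengths of the corresponding *E. coli* proteins
  (147 for nuoA up to 434 for ndh) so that bit scores have realistic
  magnitudes.
* **Proteomes** (`generateProteome()`): one planted member per present
  gene, drawn from the family but never the master itself, plus decoys
  that are residue shuffles of real members — identical amino-acid
  composition with no surviving homology, so any decoy hit is a genuine
  false positive of the scoring, not of the composition model.
* **Species sets** (`generateSpeciesSet()`): categories drawn i.i.d. from
  a frequency table. The default table plants 65% NQ species of which
  65.4% carry NDH-2, and NDH-2/UQ coexistence at 0.9% of all species,
  emulating the headline structure reported for real bacterial surveys;
  NQ species use the classical or futalosine route with equal probability.
  Phylogenetic correlation between species is deliberately *not* modelled:
  passing the recovery tests shows the pipeline machinery is correct, not
  that the biological signal in real data is phylogenetically independent.
* **Growth curves** (`generateGrowthCurve()`): exponential or logistic
  OD600 with multiplicative lognormal noise of stated CV (mean exactly 1).

All generators take one integer seed and touch no global RNG state;
identical seeds give byte-identical output.

## Growth kinetics and ALE trajectories

`growthRate()` is the classical rolling log-linear estimator: the maximum
least-squares slope of ln(OD - blank) over contiguous windows (default 5
readings). The default short window is appropriate for logistic-like
curves where only the early phase is log-linear. For curves that are
exponential throughout, the window should span the whole phase: the
max-over-windows statistic is an extreme-value statistic, and scanning
many short windows on noisy data reports the largest noise-inflated slope
(at 5% multiplicative noise and 10-minute sampling the bias approaches
+20% for 5-point windows). The parameter-recovery checks therefore use a
full-series window, where the mean bias across 100 noisy curves is well
under 2%.

Cumulative cell divisions use standard ALE bookkeeping: divisions per
passage are net new cells (final minus inoculum), accumulated across
passages; cell numbers come either from direct counts or from OD x volume
x a cells-per-OD conversion (default 8e8 cells OD^-1 mL^-1, configurable —
only the product matters for the trajectory shape). The fitness-versus-CCD
curve is fitted by isotonic regression followed by a monotone
piecewise-cubic Hermite interpolant (PCHIP with Fritsch-Butland slope
limiting, written in the package after the stock R monotone spline was
found to violate monotonicity by ~1e-6 on flat-after-rise knot patterns).
The isotonic projection means locally decreasing noise flattens rather
than bends the curve; the result is continuously differentiable and
non-decreasing everywhere, which the tests verify on 1000-point grids.

## Docking energetics

`deltaH()` is the plain enthalpy balance `E_complex - (E_protein +
E_DNA)`, unit-agnostic, exact in double precision. `compareVariants()`
pairs each variant record with its wild-type counterpart per DNA box and
reports `ddH = deltaH(variant) - deltaH(WT)` with a qualitative call; more
negative deltaH is read as more favourable binding (the standard
convention). `ddH` is antisymmetric under swapping which label is the
reference and invariant under shifting all component energies of a box by
a constant — both tested exactly. Producing the component energies
(docking, structure modelling) is out of scope; the module consumes a CSV.

## Numerical choices and degenerate inputs

* Identity for clustering = identical aligned pairs / shorter sequence
  length, from one optimal BLOSUM62 global alignment (gap open 11,
  extend 1) — the CD-HIT convention. Greedy order is longest-first with
  id as tie-break, so clustering is deterministic.
* Zero-pseudocount profiles can assign zero probability; scores are then
  -Inf rather than an error. With the default pseudocount all scores are
  finite.
* `X` residues are scored as background (odds 1); other non-standard
  letters are an input error.
* E-values saturate at `dbSize` far below the Gumbel location; survival
  probabilities are computed with `expm1` so small E-values keep full
  relative precision.
* Empty proteomes yield an all-false presence row, not an error; an empty
  co-occurrence input is an error (no denominator exists).
* Ties in spline abscissae are averaged before fitting; fewer than three
  distinct points are rejected.

## Problem sizes used in validation

The shipped validation suite runs entirely on generated data: tiny-profile
oracle comparisons (200 profile x sequence cases, L <= 3, length <= 4,
exhaustive enumeration), a survey-scale presence sheet of 7,783 species for
the tabulation stages, and a full sequence-level pipeline of 500 species x
13 markers with 20 shuffled decoys per genome and 2,000-sequence E-value
calibration per profile. These sizes keep the full suite under a few
minutes on one CPU while leaving the binomial error of the recovered
fractions (about +-2 percentage points at 3 SD) well inside the planted
signal.

## Known limitations

* Species categories are i.i.d.; no phylogenetic structure, so the
  generator cannot probe tree-aware co-occurrence tests (explicitly out of
  scope).
* The profile HMM is glocal only — no local/uni-hit mode, no domain
  envelopes, no acceleration filters; profiles and scores are therefore
  not numerically interchangeable with HMMER3 output, though the profile
  text format is convertible.
* The genome-to-species collapse rule for real multi-genome species is a
  configuration axis (`any`/`majority`/`all`), not a recommendation: the
  right choice depends on how the genome set was assembled.
* Docking energies are consumed, never produced; units follow the input.
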