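# respiromap

Comparative-genomics tooling for a specific question in bacterial
bioenergetics: do respiratory quinone chemistry and NADH dehydrogenase
type travel together across species? Bacteria use either low-potential
naphthoquinones (NQ — menaquinone, made via the classical *men* or the
futalosine *mqn* route) or high-potential ubiquinone (UQ, *ubi* genes),
and oxidise NADH with either the proton-pumping NDH-1 (*nuo* operon) or
the non-pumping NDH-2 (*ndh*). `respiromap` implements the whole
co-conservation pipeline — seed-set clustering, profile-HMM construction
and scoring, E-value calibration, marker-panel search, pathway calling and
quinone-by-dehydrogenase tabulation — together with growth-kinetics
utilities for adaptive laboratory evolution (ALE) trajectories and a
binding-enthalpy comparison for protein–DNA docking tables. A synthetic
data generator with planted ground truth makes every stage testable
offline.

## The core machinery

**Profile HMMs.** For each of 13 marker genes (menB menC menF / mqnA mqnC
mqnD / ubiA ubiC ubiG / nuoA nuoE nuoJ / ndh) a glocal profile HMM is
built from an alignment whose seed set has been de-redundified by greedy
clustering at 50% identity. Sequences are scored in bits,

> bits = log2 [ P(sequence | profile) / P(sequence | background) ],

by the full forward algorithm (`forwardBits()`; `viterbiBits()` gives the
best single alignment). Each profile's null score distribution is
summarised by a tail-censored Gumbel fit, giving
E(S) = dbSize · P(score ≥ S). A hit is kept when E ≤ the gene's cutoff
(default 1e-10) **and** bit score ≥ 100; only the best hit per
(genome, gene) counts. Species-level presence (collapse rule `any` /
`majority` / `all`) feeds pathway calls — a pathway variant needs all of
its markers by default — and the calls are tabulated into a 4 × 4
quinone-category × dehydrogenase-category table with the two headline
fractions: NQ species that carry NDH-2, and species where NDH-2 coexists
with UQ.

**Growth kinetics.** `growthRate()` is the rolling log-linear μ_max
estimator on ln(OD600 − blank); `cumulativeCellDivisions()` accumulates
net new cells per passage (ODs convert at 8e8 cells·OD⁻¹·mL⁻¹ by
default); `fitMonotoneSpline()` fits a smooth monotone cubic
(isotonic projection + Fritsch–Butland PCHIP) to fitness versus
cumulative divisions, and `aleTrajectory()` bundles the three.

**Energetics.** `deltaH()` computes
ΔH = E_complex − (E_protein + E_DNA) and `compareVariants()` reports
ΔΔH = ΔH(variant) − ΔH(WT) per DNA box with a stronger/weaker/unchanged
call (more negative = more favourable).

## Worked example

Run the whole pipeline on 100 synthetic species with planted category
frequencies (the defaults plant 65.4% NDH-2 among NQ species and 0.9%
NDH-2/UQ coexistence):

```r
library(respiromap)
res <- runCoconservationPipeline(nSpecies = 100, nRandom = 500, seed = 42)
res$table
#> Co-occurrence across 100 species
#>          dehydrogenase
#> quinone   NDH1-only NDH2-only both neither
#>   NQ-only        22        23   24       0
#>   UQ-only        23         1    1       3
#>   both            0         0    0       0
#>   neither         2         0    0       1
#> NQ species with NDH-2: 68.1% (of 69 NQ species)
#> NDH-2 coexisting with UQ: 2.0% (denominator: all)
res$gene_accuracy
#> [1] 1
```

Every one of the 1,300 species × gene presence calls matches the planted
truth, and the recovered 68.1% sits within binomial error of the planted
65.4% at this sample size. The pieces compose individually too:

```r
fam <- generateFamily("menB", masterLength = 285, nMembers = 20,
                      divergence = 0.2, seed = 1)
clusterAtIdentity(fam$members, threshold = 0.5)
#> SeqClustering: 20 sequences in 1 clusters (threshold 0.50)

gc <- generateGrowthCurve("exponential", mu = 0.6, od0 = 0.02)
growthRate(gc)
#> mu_max = 0.6000 / h  (window 9.00-9.67 h, R^2 = 1.000)
```

A 20-member family at divergence 0.2 stays one cluster at the 50%
threshold (pairwise identities are ≈ 82%), and a noise-free exponential
returns its generating rate exactly.

Real inputs slot in at the same interfaces: per-genome FASTA with
`genomeID|speciesID|label` headers (`searchGenomes()`), per-gene E-value
cutoff tables (`readThresholds()`), per-genome search-result sheets —
wide presence or long scored-hit layout — via `recomputeFromSheet()`,
plate-reader CSVs (`growthRate()`), and docking-energy CSVs
(`readDockingEnergies()`).

## Documentation

The methods vignette (`vignettes/respiromap-methods.Rmd`) describes the
model and its assumptions, the synthetic-data design, the numerical
choices (tail-censored Gumbel calibration, flank length calibration,
PCHIP slope limiting) and known limitations.
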