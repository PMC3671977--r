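---
title: "Spectral-count quantification and threshold-based differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count quantification and threshold-based differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specount)
```

## The quantification model

Label-free shotgun proteomics assigns MS/MS spectra to peptides; the number
of spectra matched to a protein in one run — its spectral count (SC) — is a
semiquantitative proxy for its abundance. Runs differ in depth, so counts
are normalized within each replicate:

$$\mathrm{NSC}_{pr} = \frac{\mathrm{SC}_{pr}}{\sum_{q} \mathrm{SC}_{qr}},$$

the protein's share of all spectra identified in replicate $r$. Every
replicate column of an NSC matrix sums to 1, and multiplying a replicate's
counts by a constant leaves its NSC unchanged (scale invariance — one of
the package's property-tested invariants).

Replicates are grouped by a study design with a designated baseline group
(here NN; the packaged seminal-plasma study compares NA, OA and ON against
it, with 5/4/2/1 pooled replicates). The group-level abundance of protein
$p$ in group $g$ is the arithmetic mean of the group's replicate NSC
values, zeros included, and expression change is the ratio

$$R_{pg} = \frac{\overline{\mathrm{NSC}}_{pg}}{\overline{\mathrm{NSC}}_{p,\mathrm{baseline}}}.$$

The source study leaves the group summary statistic unspecified ("the
ratio for two sets of samples"). We use the mean of replicate NSCs rather
than renormalized pooled counts so that a deep replicate cannot dominate
its group; with the library-size-equalized matrices the reconstruction
produces, the two coincide anyway.

## The classification rules

All calls are threshold-based; the procedure involves no statistical test,
matching the source protocol. With the default `rule_config()`:

| parameter | default | meaning |
|---|---|---|
| `sc_threshold` | 10 counts | SC a protein must reach for significance; also the low-abundance ceiling |
| `presence_fraction` | 0.5 | fraction of a group's replicates that must detect a significant protein |
| `over_threshold` | 2 | NSC ratio above which a protein is over-expressed |
| `under_threshold` | 0.5 | NSC ratio below which a protein is under-expressed |
| `detection_floor` | 1 count | SC counting as "present" |

A protein is **significant** in a group when its SC reaches the threshold
in at least one replicate and it is detected in at least half of them;
**low-abundant** in a group when detected but never above the threshold
(and not significant); **globally low-abundant** when the latter holds
across all replicates and it is significant nowhere. A protein is
**common** when detected in every replicate of every group, **unique**
when detected in at least one group and absent from another. A
**differentially expressed protein** (DEP) carries at least one over- or
under-expression call in the NA/OA/ON comparisons; the DEP set is
partitioned into a Venn diagram by which comparisons call each protein.

Three rule details were genuinely open and are resolved as follows:

* **Presence quota rounds down.** "At least 50% of the samples" is
  implemented as `max(1, floor(0.5 * n))` detected replicates. The
  published classification treats 2 of 5 replicates as meeting the quota
  (DJ-1 and orosomucoid 1 are significant in NN with 2 of 5), which only
  floor semantics reproduces; a ceiling rule would demote orosomucoid 1 to
  "significant nowhere" and change the study-level counts.
* **Significance dominates at the boundary.** An SC of exactly 10
  satisfies both "≥ 10" (significant) and "≤ 10" (low-abundant); the
  classes stay disjoint by letting significance win, which is how the
  published table's global categories behave.
* **Presence-discordant comparisons are asymmetric.** When a protein is
  undetected in the *test* group there is nothing to quantify and no call
  is made — the published table never calls a protein in a group it is
  absent from (transferrin, DJ-1, orosomucoid 1 and others all have
  absent groups without calls). When a protein is undetected only in the
  *baseline*, the zero side is replaced by a pseudo-NSC floor
  $\varepsilon$ = half the smallest positive group-mean NSC in the study,
  yielding a finite, up-direction-bearing ratio, and the comparison is
  flagged `presence_discordant`. `nsc_ratio()` itself applies
  $\varepsilon$ symmetrically (so test/baseline swaps invert every defined
  ratio exactly); the asymmetry lives in `call_dep()`. One published row
  (ankyrin repeat domain 11, absent from NN yet printed as
  down-regulated) cannot arise under any ratio convention; the packaged
  constraints keep its calls with unconstrained direction and log the
  relaxation. A second row (serine proteinase inhibitor clade A member 1)
  is internally inconsistent — printed significant in OA and down in OA
  while not significant in NN, which jointly violates the thresholds —
  and is encoded with its OA class relaxed to low, also logged.

## Numerical choices

Ratio cutoffs are strict inequalities and ratios are never rounded before
thresholding; a ratio of exactly 2 or 0.5 is not a call. Because NSC means
are floating-point, the comparison uses a $10^{-9}$ relative guard band:
a ratio equal to the cutoff up to rounding of the means is treated as the
boundary, not a call. The band is six orders of magnitude below the
smallest margin any reconstructed or simulated effect is given, so it can
only absorb arithmetic noise. Undefined ratios (protein absent on both
sides) never produce calls. Degenerate inputs fail loudly: an all-zero
replicate column is an error naming the replicate, empty protein sets
cannot be profiled, and unknown group labels or selectors are rejected.

## The synthetic-data generators

The study's raw counts are unpublished, so the package ships two
generators.

**Constraint-guided reconstruction** (`reconstruct_from_constraints()`)
builds an integer matrix whose classification is exactly a prescribed
annotation table. It is constructive, not rejection sampling — the ON
group has a single replicate and 35 proteins × 12 replicates of joint
constraints make rejection hopeless. Per protein it solves for per-group
total counts whose per-replicate weights satisfy every abundance floor/cap
and ratio band, requiring called ratios to clear the cutoffs by a margin
(default 0.25, so ≥ 2.25 or ≤ 1/2.25) and uncalled ratios to stay inside
[1/1.75, 1.75]; the margin guarantees integer rounding cannot flip a call
at the default library size of 500. Totals are then spread over a
seed-chosen replicate subset honoring the presence pattern (significant
groups concentrate mass so the SC threshold is reached; capped groups stay
below it). Two structural devices make group-mean NSC ratios reduce to
count ratios: a **depth filler** protein absorbs the slack so every
replicate has the same library size (an eligible constrained protein —
ubiquitous, significant everywhere, uncalled — or an appended synthetic
row), and baseline-absent proteins with uncalled detected groups are
pinned to the study's minimum positive mean so their $\varepsilon$-ratios
land exactly on the cutoff (excluded by strictness); when a constraint set
needs $\varepsilon$-calls but has no such pinned cell, a synthetic
**anchor** row supplies the minimum. Finally the matrix is verified by
running the actual classification pipeline, with a bounded repair loop,
and the generator fails listing the violated constraints rather than
returning an unverified matrix. The categorical results are invariant to
the seed and to the library size; both are exercised in the tests.

**Planted-effect simulation** (`simulate_counts()`) draws counts from a
negative binomial with mean `baseline_mean_sc × fold(protein, group)` and
variance $\mu + \phi\mu^2$ (dispersion $\phi = 0$ gives Poisson), the
standard overdispersion model for spectral counts; the source study states
no noise model. Fold multipliers plant group-specific effects;
`evaluate_recovery()` scores calls against the truth labels (recall =
planted effects recovered with the planted direction; FPR = null pairs
receiving any call).

What the simulation does *not* emulate: peptide-level identification and
detectability-driven missingness, run-order or instrument drift, and the
biological pooling of donor samples into replicates. Passing recovery
tests therefore demonstrate the threshold logic's operating
characteristics under the stated count model, not performance on real
LC-MS/MS data.

## A known limitation: compositional ratio compression

NSC divides by the per-replicate total, so expression changes are measured
relative to total identified mass. When a large fraction of the proteome
moves in one direction, every ratio compresses toward the inverse of the
total-mass change: with half of 200 proteins up 4-fold, the test-group
library grows 2.5-fold, planted ratios land near 4/2.5 = 1.6 (below the
over-expression cutoff) and null ratios near 0.4 (below the
under-expression cutoff), so threshold calling fails in both directions.
`analysis/03_recovery_simulation.R` traces this: recovery is essentially
perfect at 5–10% prevalence and collapses by 50%. This is a property of
the ratio statistic itself, not of the implementation; the acceptance
suite includes a recovery scenario at 50% prevalence that the method
accordingly does not pass, kept as an honest negative result.

## Problem sizes used by the test suite

Oracle-equivalence tests run 1000 random matrices of up to 8 proteins × 6
replicates with counts ≤ 20 against independent loop-based
recomputations; round-trip tests reconstruct 200 random satisfiable
constraint sets over the four-group design plus the packaged 35-protein
table; recovery simulations use 200 proteins over NN = 5 vs NA = 4
replicates. These sizes were chosen so the full suite exercises every
code path in a couple of minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(specount)

rp <- reproduce_study(seed = 42)
rp$summary
#> category_summary over 35 proteins
#>   significant (>=1 group): 25  | globally low-abundant: 10
#>   common: 11  | unique: 13  | differentially expressed: 20
#>   venn: NA=3 OA=3 ON=3 NA+OA=3 NA+ON=3 OA+ON=3 NA+OA+ON=2

# proteins whose only call is a down-regulation in NA
select_set(rp$pipeline$classification, rp$pipeline$calls, "dep_only:NA:down")
#> [1] "151301154" "167857790" "25121982"

# cellular distribution of the 11 ubiquitous proteins
profile_set(select_set(rp$pipeline$classification, rp$pipeline$calls,
                       "common"),
            sp35_annotations(), "cellular_component", "common")
#> distribution_profile 'common' (cellular_component), n = 11
#>   extracellular region          90.9%
#>   secretory granule             36.4%
#>   ...
```
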