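---
title: "Methods: cross-species and within-family pharmacology with orthopharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species and within-family pharmacology with orthopharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When a drug-discovery program moves from human cell assays to rat models, it
implicitly assumes that a compound binds the rat ortholog of its target about
as tightly as the human protein. Within one genome, the mirror question is
selectivity: how much does binding differ between recently duplicated
paralogs, and how does that relate to how far their sequences have diverged?
`orthopharm` implements a complete, testable pipeline for both questions on
heterogeneous literature bioactivity data.

The pipeline has six stages:

1. **Harmonization.** Literature activities arrive as Ki, IC50, EC50, pA2 or
   pKi. Concentration results are converted to molar and transformed as
   `pKi = -log10(value_in_M)`; pA2 and pKi, already on a negative log scale,
   pass through unchanged. Only in vitro binding assays (assay type code `B`)
   with unambiguous target mapping are used.
2. **Pairing.** For every homologous target pair (human–rat ortholog or
   human paralog pair) and every compound measured on both members, the
   signed difference Δ = pKi(member a) − pKi(member b) is computed, after
   taking the per-side median when a compound has several measurements.
   Ortholog pairs are oriented human-first, so Δ > 0 means the compound
   prefers the human protein.
3. **The inter-assay null.** Two assays of the same compound on the same
   target rarely agree exactly; the distribution of such inter-assay
   differences is the natural null for deciding whether a between-species
   difference is real. The control is a composite of 1,500 randomly drawn
   human and 1,500 rat inter-assay differences, sized to match a typical
   ortholog comparison set.
4. **The screen.** Each target pair's Δ distribution is compared with the
   control by a two-sided Mann–Whitney U test; p-values are
   Bonferroni-multiplied by the number of pairs actually tested, and pairs
   with adjusted p < 0.05 are flagged as candidate species-specific
   pharmacology.
5. **Sequence context.** Divergence in binding is related to sequence
   identity at three resolutions — full sequence, the binding-site-containing
   Pfam domain, and the binding-site residues — by Spearman correlation and
   by 20-percent-wide identity bins.
6. **Chemotypes.** Ligands are clustered into chemical series (chemotypes)
   with LINGO q-gram fingerprints and complete-linkage clustering at a
   Tanimoto cutoff of 0.75, so that species effects can be attributed to
   particular scaffolds.

## Statistical models and their assumptions

**Laplace description of difference distributions.** Both ortholog and
paralog Δ distributions are heavy-tailed and sharply peaked at zero; a
Laplace (double-exponential) distribution describes them well, and the
package fits it by maximum likelihood in closed form: location = median,
scale `b` = mean absolute deviation from the median (`fit_laplace()`).
The scale is the single interpretable spread parameter: doubling `b` doubles
the typical log-unit disagreement. Published analyses of this kind have
reported the two scales with an assignment (orthologs vs paralogs) that
conflicts with their own variance test; `orthopharm` therefore always
computes and reports both fitted scales side by side and leaves the
interpretation to the analyst.

**The Mann–Whitney screen.** The U test compares each pair's Δ sample
against the composite control without distributional assumptions. It is
two-sided (a rat-preferring pair is as interesting as a human-preferring
one), and the whole screen is invariant to a global sign flip of all
differences. The Bonferroni divisor is the number of pairs actually tested —
pairs with fewer than `min_n = 5` compounds are excluded first — which is
the set of hypotheses genuinely examined. The default floor of 5 keeps
single-compound anecdotes out while still admitting small but consistent
pairs.

**Identity bins.** Bins are half-open `[lo, hi)` with the last bin closed,
`[80, 100]`, so 100% identity is representable and a value exactly at an
interior edge belongs to the bin above it. Adjacent occupied bins are
compared by two-sided Mann–Whitney tests with Holm adjustment; stars mark
0.05/0.01/0.001. Holm was chosen over further Bonferroni because the
adjacent-bin family is small and ordered.

**Molecular-weight analysis.** Compounds are split into five equal-count
(adaptive) bins of molecular weight; values equal to an interior quantile
edge go to the lower bin, and assignment is monotone in weight. A one-way
ANOVA F test across bins is followed by Tukey HSD comparisons restricted to
neighbouring bins (a pairwise-Welch-plus-Holm alternative is available
behind `method = "welch_holm"`). The hypothesis under examination is that
larger ligands, which depend on more protein contacts, are more likely to
"sample" a substitution near the binding site and hence diverge more.

## The binding-site-to-domain heuristic

Most pharmacological targets carry a single annotated Pfam domain, for which
the binding site can safely be assumed to lie within that domain. Those
targets seed a frequency dictionary (`build_domain_dictionary()`), counting
each accession once per single-domain target; multiple copies of one
accession in one target still count as a single-domain architecture.
Multi-domain targets are then mapped (`map_binding_site()`): one dictionary
hit maps directly; two or more hits map to the hit with the highest
dictionary count; no hit leaves the target unmapped. An exact count tie is
resolved to the lexicographically smallest accession and tagged, a case the
source heuristic never had to define; tagging keeps the arbitrary choice
visible downstream.

## LINGO fingerprints and chemotype clustering

A LINGO fingerprint is the multiset of all length-4 substrings of a SMILES
string after ring-closure digits are normalized to `0` (digits inside
square-bracket atom expressions are isotopes, H counts or charges and are
left alone). Strings shorter than 4 characters contribute themselves as a
single gram. The default similarity is the integral multiset form

Tc(A, B) = (1/ℓ) Σᵢ (1 − |Nᴬᵢ − Nᴮᵢ| / (Nᴬᵢ + Nᴮᵢ)),

summed over the ℓ distinct grams present in either molecule; a set-based
Tanimoto (`mode = "set"`) is provided for sensitivity analysis because the
descriptor literature uses both. No SMILES canonicalization is performed in
core: database exports are assumed pre-canonicalized, and silently
re-writing structures would make fingerprints irreproducible against the
source export.

Chemotypes are complete-linkage clusters cut at distance `1 − 0.75`: every
pair of compounds inside a chemotype has Tc ≥ 0.75. The agglomeration is
implemented with an explicit deterministic tie-break — at equal merge
heights, the pair of clusters with the smallest original compound indices
merges first — which makes the partition invariant to input order, a
property generic dendrogram implementations do not guarantee. The generic
implementation (`stats::hclust` + `cutree`) serves as an independent oracle
in the test suite, never as the implementation.

## The inter-assay control in detail

Within one species, for every (compound, target) measured in at least two
distinct assays, replicates are first averaged within each assay. With
exactly two assays the difference of the assay means is taken, ordered by
assay identifier — the sign of an inter-assay difference is arbitrary, and
an explicit ordering makes it reproducible; the screen is two-sided, so the
convention cannot affect any conclusion. With more than two assays the
per-assay means are split into two groups and the group averages
differenced. How exactly the groups are formed is genuinely open; the
package implements a seeded random bipartition as the default and a
deterministic first-vs-rest mode behind `grouping = "first_vs_rest"`. The
composite control then draws `n_per_species = 1500` values per species,
without replacement when the pool allows, with replacement (and a provenance
note) otherwise.

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions; its defaults are not tuning
knobs:

| Parameter | Default | Meaning |
|---|---|---|
| true affinity prior | Uniform(4, 12) pKi | the observed affinity range of literature binding data |
| `noise_scale` | 0.45 log units | Laplace scale of the difference between two replicate assays; each observation gets Laplace(0, 0.225) noise |
| `ortholog_identity` | mean 0.90, sd 0.05 | ortholog identities peak near 90% |
| `paralog_identity` | mean 0.45, sd 0.15 | paralog identities sit broadly mid-range |
| `paralog_divergence` | 1.5 | slope linking (1 − identity) to the Laplace scale of paralog binding offsets |
| `assay_replication` | (0.5, 0.3, 0.2) | probabilities of 1, 2, 3 assays per compound–target |
| `n_chemotypes_per_target` | 3 | scaffolds per pair |

Inter-assay noise is Laplace rather than Gaussian because real difference
distributions of this kind are demonstrably non-normal and well described by
a double exponential. Sequence pairs are realized by actually mutating a
random protein at `round((1 − identity) · L)` positions, so the identity
computed from the emitted alignment matches the drawn value to within
rounding. Chemotypes are built as a shared scaffold (24 characters, mutually
dissimilar between chemotypes by rejection at Tc < 0.3) plus a 0–2 character
decoration, which guarantees within-chemotype Tc above the 0.75 cutoff and
between-chemotype Tc well below it — so exact chemotype recovery by the
clusterer is a construction property the tests can assert.

What the generator does **not** model: the target-class composition of real
databases (GPCR and kinase over-representation), assay-quality covariates,
chemically valid SMILES beyond LINGO computability, and correlated
measurement error between laboratories. Passing tests therefore demonstrate
that the machinery is correct and well calibrated under the stated noise
model, not that real databases are free of structured artifacts — the
misannotation filters (exclusion lists) exist precisely because they are
not.

A positive `mw_effect_rho` scales paralog offsets by a monotone power of the
molecular-weight rank; the exponent is calibrated against the requested
Spearman correlation on the generated sample itself, so the planted effect
is expressed in the same units the analysis measures.

## Numerical choices and degenerate inputs

* pKi conversion rejects non-positive concentrations and unknown units
  rather than producing `NaN`; harmonized values outside [0, 15] warn but
  are kept (the plausible range is wide, and the filter should not silently
  censor).
* Duplicate removal collapses rows identical on (compound, target, assay,
  pKi rounded to 2 decimals): coarse enough to absorb re-published values,
  fine enough to keep genuine replicates. The rounding width is
  configurable.
* Sequence identity is computed over overlap columns only (both residues
  non-gap); an alignment with no overlap columns is an error, not identity
  zero.
* The utility global aligner breaks dynamic-programming ties
  deterministically (diagonal, then up) so alignments are reproducible; it
  exists for the synthetic path, real analyses consume precomputed
  alignments.
* `fit_laplace()` on constant data (scale 0) errors instead of returning a
  degenerate distribution.
* Equal-count binning errors when quantile edges collapse (all-equal or
  massively tied data) rather than silently producing empty bins.
* All randomized steps (sign assignment, control sampling, >2-assay
  bipartitions, generation) take explicit seeds; a master seed is forked
  into named substreams (`substream_seed()`) so stages can be rerun
  independently with identical results.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script run entirely on synthetic data:
null calibration and power use 200 replicates of 30 pairs × 20 compounds
(power plants a 1.0 log-unit offset on a 50-compound pair); Laplace recovery
uses 10^4 draws at scales 0.5, 0.7 and 1.3; the identity–divergence analysis
uses 500 paralog pairs × 20 compounds; clustering is verified against an
independent complete-linkage oracle on molecules of up to 8 compounds and on
planted chemotype universes; the domain-mapping heuristic is verified
exhaustively over all ≤4-domain architectures on a 6-accession alphabet.
These sizes were chosen to give stable Monte-Carlo estimates (standard
errors a few percent or less) while keeping a full validation run in the
minutes range on one core.

## Known limitations

* IC50/EC50 values are pooled with Ki after the same log transform, without
  Cheng–Prusoff correction; a Ki-only analysis is available by restricting
  `permitted_types`.
* pA2 values pass through unshifted.
* Binding-site comparison requires pre-corresponded residue positions; the
  package does not build the family alignments that establish the
  correspondence.
* Chemotype counts depend on the SMILES export's canonicalization; absolute
  counts are not comparable across differently canonicalized sources.
* The domain heuristic is frequency-based, not structural; fused or
  repurposed domains will be mis-assigned and can only be caught downstream.
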