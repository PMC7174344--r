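---
title: "Timing myeloma evolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing myeloma evolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomm)
```

`chronomm` estimates *when* the landmark events of multiple myeloma
development happened — large chromosomal gains, and the emergence of the
most recent common ancestor (MRCA) of the sampled tumour — by combining
three statistical components: constrained mutational-signature fitting,
molecular time of copy-number gains, and a mixed-effects calibration of
the clock-like signature SBS5. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open. No empirical claim is made here that the
package's tests or acceptance script do not themselves compute.

## 1. Substitution classes and catalogs

Single-base substitutions are classified on the pyrimidine strand into
96 classes (six substitution types × 4×4 trinucleotide contexts) or
1536 classes (pentanucleotide context), ordered as in COSMIC v3
reference files so published signature TSVs load unchanged
(`read_signatures`). Purine-reference mutations are reverse-complemented
together with their flanking context. Contexts containing `N` are
excluded and counted. Collapsing the 1536-class catalog over the outer
flanks reproduces the 96-class catalog exactly (a tested invariant).

## 2. Signature fitting with sequential censoring

Exposures solve the non-negative least-squares problem
`min ‖S·x − y‖₂, x ≥ 0` on raw counts, rescaled so `Σx` equals the
catalog total — exposures stay in mutation units. The NNLS solver is a
Lawson–Hanson active-set implementation in compiled code (no suitable
solver ships with the pre-installed stack); tests compare it with an
exhaustive grid-search oracle.

Fitting all reference signatures to every sample lets signatures
"bleed" between samples. The censoring loop counteracts this:
repeatedly, the least-contributing non-protected signature (by current
exposure fraction; ties drop the alphabetically last name, for
determinism) is provisionally removed and the catalog refit. If the
cosine similarity between the observed catalog and the reconstruction
falls by less than the **threshold 0.01** relative to the current fit,
the removal becomes permanent; otherwise the signature is restored and
censoring stops. **SBS1 and SBS5 are never removed** — they are active
in essentially all human tissues and anchor the clock. Contributions
are re-ranked after every removal (the published description does not
say whether the ranking is refreshed; sequential re-evaluation is the
default and `reevaluate = FALSE` preserves the initial ranking).

Uncertainty: the catalog is resampled 1000× as
Multinomial(total, class fractions), the whole censoring loop re-run
per draw, and the 2.5th/97.5th percentiles reported. Coverage measured
on synthetic mixtures is ≈ 94% at 1000 draws; reducing draws to 200
costs ~2 points of coverage, so the defaults should be kept for
inference. Catalogs under 50 mutations are fit but flagged
low-confidence (gain-level and kataegis-level catalogs can be tiny).

Transcriptional strand bias is tested per class or signature with the
exact conditional Poisson rate-ratio test (`stats::poisson.test`, which
conditions on the total and reduces to a binomial test), two-sided,
with Benjamini–Hochberg adjustment across groups (the multiplicity
correction is this package's choice). Mutations in genes on both
strands are `ambiguous` and excluded from the counts; the
"untranscribed" label means the annotated gene strand carries the
pyrimidine of the normalized class. Zero counts report a finite exact
p with the rate ratio flagged 0/∞ rather than NaN.

De novo extracted profiles are mapped to a reference by cosine
similarity against every single signature and every NNLS-fit pair;
`single` is chosen at cosine ≥ 0.9 (or within 0.01 of the best pair —
prefer the simpler explanation), `pair` at pair cosine ≥ 0.9, otherwise
`novel`. The 0.9/0.01 constants are unpublished and configurable.

## 3. Kataegis

A kataegis event is a maximal run of ≥ 6 consecutive mutations with
mean inter-mutation distance ≤ 1000 bp, grown greedily along each
chromosome; duplicate positions collapse first. The mean-based rule is
taken literally (a single gap > 1 kb is tolerated if the mean stays
within bounds); `strict_gaps = TRUE` provides the per-gap variant.
Events are annotated with the distance to the nearest same-chromosome
SV breakend (window 1 Mb) and classified by running the censored fit on
the event's mini-catalog with the clock signatures plus SBS2/SBS13
(grouped as APOBEC), SBS9 (nc-AID) and SBS84 (c-AID). Events
overlapping user-declared immunoglobulin loci are flagged `ig = TRUE`
so non-IG summaries can exclude them.

## 4. Molecular time of gains

Within a clonally gained region, a mutation's allelic multiplicity
separates pre-gain from post-gain history. Assuming a constant per-copy
mutation rate μ, expected counts by multiplicity are linear in the gain
time t₁ (and t₂ for sequential tetrasomies), giving closed forms for
π = t/T (T = time to the MRCA); e.g. trisomy: π = 3n₂/(2n₂+n₁);
CN-LOH and synchronous 2+2 tetrasomy: π = 2n₂/(2n₂+n₁); sequential
tetrasomies yield (π₁, π₂). These forms were re-derived here from
per-copy Poisson accrual by enumerating copy lineages, and the tests
validate them against that independent forward simulation (mean
absolute error ≤ 0.05 at ≥ 500 mutations). Ratios outside [0, 1]
(sampling noise) are clipped and flagged.

Multiplicity assignment fits a **binomial mixture with fixed means** at
`expected_vaf(m, ρ, CN) = m·ρ/(ρ·CN + 2(1−ρ))` — only the mixing
weights are free — because purity and copy number pin the component
locations; a free-mean quasi-Gaussian fallback
(`method = "gaussian"`) exists for miscalibrated purity. The published
workflow names only a generic mixed-model tool, so the fixed-mean
binomial is this package's design. Gains need **> 50 clonal
mutations**; smaller segments return counts but refuse estimation.
Subclonal segments are not timed.

Sequential tetrasomies are separated from synchronous ones by the
intermediary stage: mutations on two of four copies (VAF 50% at purity
1) accumulate only if time passed between the gains;
`detect_intermediate_stage` calls `two_windows` at ≥ k = 10 such
mutations (configurable; the floor guards against stray
misassignments). Only the 2-of-4 arithmetic is supported — a 2-of-3
state cannot produce a 50% corrected VAF.

Confidence intervals bootstrap the multiplicity counts
(multinomial, 1000 draws, percentile). Gains of one patient are merged
into time windows by clustering each bootstrap draw (complete linkage
on |πᵢ − πⱼ|, tree cut at 0.15 in π units — configurable, unpublished),
taking a majority-vote consensus across draws (transitive closure at
50% co-clustering), then merging clusters whose pooled 95% intervals
share a common point: gains whose uncertainty regions overlap cannot be
ordered and belong to one window. The CI-overlap merge is load-bearing:
without it, bootstrap-level noise (≈√2× the point-estimate SD)
oversplits same-epoch gains at realistic mutation counts.

## 5. The SBS5 clock

The clock model is a through-origin random-slope linear mixed model,
fit by REML (lme4):

burden_ij = (β + b_i)·age_ij + ε_ij,  b_i ~ N(0, σ_b²)

The observation unit is the **root-to-tip SBS5 burden of one sample**
(clonal plus that sample's lineage-private mutations) — pooling
parallel subclones would double-count time. No intercept is fit: a
lineage has zero mutations at conception, and the downstream
age arithmetic (age = burden/rate) assumes exact proportionality. This
is the package's reading of the published model, which does not state
whether an intercept or observation weights were used; both alternatives
are deliberate non-features rather than flags left half-tested.
Wald 95% intervals are reported for β; per-patient rates are the
shrunken β + b_i (patients with a single sample shrink fully toward
β). With fewer than two multi-sample patients σ_b is unidentifiable and
the function falls back to a fixed slope with a warning.

Sensitivity: `quadratic_sensitivity` adds a fixed age² term (ML fits,
AIC and likelihood-ratio comparison) and declares "no improvement"
unless the quadratic model beats the linear one by more than 2 AIC
points. Eligibility: samples with > 10,000 SNVs (hypermutators, where
the age–burden relationship collapses) or ploidy > 4 (double genome
duplication) are excluded before calibration.

## 6. Absolute ages

`mrca_age` = clonal SBS5 burden / patient rate, capped at the sampling
age (with a flag). For multi-gain events the molecular-time workflow is
repeated on **SBS5-only** multiplicity counts: per multiplicity group,
the censored fit of the group's catalog supplies its SBS5 count. This
matters — the package's own simulations show all-mutation π is biased
late when AID/APOBEC activity varies across epochs, while the SBS5-only
route is unbiased, because only the clock signature accrues at a
constant rate. Collapsed multi-gain events require **> 100 SBS5
mutations**. The gain age anchors to the MRCA:
age_gain = π × age_MRCA, since the clonal lineage spans conception to
MRCA under the through-origin clock; anchoring to genome-wide
duplicated SBS5 counts directly is the documented alternative, not the
default. Uncertainty is propagated by Monte Carlo (1000 draws): uniform
over the burden and π intervals (they are percentile intervals without
a parametric form), normal for the rate (Wald). Widening any component
interval can only widen the age interval (tested).

Paired-timepoint mutations are classed `clonal/positive/negative/
neutral` with a CCF-change threshold δ = 0.1 (unpublished,
configurable), and multi-sample mutations as early-clonal / late-clonal
/ subclonal by the literal all/some/none-clonal rules. The APOBEC
high/low split thresholds at the 75th percentile of burden among
patients with any APOBEC activity; the source cohort's threshold of 49
mutations is documentation, not a constant in code.

## 7. What the simulator emulates — and what it does not

`simulate_patient` generates, per epoch (pre-gain, gain→MRCA,
post-MRCA), Poisson mutation counts over a 500-Mb five-chromosome
genome in which chr1 carries the gain. The per-year SBS5 rate is
constant; other signatures scale relative to SBS5 by epoch-specific
activity fractions, emulating the four observed temporal patterns of
AID/APOBEC activity (AID early, APOBEC later). Pre-gain mutations on
the gained allele become duplicated; LOH-type scenarios drop pre-gain
minor-allele mutations; post-gain epochs add the extra copies'
mutations. Read counts are Binomial(depth, expected VAF) at the
configured purity (default 0.8) and depth (60×, WGS-like). Kataegis
clusters (APOBEC classes, ~100 bp spacing) are planted beside simulated
SV breakends. Multi-sample patients re-observe the shared clonal
mutations with independent read draws and add sample-private subclonal
mutations — matching the multi-timepoint design used to time MRCAs.

Deliberate simplifications: uniform mutation placement (no chromatin/
replication-timing topography), a single gained segment per patient,
subclonal mutations at a fixed CCF of 0.4 rather than a Dirichlet
process, binomial read noise only (no mapping or sequencing artefacts),
and sequential-tetrasomy intermediate multiplicities assigned by an
approximate epoch-fraction rule rather than exact per-copy genealogy.
A green test therefore establishes estimator correctness under the
stated generative model — not robustness to purity error, subclonal
copy number, or caller artefacts.

Default cohort parameters are the published population values: rate
mean 38.8 and between-patient SD 7.1 mutations/year (rates truncated
at > 5/year to stay physical), sampling ages 40–80. The end-to-end
recovery world draws gain ages U(10, 40) — gains arise across decades
of life — with 2–3 samples per patient; with a narrower gain-age spread
the rank-correlation criterion would measure the spread of the truth,
not the estimator. The directional "early gains" check keeps gains at
15–25 years.

## 8. Numerical choices and degenerate inputs

* NNLS tolerance is relative (1e-10 × ‖Sᵀy‖∞); exposures at the bound
  are zeroed exactly.
* Censoring ties break alphabetically (drop the last name):
  deterministic output for identical inputs.
* All stochastic operations take an explicit seed and restore the
  caller's RNG state; identical seeds give byte-identical results.
* Zero-width uncertainty intervals collapse to the point estimate; a
  zero strand count reports a flagged 0/∞ ratio with a finite exact p;
  an all-zero catalog, a zero burden, and an empty cohort are errors,
  not NaNs.
* π clipping to [0, 1] and the MRCA sampling-age cap are flagged in the
  returned objects, never silent.

## 9. Known limitations

* Signature bleeding inflates fitted SBS5 by several percent when many
  minor processes are censored; cohort-level rate calibration on the
  same fitted quantities largely cancels the effect in event ages
  (demonstrated in the end-to-end test), but single-patient absolute
  ages computed with an external rate inherit the bias.
* The binomial multiplicity mixture trusts the supplied purity; use the
  Gaussian fallback if purity is suspect.
* Kataegis segmentation is a greedy run rule, not piecewise-constant
  fitting; borderline clusters at the 6/1 kb boundary are sensitive to
  single mutations.
* The synthetic signature reference is a stand-in with well-separated
  support; real COSMIC signatures overlap far more, and censoring
  behaviour on real data will be less clean than the recovery tests
  suggest.
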