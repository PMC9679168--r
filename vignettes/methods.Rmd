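---
title: "Methods: biomarker-linked connectivity and regional gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker-linked connectivity and regional gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, the design choices that were
genuinely open, and what the synthetic-data validation does and does not
establish about real data.

## The analysis problem

A cohort of biomarker-characterized subjects (controls and gene carriers,
with CSF neurofilament light in pg/ml as the disease-burden covariate)
each contributes weighted, undirected connectomes over a labelled atlas of
cortical and subcortical regions. The scientific questions are layered:

1. Do connectomes differ between groups, edge-wise (network-based
   statistic) or in bulk (density)?
2. Does connectivity covary with the biomarker, edge-wise and per region?
3. Is the spatial pattern of the biomarker–connectivity association
   aligned with regional gene expression (PLS), and which genes, ontology
   terms and cell types drive that alignment?

Each layer consumes the previous one: node strengths feed the regional
map, the map is the PLS response, the PLS ranking feeds the enrichment
procedures.

## Edge-wise inference: the network-based statistic

Per edge, an ordinary-least-squares model `weight ~ contrast + age + sex`
yields the t statistic of the contrast coefficient. Edges with `t`
strictly above the primary threshold (default **τ = 3.1**, a conventional
primary threshold for this family of analyses; ties at τ are excluded)
form a graph; its node-connected components are the candidate
subnetworks. Significance is assessed on component *extent* (edge count)
against the permutation distribution of the maximum component size, so
each component's p-value is family-wise-error-corrected by construction
and bounded below by `1/(n_perm + 1)` (default `n_perm = 5000`). The
intensity statistic (summed suprathreshold t) is deliberately not
implemented: extent matches how subnetworks are conventionally reported
(connection counts).

**Covariates under permutation.** Age and sex cannot simply be shuffled
along with the contrast. We use Freedman–Lane residual permutation: fit
the nuisance-only model, permute its residuals, add back the nuisance
fit, and recompute the full-model statistic. One permutation is shared by
all edges per iteration — permuting edges independently would destroy the
dependence structure that the maximum-statistic correction relies on.
Implementation detail: by the Frisch–Waugh–Lovell identity the
permuted-data t reduces to inner products of the permuted residualized
regressors with the residualized data, so a whole permutation batch is two
BLAS matrix products; this is what makes 200-replicate calibration runs
tractable. Edges whose variance is numerically fully absorbed by the
nuisance model are assigned t = 0 rather than a roundoff ratio.

One-sided tests are run separately per direction (positive/negative
contrast), matching how such results are conventionally tabulated. The
same engine, restricted to a single "edge", provides the connectome
density permutation test (two-tailed there, pooled-variance t inside the
permutation).

## Regional maps

The primary response map is the partial Spearman correlation, in carriers
only, of node strength with the biomarker given age and sex. We
rank-transform (midranks for ties), residualize both ranked variables on
the covariates with an intercept, and correlate the residuals — the
rank-then-residualize construction extends cleanly to any number of
covariates, unlike the recursive partial-correlation identity, and agrees
with it for one covariate on ties-free data. P-values use the
t-approximation `t = ρ√(df/(1-ρ²))`, `df = n - 2 - #covariates`; a
permutation option exists because the approximation is only asymptotic.
Whole-cohort and control-only maps are available as negative controls.

The alternative map is the per-region OLS interaction coefficient from
`strength ~ 1 + age + sex + group × NfL`, in strength units per pg/ml.
Although such models are sometimes described as mixed models, with one
row per subject and no stated random effects there is nothing for a
random term to absorb, so plain OLS is the defensible reading; this was
an open design choice and is recorded here.

Both maps carry Benjamini–Hochberg q-values across regions
(`stats::p.adjust`).

## PLS with spatially constrained nulls

The region × gene expression matrix (gene columns z-scored across
regions; the response centred but never rescaled) is regressed on the map
by SIMPLS-style two-block PLS with deflation. No specific PLS variant is
canonical for this analysis; SIMPLS was chosen for its direct deflation
of the cross-covariance and clean explained-variance accounting: with
orthonormal score vectors `t_k`, component `k` explains
`100 · (y'·t_k)² / ‖y_c‖²` percent of the response. Conventions: gene
weight vectors are reported with unit norm, and each component is
oriented so its region scores correlate positively with the response —
PLS signs are otherwise arbitrary, and this fixes the meaning of
"upweighted" and "downweighted".

**Why spin nulls.** Expression maps and response maps are both spatially
autocorrelated; shuffling regions iid produces an anti-conservative null.
The spin null rotates sphere-projected cortical centroids by a uniform
random 3-D rotation (mirrored across hemispheres), then reassigns regions
greedily one-to-one by distance. Subcortical regions cannot live on the
cortical sphere, so they are permuted uniformly among themselves — a
bijection-preserving fallback that admits no spatial model for the
striatum (none is available). Component p-values compare observed
explained variance per component with the spin distribution; gene-level
q-values are the proportion of spins in which the observed weight fails
to strictly exceed that spin's 95th weight percentile (or fall below the
5th, on the downweighted side; percentiles by linear interpolation).
Component and gene inference deliberately consume the *same* spin set —
one shared spatially constrained null. A fitting detail worth recording:
refitting PLS on row-reordered X is algebraically identical to fitting
the original X against the inversely permuted response, which the
implementation exploits (and a test verifies).

Bootstrap gene ranking resamples **regions** with replacement — regions,
not genes, are the sampling units of the map — refits the first
component, aligns signs to the original weights, and reports
`Z = w / SD_boot(w)`, ranked descending. Degenerate resamples with a
constant response are redrawn.

## Enrichment

*Over-representation*: hypergeometric upper tail per term, after
intersecting each term with the supplied background; terms larger than
1000 genes (measured after intersection) are excluded to avoid
uninformatively broad categories; BH across tested terms.

*EWCE*: specificity of a gene for a cell type is its mean expression in
that type divided by its total across types (rows of the specificity
matrix sum to 1). The observed statistic per type sums specificity over
the target list; null lists of the same size are drawn with bootstrap
lists matched to the target on transcript length and GC content via
10 × 10 joint decile bins (bins sparser than two genes are widened to the
length decile, then to the whole background, with a warning). Matching on
these two covariates is the standard guard against length/GC-driven
artefacts in enrichment. Defaults: 100 000 bootstrap lists; top/bottom
10, 20 and 30% of the ranking are the conventional target-list presets.

*Candidate lists*: the summed Z over the candidate genes versus sums over
equal-size random draws from the ranked list; one-sided toward high
weights by default, with the low tail available — whether such tests are
run one- or two-sided is typically unstated, so the choice is exposed.
Candidate genes missing from the ranked background are dropped and
counted, never imputed. Null sums are accumulated in index order so that
the degenerate case (candidate = entire background) ties exactly under
floating-point addition. The observed/expected ratio of signed Z sums is
not meaningful, so `fold_change` is reported as `NA` for this procedure.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised
and calibrated without any subject-level data. Its defaults are the
emulated study conditions: a 100 + 14-region atlas (a 500 + 14 variant
checks granularity), 41 controls and 46 carriers, biomarker levels from
zero-truncated normals with means/SDs 354/261 (controls) and 767/585
(carriers) pg/ml — truncation by resampling, since concentrations cannot
be negative, keeps the printed moments approximately while respecting
units — and ages/sexes balanced across groups.

Structure planted for recovery testing:

* **Connectomes.** Structural weights are nonnegative with
  distance-decaying expectation (`exp(-d/40 mm)` times lognormal subject
  noise). Functional baselines are `tanh` of a shared Gaussian edge field
  plus subject noise — correlation-like weights in (-1, 1) without
  simulating time series. On planted edges the functional weight adds
  `coupling · (NfL − group mean)` plus noise; whether the coupling acts
  in carriers only or in the whole cohort is exposed as an option, since
  neither is asserted as the generative truth. Planted subnetworks are
  grown connected so the NBS should recover them as one component.
* **Expression.** Genes are draws from a Gaussian process over region
  centroids with a squared-exponential kernel (default length-scale
  20 mm) — the simplest stationary model consistent with the spatial-null
  logic; subcortical centroids share the kernel for lack of a separate
  smoothness model. Planted genes mix the response map with an
  independent GP draw at a target correlation. Transcript lengths
  (lognormal) and GC fractions (beta) are drawn broad and positive.
* **Cell-type reference.** Nine major classes (glutamatergic, GABAergic,
  astrocyte, microglia, oligodendrocyte, OPC, endothelial, pericyte,
  VLMC); markers get a fold-elevated mean in their class. Optionally one
  class's markers are drawn from a designated pool — the end-to-end
  pipeline uses this to couple response-tracking genes to the
  glutamatergic class, so the enrichment stage has a recoverable signal
  rather than pure null noise.

What the generator does **not** emulate: fMRI time series and their
noise structure, tractography biases, probe-level donor structure beyond
what probe collapsing needs, hemispheric asymmetries of expression,
non-stationary spatial autocorrelation, and biomarker–age dependence.
Passing tests therefore establish that the estimators are correctly
implemented and calibrated *under the assumed generative structure* —
they do not certify sensitivity or specificity on real connectomes, where
effect sizes, autocorrelation shape and confounding are less benign.

## Numerical choices and degenerate inputs

* Symmetry tolerance for connectomes is 1e-9; asymmetric matrices (text
  round-trips) are symmetrized by averaging with a warning; diagonals are
  forced to zero.
* All permutation/bootstrap p-values use the `(1 + #exceed)/(1 + n)`
  form, hence never zero and reproducible under a fixed seed; every
  seeded routine restores the caller's RNG state.
* One pipeline seed fans out into per-stage seeds via a deterministic
  label hash kept inside the 32-bit integer range, so changing one
  stage's parameters leaves upstream outputs byte-identical.
* Probe collapsing keeps probes above background in strictly more than
  50% of samples; among survivors per gene the highest mean intensity
  wins, exact ties going to the lexicographically smaller probe id.
* Constant gene columns are dropped (with a warning) before z-scoring;
  constant ranks raise an undefined-correlation error; designs are
  checked for rank deficiency and the collinear columns are named.
* The carrier split threshold is the linearly interpolated control
  percentile, with strict `<` for the "low" label.

## Problem sizes used in validation

The test suite validates calibration and recovery at sizes chosen to keep
a full run to minutes on one core while leaving the study-scale structure
intact: NBS null calibration uses 200 replicate cohorts (41 + 46
subjects, 114 regions) at 500 permutations; planted-subnetwork recovery
10 seeds at 1000 permutations; PLS recovery 100 replicates at 2000 genes,
300 spins and 100 bootstraps; EWCE at 2000 bootstrap lists (300 for the
calibration sweep); candidate-list calibration 200 replicates at 500
permutations. The defaults wired into the functions themselves remain the
full-scale values (5000 NBS permutations, 1000 spins, 100 000 EWCE
lists). The acceptance script re-runs the end-to-end pipeline at 114
regions and 2000 genes and reports its headline numbers as JSON.

## Known limitations

* The spin assignment is greedy nearest-pair, not an optimal transport
  matching; for very fine parcellations the tail of assignments can be
  distorted.
* The t-approximation for partial rank correlations is asymptotic;
  switch to the permutation option for small carrier counts.
* EWCE length × GC matching assumes the metadata covers every background
  gene; genes missing metadata must be filtered upstream.
* The interaction map treats regions independently; no spatial shrinkage
  across regions is attempted.
* With expression for one hemisphere only (a common situation for
  donor-derived atlases), mirroring is *not* performed; analyses should
  restrict to regions with coverage.
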