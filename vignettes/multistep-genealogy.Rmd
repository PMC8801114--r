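---
title: "Multistep incidence-age modelling and the genealogy tree of neurodegenerative diseases"
author: "ndsteps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistep incidence-age modelling and the genealogy tree of neurodegenerative diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndsteps)
```

## The model

Several neurodegenerative diseases (NDs) — amyotrophic lateral sclerosis
(ALS), Alzheimer's disease (AD), Parkinson's disease (PD) and others —
show age-specific incidence curves consistent with a multistage model
originally developed for cancer epidemiology: disease onset requires $n$
sequential rate-limiting steps, each with a small per-year probability.
If step $k$ has average background risk $u_k$, the incidence at age $t$ is

$$ i(t) = u_1 u_2 \cdots u_n \, t^{\,n-1} = u\,t^{\,n-1}, $$

so the points $(\log t, \log i)$ lie on a line with slope $m = n - 1$ and
intercept $c = \log u$.  `ndsteps` estimates the line by ordinary least
squares in $\log_{10}$ space (the slope is invariant to the log base),
converts the intercept to natural-log scale, and reports

* the step count $n = \mathrm{round}(m + 1)$, rounded half-up with a
  floor of 1 — this rounding reproduces the standard literature mappings
  of slopes 4.8 and 4.6 to six steps, and no source states a different
  rule;
* the background risk $u = e^{c}$, the product of the per-step risks, on
  the scale of the incidence data (cases per 100,000 person-years); and
* the per-step geometric mean risk $\mu(u) = u^{1/n}$.

Two data-preparation rules precede the fit.  First, each age bin is
represented by its midpoint; the sources plot log(age) without stating a
bin representative, and the midpoint is the least biased simple choice.
Second, bins with midpoints at or above 80 years are removed — incidence
estimates above 80 are distorted by competing mortality and diagnostic
under-ascertainment — but only when at least 4 points remain afterwards,
so sparse strata are never truncated into infeasibility.  Zero-incidence
bins are dropped before the log transform.

When one stratum (a disease/sex combination; labels ending in lowercase
`m`/`f` are male/female, all-uppercase labels pool both sexes) has
several studies, their points are pooled and fitted jointly rather than
averaged first.  Pooling preserves the sample size for the regression;
the averaged, harmonized path exists separately for the matrix analyses
below.  Whether the original analyses pooled or combined per-study fits
is not documented; pooling is this package's explicit choice.

### The linearity gate

Multiple sclerosis (MS) serves as the reference disease that does *not*
follow a multistep model: its incidence peaks in early adulthood and then
declines, so its log-log trajectory is not an increasing line.  The
literature excludes such profiles without stating a criterion; `ndsteps`
makes the decision explicit and testable with a *linearity gate*: a
stratum is treated as multistep-consistent when its fit has
$R^2 \ge 0.8$ **and** a positive slope.  The threshold is configurable;
0.8 is deliberately permissive for genuinely linear but noisy profiles
while rejecting non-monotone ones, whose OLS slope over adult ages is
negative (slopes at or below $-1$ have no valid step count and are floored
to $n = 1$; such strata always fail the gate).  Gated-out strata are
excluded from step allocation but remain in the embeddings as reference
profiles.

## Harmonization and embeddings

Studies report incidence on heterogeneous age-bin schemes.  To compare
trajectories, each study is interpolated with a natural cubic spline
(second derivative zero at the boundary knots) through its (midpoint,
incidence) points, evaluated on a common integer age grid (default 30–79
years, configurable).  The spline is *never* extrapolated: grid ages
outside a study's midpoint range are missing, because interpolating
splines diverge quickly outside their support.  Rare negative excursions
between knots are clipped to zero.  Studies of one stratum are averaged
age-by-age over the studies covering that age, giving the $d \times a$
incidence matrix $I$ with $I(i,j)$ the mean incidence of stratum $i$ at
age $j$, plus a coverage count per cell.

For embeddings (PCA by SVD, and UMAP), profiles are taken per dataset by
default (per-stratum averages are available), restricted to grid columns
covered by every profile, and $\log_{10}$-transformed.  Each profile's
mean log level is then removed (`rowCenter = TRUE`) before the usual
column centering; no unit-variance scaling is applied.  The row-centering
deserves a note, because an alternative — column-centering only, which
preserves amplitude — was considered and rejected: per-disease incidence
amplitudes legitimately span more than three orders of magnitude (CJD at
roughly 0.15 per 100,000 person-years versus AD in the hundreds), so
without row-centering the first principal component merely ranks diseases
by how common they are, and the scientifically interesting contrast — a
*declining* MS-like trajectory against the *rising* power-law
trajectories — is buried.  Removing each profile's mean log level turns
the embedding into a trajectory-shape analysis, on which the non-multistep
control is the most extreme profile on PC1 and the step-count tiers
separate on the remaining axes.  `rowCenter = FALSE` restores the
amplitude-preserving variant.  UMAP runs single-threaded with exact
nearest neighbours and a fixed seed, so embeddings are reproducible;
defaults are `n_neighbors = 5`, `min_dist = 0.3`.

## Age ranges, years per step, and the genealogy tree

A stratum's *incidence age range* runs from the start of its first
nonzero-incidence bin to the end of its last one, across all its studies,
after the same age-80 truncation as the fit.  Bin edges rather than
midpoints define the interval because the onset interval is a statement
about coverage; a midpoint convention is available.  Dividing the range
width by the step count gives the *years per step*, the average time for
one step to occur.  Regressing the (integer, post-rounding) step count on
the range width across gated strata quantifies the inverse relation
between the two; `sharedAgeBins()` partitions the age axis (default
2-year bins) and counts, per bin, the strata whose interval covers it,
reporting the maximal-count contiguous interval.

The *genealogy tree* allocates each gated disease's steps into steps
shared with other diseases (the trunk) and disease-specific steps (the
branches), under two parsimony criteria: *preserving the ordinal number
of each step* (a set of diseases can share step $k$ only if each has at
least $k$ steps) and *maximizing the number of shared steps between
diseases*.  Sharing sets along the trunk must be nested — the set at
ordinal $k+1$ is a subset of the set at ordinal $k$ — because the output
is a tree with a single trunk.  Which pairs of diseases *may* share steps
at all is not recoverable from incidence data alone; `ndsteps` therefore
makes compatibility an injectable symmetric predicate, defaulting to
"all gated diseases are mutually compatible".

### Why the selection is exact, not greedy

A natural heuristic picks, at each ordinal, the largest feasible subset
nested in the previous one.  Under the default all-compatible predicate
this is optimal, but under an arbitrary compatibility predicate it is
not: subset size is a poor proxy for the objective (three mutually
compatible 2-step diseases share 6 steps; an excluded pair of 13-step
diseases would share 26).  `ndsteps` instead exploits the structure of
the problem: any subset of a pairwise-compatible set is itself
compatible, so once the starting sharing set $S$ is fixed the rest of the
chain is forced (each member stays until its steps run out or it loses
company), and the total shared steps equal
$\sum_{d \in S} \min(n_d, \text{second-largest } n \text{ in } S)$.
This objective is monotone under adding compatible members, so the
optimum is attained at a maximal clique of the compatibility graph;
`allocateSteps()` scores every maximal clique (via `igraph`) with the
closed form and keeps the best, breaking ties deterministically by size,
then by larger step counts, then lexicographically.
`bruteForceAllocate()` — a literal enumeration of all nested selections
on instances of at most 5 diseases and 13 steps — serves as the
independent oracle in the tests.

The extended tree then attaches quantitative widths: branch points sit at
each distinct common-step count, and the trunk width there is the
arithmetic mean of the years/step of the diseases branching at that
point.  Step-count tiers follow the published bands — *stem* below 3
steps, *trunk-level* 5–7, *crown* above 7; counts of 3–4 fall in the gap
between the bands and are labelled `unclassified`.  In the sex-split
rendering, male branches draw on the left and female on the right.

## The synthetic study conditions

Because the original 404-dataset collection is external, every claim is
validated on synthetic panels with known ground truth.
`defaultPanelSpecs()` fixes the study conditions:

* ten multistep strata with true step counts
  $\{2, 6, 6, 6, 6, 8, 9, 11, 12, 13\}$, assembled from the step counts
  reported across the ND literature (HD 2; ALS, PD, FTD, CJD 6; PDM 8;
  PDD 9; AD 11 in men and 13 in women; DLB 12);
* designed incidence age ranges inversely related to the step count, so
  that years/step falls into three tiers (HD at $65/2 = 32.5$ years/step;
  the six-step diseases at 7–8.4; the high-step diseases at 1.5–4), and
  chosen so every stratum covers the common interval 60–78 years;
* background risks $u$ set so incidence at age 70 lies in a realistic
  0.15–250 per 100,000 person-years window for each disease;
* multiplicative log-normal noise with $\sigma = 0.05$ on incidence —
  positivity is preserved and the log-log fit's error becomes additive
  Gaussian, matching the model being tested (no noise model for real
  incidence estimates is documented anywhere; this is a stand-in, not an
  inference);
* three studies per stratum with heterogeneous bin widths (4–6 years)
  and a uniform 0–2-year jitter of each study's bin edges, so the spline
  harmonization is actually exercised;
* one MS-like control whose incidence follows a unimodal Gamma-shaped
  curve peaking near age 30 (sharpness configurable), so its log-log
  trajectory is non-linear and mostly decreasing.

What the generator does *not* emulate: per-country registry sizes,
reporting artefacts, cohort effects, competing mortality, or any
correlation between studies of one disease beyond the shared power law.
Passing tests therefore demonstrate that the pipeline recovers the
structure it assumes, under noise it models — not that real incidence
registries satisfy those assumptions.

## Numerical choices and degenerate inputs

* OLS is unweighted; the engine is `stats::lm`, cross-checked against
  brute-force normal equations to $10^{-10}$ in the tests.
* Two-point fits have $R^2 = 1$ by construction; fits with zero age
  variance raise an error.
* Spline interpolation at knots is exact to $10^{-9}$ relative; empty
  grid/study overlap yields an all-missing trajectory with a warning.
* `sharedAgeBins()` aligns bins to multiples of the bin width; ties for
  the maximal count resolve to the widest contiguous run.
* Subset enumeration in `buildSharingMatrix()` is capped at 15 diseases;
  the allocation itself scales with the number of maximal cliques, not
  with $2^d$.
* All simulation draws derive per-dataset sub-seeds (below $2^{31}$) from
  the master seed, the stratum label and the study index, so panels are
  reproducible element-wise, and RNG state is restored after each call.

## Problem sizes

The shipped tests and the acceptance script use: 200 replicates per true
step count for recovery rates, 100 replicates for the control's gate
failure rate, 100 random point sets for the regression oracle, 50 random
instances (2–5 diseases, 1–13 steps, 30% pair incompatibility) for the
allocation oracle, and the default panel (11 strata × 3 studies) for the
end-to-end pipeline — sizes at which every stochastic rate estimate is
stable to a few percent while the whole suite runs in well under a
minute.

## A worked example

```{r example}
cfg <- pipelineConfig(seed = 1L, outdir = tempfile())
res <- runPipeline(cfg, quiet = TRUE)
fitTable(res$fits)[, c("stratum", "slope_m", "n_steps", "r_squared",
                       "passes_linearity")]
res$stepsVsRange
res$sharedBins$sharedInterval
allocations(res$tree)
```

## Known limitations

* Step counts carry no confidence intervals, matching the source
  analyses; the rounding step hides slope uncertainty entirely.
* The counterpart-exclusion rule assumes pooled and sex-stratified
  datasets of one study are redundant; how pooled incidences relate
  numerically to the sex-stratified ones is not documented, and no
  reconciliation is attempted.
* The default compatibility predicate makes the maximal nested tree; the
  biologically constrained trees of the original analyses used
  feasibility information that is not recoverable from this data, so
  published shared-step counts are not reproduced, by design.
* Real-data quantities tied to the external 404-dataset collection
  (per-disease years/step, PCA variance percentages, the printed
  steps-vs-range $R^2$ values) are out of scope; the package reproduces
  the *properties* of those findings on designed synthetic panels.
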