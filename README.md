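# ndsteps

Multistep incidence-age modelling and genealogy trees of
neurodegenerative diseases (NDs).

## The problem

Age-specific incidence of several NDs — ALS, Alzheimer's, Parkinson's,
Huntington's and others — rises with age like a power law, the signature
of a multistage onset process: if a disease requires *n* sequential
rate-limiting steps with background risks *u₁…uₙ*, incidence at age *t*
is

    i(t) = u · t^(n−1),   u = u₁·u₂·…·uₙ

so log(*i*) against log(*t*) is a line with slope *m* = *n* − 1 and
intercept *c* = log(*u*). From a fitted line one reads off the step count
*n* = round(*m* + 1), the background risk *u* = e^c, and the per-step
geometric mean risk μ(*u*) = *u*^(1/n).

`ndsteps` is for epidemiologists and computational biologists who want to
run this analysis end to end on age-stratified incidence tables: fit the
log-log regression per disease/sex stratum (with the age-80 truncation
rule and an explicit linearity gate that filters out non-multistep
profiles such as MS), harmonize heterogeneous studies onto a common age
grid with natural cubic splines into a diseases × ages incidence matrix
(a `SummarizedExperiment`), embed incidence-trajectory shapes with PCA
and UMAP, compute onset age ranges and the **years-per-step** statistic
(range width ÷ step count), regress step counts on age-range widths, and
allocate each disease's steps into **common** (trunk) and
**disease-specific** (branch) steps by an ordinal-preserving,
sharing-maximizing parsimony criterion — the extended *genealogy tree*,
whose trunk width at each branch point is the mean years/step of the
diseases branching there. A synthetic-panel generator with known ground
truth (true step counts, background risks, designed age ranges, noise,
heterogeneous bin schemes, and an MS-like non-monotone control) makes
every stage testable without external registry data.

## Worked example

Fit one simulated male ALS stratum (true *n* = 6, three studies, 5% log
noise):

```r
library(ndsteps)
spec <- diseaseSpec("ALS", sex = "male", nTrue = 6L, backgroundRiskU = 1e-9,
                    ageMin = 45, ageMax = 80, noiseSigma = 0.05, nStudies = 3L)
panel <- generatePanel(list(spec), seed = 1L)
fitPanel(panel)[["ALSm"]]
#> MultistepFit ALSm: m=5.065 -> n=6 steps, u=7.68e-10, mu=0.0303, R2=0.998 (21 points)
```

The slope 5.065 rounds to six steps — the true value — with background
risk close to the simulated 1e-9 and an essentially perfect log-log line.

Run the whole pipeline on the default panel (10 multistep strata with
step counts 2–13, designed age ranges inversely related to the step
count, plus an MS-like control):

```r
res <- runPipeline(pipelineConfig(seed = 1L, outdir = tempfile()), quiet = TRUE)
res$stepsVsRange
#> $slope      [1] -0.2404317
#> $rSquared   [1] 0.9160804
#> $nStrata    [1] 10
res$sharedBins$sharedInterval
#> $ageStart 60   $ageEnd 78   $count 11
res$tree
#> GenealogyTree (pooled): 10 diseases, trunk height 12
#>   reference leaves: MS
head(allocations(res$tree), 4)
#>   stratum nSteps commonSteps specificSteps yearsPerStep        tier   side
#> 1     ADf     13          12             1     1.669980       crown center
#> 2     ADm     11          11             0     2.351636       crown center
#> 3     ALS      6           6             0     7.637938 trunk_level center
#> 4     CJD      6           6             0     8.644060 trunk_level center
```

Read: step counts fall as onset age ranges widen (negative slope,
R² = 0.92 across the 10 gated strata); every stratum, including the
control, has incidence in the 60–78-year window; the MS-like control
fails the linearity gate and hangs off the tree as a reference leaf; the
two 13/12-step diseases share 12 ordinal steps, the 6-step diseases share
their full chains, and years/step separates crown (≈1.7–4), trunk-level
(≈7–9) and stem (≈33) tiers. The run also writes `fits.csv`,
`incidence_matrix.csv`, `pca.csv`, `umap.csv`, `age_ranges.csv`,
`tree.json` and `manifest.json` (each CSV stamped with the config hash)
to the output directory.

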