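# corrsubpop

Correlation-guided subpopulation discovery in biochemical cohorts.

## The problem

In the laboratory work-up of suspected mitochondrial disease, muscle
biopsies yield paired biochemical measurements: respiratory-chain enzyme
activities (complexes I+III, II+III, II, III, IV, in nmol/min·mg protein),
citrate synthase (CS) activity as an index of mitochondrial abundance, and
coenzyme Q10 (CoQ) content (nmol/g protein). Over a whole referral cohort
these variables correlate only moderately — the cohort mixes disease
states, healthy muscle and assay noise. The question this package answers
is: **does a large subpopulation of subjects exist in which two variables
are tied by a nearly exact linear relationship**, and how many subjects
belong to it? A large high-correlation subpopulation is evidence that one
variable (e.g. CoQ) can serve as a biomarker or normalizer for the other
(e.g. an enzyme activity).

## The method

For a subject set *M* and Pearson correlation ρ, corrsubpop implements two
greedy subset-selection procedures around the *correlation loss* and
*correlation gain* measures

    CLM(M, i) = ρ(X_M, Y_M) − ρ(X_{M∪{i}}, Y_{M∪{i}})      (adding subject i)
    CGM(M, i) = ρ(X_{M−{i}}, Y_{M−{i}}) − ρ(X_M, Y_M)      (deleting subject i)

- **Agglomerative**: detect candidate linear axes with a trimmed k-lines
  procedure, seed from the three subjects nearest each axis, then
  repeatedly add the subject with the smallest correlation loss while the
  set's correlation stays ≥ r\* (default 0.95). Grow every axis; keep the
  grown cluster with the most individuals.
- **Divisive**: start from the whole cohort and repeatedly delete the
  subject with the largest correlation gain, stopping at the first set
  whose correlation reaches r\*. Deterministic, needs no seeding.

Agreement between the two solutions (100·|A∩D|/max(|A|,|D|)) validates the
result. Around the core sit Pearson correlation tables with per-pair sample
sizes and p < 0.01 screening, summary statistics, enzyme-activity
normalization (mUnits/CS-Units convention), a robust outlier screen, and a
synthetic cohort generator with planted ground truth.

## Worked example

The package ships a fully synthetic reference cohort
(`syntheticReferenceCohort()`, a labelled stand-in emulating the marginal
structure of a large pediatric muscle-biopsy series) with planted
high-correlation subpopulations as ground truth:

```r
library(corrsubpop)

ref <- syntheticReferenceCohort(seed = 1)
ref$table
#> BiomarkerTable: 448 subjects x 3 variables
#>   CoQ            [nmol/g protein]  n=447, missing=1
#>   CS             [nmol/min*mg protein]  n=448, missing=0
#>   CIII           [nmol/min*mg protein]  n=305, missing=143

pair <- pairwiseComplete(ref$table, "CoQ", "CS")
pearsonCorrelation(pair)
#> Pearson CS vs CoQ: r = 0.418 (N = 447); p = 2.64e-20 *
```

Cohort-wide, CoQ and CS correlate moderately (r ≈ 0.42 at this seed, over
447 pairwise-complete subjects, clearly significant). The divisive search
asks how many subjects support a near-exact linear relationship:

```r
scr <- screenOutliers(pair)            # robust-z screen, threshold 4.0
d <- divisiveSearch(scr$pair, SearchConfig(rStar = 0.95))
d
#> SearchTrace (divisive): 123 steps, final n = 302, final r = 0.9505 (threshold)

ag <- agglomerativePipeline(scr$pair, SearchConfig(rStar = 0.95), seed = 1)
compareSolutions(finalSet(ag$best), finalSet(d))
#> AgreementReport [CS vs CoQ]: agglomerative n = 302, divisive n = 302, common = 298, agreement = 98.7%
```

After deleting 123 subjects one at a time, 302 of 425 screened subjects
remain with within-set r = 0.9505 — a large subpopulation in which CS
activity is almost exactly proportional to CoQ content. The independently
seeded agglomerative search lands on essentially the same set (98.7%
agreement), the cross-validation that makes the subpopulation credible
rather than an artifact of one greedy path. Against the generator's ground
truth, the divisive set contains over 99% of the planted cluster members.

`agreementTable()` runs the whole pipeline over many enzyme/anchor pairs and
tabulates subpopulation sizes and agreement per pair;
`runCorrelate()`/`runSearch()`/`runCompare()`/`runSimulate()` are the
file-based workflow equivalents, each writing a reproducibility manifest.

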