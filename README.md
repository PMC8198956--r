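# seroscreen

Autoantibody (aAb) screening analysis for self-assembled antigen protein
microarrays (NAPPA-style), aimed at serological biomarker discovery in
sporadic colorectal cancer (sCRC) and similar settings. The package takes
spot-level array quantification tables (a GenePix-results dialect) from
plasma screenings of tumor-associated antigens (TAAs) and carries them
through control-spot normalization, seropositivity calling, differential
"immunome" definition, metastasis marker selection, and panel evaluation.
It is written for analysts who have (or simulate) per-spot 532 nm
intensities for cohorts of healthy donors and patients.

## The method

Every array carries three control classes besides the printed TAA spots:
**nonspot** positions (no printed material; the background reference),
**empty expression-vector** spots (vector with no insert; the
normalization and positivity reference), and positive controls (QC only).
For each array:

1. **Background correction** — background is the first quartile of the
   nonspot intensities; each spot's corrected value is
   `max(intensity − Q1, 0)`.
2. **Normalization** — each corrected value is divided by the median of
   the corrected empty-vector spots, which cancels per-array
   multiplicative scale exactly and pins the normalized empty-vector
   median at 1.
3. **Positivity** — a TAA is seropositive in a sample when its normalized
   value strictly exceeds that sample's `mean + 3·SD` of the normalized
   empty-vector spots.

The **immunome** is the set of TAAs that, comparing healthy donors
(group 1) against patients (group 2), satisfy all four of: (i)
Mann-Whitney p < 0.05 on normalized values; (ii) no positive call in any
healthy donor; (iii) positive in ≥ 2 patient samples; (iv) mean per-case
fold change above 1, where

```
FC = log2( case value / median(group 1) + 1 )
```

so FC = 1 exactly when a case sits at the reference median. The
metastasis differential re-runs the Mann-Whitney test on the immunome,
non-metastatic vs metastatic patients.

**Marker selection** uses a balanced leave-one-out LASSO vote: each round
holds out one metastatic sample, trains an L1-penalized least-squares
classifier (labels +1 metastatic / −1 non-metastatic, sign classifies)
on the remaining metastatic samples plus an equal-size random draw of
non-metastatic samples, and validates on the held-out metastatic sample
plus all undrawn non-metastatic samples. The penalty path is tuned so the
active set has k = 1, 2, 3 markers; features are tallied across rounds
into a vote histogram, and accuracy/recall are reported per k. Panels are
evaluated by ROC/AUC and Ward clustering.

A synthetic-cohort generator (`generate_cohort()`) emulates the data
structure — right-skewed lognormal intensities, sparse group-dependent
seroreactivity, planted differential TAAs, per-array scale jitter — so
the whole pipeline is testable without raw scanner data. The published
per-sample reactivity counts and the 67-TAA differential immunome of the
reference cohort ship as plain-text fixtures
(`load_table2_fixture()`, `load_table3_fixture()`).

## Worked example

```r
library(seroscreen)

cfg <- cohort_config(n_healthy = 7, n_crc_nonmet = 26, n_crc_met = 12,
                     n_taa = 300, reactive_fold = 10,
                     background_prevalence = 0.1,
                     planted_crc_taa = sprintf("TAA_%04d", 1:10),
                     planted_crc_prevalence = 0.95,
                     planted_met_taa = "TAA_0010",
                     planted_met_prevalence = 0.15, seed = 42)
g <- generate_cohort(cfg)
s <- run_pipeline(g$cohort, config = run_config(seed = 42))
s
#> run_summary: 45 samples ( 7 healthy / 26 non-met / 12 met ), 300 TAA features
#>   tested: 300 | immunome: 13 ( p < 0.01 : 11 ) | met-discriminant: 1
#>   LOO rounds: 12 | top k=1 marker: TAA_0010 (AUC 0.968)
```

Ten TAAs were planted as sCRC-reactive (prevalence 0.95, fold 10);
`TAA_0010` additionally loses reactivity in metastatic samples
(prevalence 0.15). The run finds a 13-TAA immunome containing all ten
planted antigens plus three background features (the per-test false
inclusion expected without multiplicity correction), flags one
metastasis-discriminant TAA, and the vote histogram puts `TAA_0010` on
top in all 12 leave-one-out rounds; the oriented single-marker ROC gives
AUC 0.968. The strict reporting subset looks like the published
immunome table:

```r
head(report_table3_style(s$healthy_vs_crc, p_cutoff = 0.01), 3)
#>     taa_id      p_value n_positive n_group  fc_mean fc_median pct_cases_fc_gt1
#> 1 TAA_0005 3.333275e-05         37      38 3.555246  3.535326        100.00000
#> 2 TAA_0008 5.718179e-05         37      38 3.430352  3.450378         97.36842
#> 3 TAA_0006 6.528874e-05         36      38 3.900280  3.981105        100.00000
```

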