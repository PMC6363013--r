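# RadSurv

MRI radiomics feature extraction and survival stratification for brain
tumor studies.

## The problem

In glioblastoma, MGMT promoter methylation is the standard molecular
marker of favorable prognosis, but it splits patients into only two
groups and leaves large survival heterogeneity unexplained. Quantitative
descriptors of tumor appearance on routine pre-treatment MRI — texture,
shape, intensity histogram and edge statistics computed inside the tumor
segmentation ("radiomics") — can carry complementary prognostic signal.
RadSurv implements, as reusable and tested R code, the full analysis
chain that evaluates this idea:

1. **Extraction.** From three co-registered sequences (T1WI, contrast-
   enhanced T1WI, FLAIR) sharing a single binary tumor mask, compute a
   fixed catalog of 286 features: 20 intensity-histogram features per
   sequence (unscaled intensities), 26 gray-level co-occurrence (GLCM)
   and 16 gray-level size-zone (GLSZM) features per sequence after
   rescaling to Q = 128 gray levels with
   `V_Q(x) = round((Q-1)(x - V_min)/(V_max - V_min) + 1)`,
   mean/SD/skewness/kurtosis of 24 Gabor edge-magnitude maps
   (orientations 0/30/45/90 degrees, carrier wavelengths 2 and 2*sqrt(2)
   pixels, applied slice-wise), and 4 mesh-based shape features
   (volume, surface area, sphericity `pi^(1/3)(6V)^(2/3)/A`, and A/V).
2. **Selection.** LASSO-penalized logistic regression (elastic net,
   mixing parameter 1) of vital status on the standardized features,
   tuned by 10-fold cross-validated deviance; features with non-zero
   coefficients are retained.
3. **Stratification.** Each selected feature is dichotomized at its
   Youden-index optimal ROC cutpoint; groups are compared by
   Kaplan-Meier curves and the log-rank test with Bonferroni correction
   over the tested features.
4. **MGMT combination and validation.** The favorable combination
   (methylated MGMT *and* feature below the cutoff) is compared against
   all other known-MGMT patients, and every cutoff is frozen and
   re-applied without re-estimation to an independent validation cohort.

Because patient imaging of this kind is rarely shareable, the package
includes a first-class synthetic module: ellipsoidal tumor phantoms with
an enhancing rim of controllable edge width, interior texture of
controllable correlation length, a FLAIR edema halo, and survival times
from a proportional-hazards model driven by MGMT and a planted image
property. Every pipeline stage is exercised end to end on these phantoms.

Intended users: imaging scientists and biostatisticians building or
auditing radiomics prognosis pipelines, and method developers who need a
fully controlled, reproducible test bed.

## Worked example

Generate one phantom study and extract its features:

```r
library(RadSurv)
study <- makePhantom(PhantomSpec(seed = 7))
study
#> MRIStudy 'phantom'
#>   grid: 48 x 48 x 48 voxels, spacing 1/1/1 mm
#>   mask: 4552 voxels (4.12% of grid)

fv <- extractFeatures(study, Q = 128)
round(fv[c("T1WI_CE.gabor.theta0_f2_skewness",
           "shape.morphology.sphericity",
           "shape.morphology.surface_to_volume_ratio")], 3)
#> T1WI_CE.gabor.theta0_f2_skewness   shape.morphology.sphericity
#>                            2.705                         0.953
#> shape.morphology.surface_to_volume_ratio
#>                                    0.306
```

The Gabor skewness of 2.7 says the edge-magnitude distribution inside
the tumor has a long right tail — a thin, bright enhancing rim; the
sphericity of 0.95 and surface-to-volume ratio of 0.31/mm describe a
compact, nearly spherical lesion.

A full training run on a synthetic cohort (features -> LASSO -> Youden
cutpoints -> KM/log-rank -> MGMT combination):

```r
cs <- CohortSpec(n = 80L, seed = 42L)
re <- extractCohortFeatures(cs)   # RadiomicsExperiment: 286 x 80
tr <- runTraining(re, seed = 1)
head(selectedFeatures(tr$selection), 2)
#>                            feature coefficient
#> 1 T1WI_CE.gabor.theta0_f2_kurtosis  0.13308924
#> 2           T1WI_CE.histogram.mean -0.04321264

tr$combined[[1]]
#> StratumResult 'MGMT+T1WI_CE.gabor.theta0_f2_kurtosis' cutoff = 10.16
#>   groups: methylated+low (n=25), rest (n=55)
#>           group  n   median       lcl      ucl
#>  methylated+low 25 42.54531 24.637760       NA
#>            rest 55 11.93452  6.915969 17.41776
#>   log-rank p = 2.74e-05, Bonferroni-adjusted p = 2.74e-05
```

The selection lands on the contrast-enhanced channel — where the
generator planted the hazard-linked rim property — and the combined
group (methylated MGMT with a favorable edge phenotype) shows a median
survival of 42.5 months against 11.9 months for everyone else, the
qualitative pattern the pipeline is designed to expose. Frozen-cutoff
validation on an independent cohort is then
`runValidation(reValidation, tr)`.

See the vignette (`vignettes/radsurv-methods.Rmd`) for the models,
parameter defaults, numerical conventions and the design of the
simulation studies.

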