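# facemotion

Prediction models that map 3D facial key-point motion onto six SCL-90
symptom dimensions — and the psychometric machinery to judge whether such
models measure anything.

Digital-phenotyping studies record the 36 facial key points of a seated
participant with a depth camera (30 Hz, ~700+ frames) while they read a
neutral text, and ask whether the motion statistics of those points predict
the participant's Symptom Checklist-90 subscale scores for interpersonal
sensitivity, depression, anxiety, hostility, phobic anxiety and
psychoticism (55 five-point Likert items). `facemotion` implements that
analysis end to end for researchers in biostatistics and computational
psychiatry, together with a synthetic cohort generator with known ground
truth, because the raw human recordings behind such studies are typically
not shareable.

## The method

For participant $i$ with recording $X_i$ (frames × 36 points × 3 axes):

1. **Preprocess**: translate every frame to key point 0 (nulls rigid head
   translation), smooth with a three-frame moving average, keep frames
   [100, 700), and first-difference — 108 coordinate-change series of
   length 599. Frames at even/odd window positions give two 300-frame
   split-half recordings (299 changes each).
2. **Features**: 30 time-series characteristics (extremes, moments,
   energy, change magnitudes, run lengths, extremum locations,
   reoccurrence statistics, …) per series → a participants × 3,240 feature
   matrix per variant (whole / odd / even).
3. **Models**: per dimension, select the 50 features with the largest
   univariate $F = \frac{r^2}{1-r^2}(n-2)$ against the raw subscale score,
   standardise, and fit the LASSO
   $\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 + \lambda\lVert\beta\rVert_1$
   with $\lambda$ tuned by five-fold cross-validation; every participant is
   predicted out of fold, for all three variants, by the model that never
   saw them.
4. **Psychometrics**: split-half reliability $R_1$ (correlation of odd-
   and even-half predictions), criterion validity $R_2$ (correlation of
   whole-data predictions with actual scores), and a 12 × 12
   multitrait-multimethod matrix yielding convergent and discriminant
   verdicts per dimension.

Feature selection and scaling are fit on the full sample by default —
faithfully replicating the reference protocol, leakage included;
`strict_cv = TRUE` refits them inside each training fold for honest
evaluation. The methods vignette
(`vignettes/facial-symptom-models.Rmd`) shows why the distinction matters:
the default protocol reaches $R_2 \approx 0.66$ on cohorts with *no*
facial signal at all.

## Worked example

```r
library(facemotion)
study <- run_study(n = 100, seed = 1)
study
#> Facial symptom study: 100/100 participants included
#> Psychometric evaluation of facial symptom-prediction models
#>
#>   Interpersonal sensitivity  R1 =  0.992  R2 =  0.934  convergent: pass  discriminant: pass
#>   Depression                 R1 =  0.992  R2 =  0.923  convergent: pass  discriminant: pass
#>   Anxiety                    R1 =  0.994  R2 =  0.910  convergent: pass  discriminant: pass
#>   Hostility                  R1 =  0.990  R2 =  0.885  convergent: pass  discriminant: pass
#>   Phobic anxiety             R1 =  0.983  R2 =  0.896  convergent: pass  discriminant: pass
#>   Psychoticism               R1 =  0.994  R2 =  0.902  convergent: pass  discriminant: pass
```

`run_study()` simulated 100 participants (default: moderate planted effect,
left-lateralised facial signal, inter-trait correlations 0.30–0.70),
excluded none (all recordings have 720 ≥ 700 frames, no all-minimum or
all-maximum response patterns), and fit the six models. $R_1$ near 1 says
the odd- and even-frame halves of a recording yield nearly identical
predictions (the measurement is stable); $R_2 \approx 0.9$ says the
planted facial signal is recovered almost fully at this effect size — far
above what real faces give, which is the point of a clear-recovery
default. `glance(study$fit)` shows each model keeps 12–20 of its 50
features at the tuned penalty.

The assessment half runs equally on published numbers. The packaged
reference matrix (the MTMM table printed by a facial-movement study of
these six dimensions) has validity diagonal 0.26–0.42, and exactly one
dimension — depression — fails the convergent-validity rule:

```r
ref <- read_mtmm(system.file("extdata", "reference_mtmm.csv", package = "facemotion"))
range(validity_diagonal(ref)$r)
#> [1] 0.26 0.42
subset(assess_convergent(ref), !pass)$dimension
#> [1] dep
```

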