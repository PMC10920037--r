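# trajvade

Deep embedding clustering of multi-informant psychopathology
trajectories, with predictor analysis of cluster membership.

## The problem

Adolescent psychopathology is heterogeneous and highly comorbid:
depressive symptoms, psychotic-like experiences, conduct problems,
somatic complaints and suicidality wax and wane together in ways that
classic latent-class trajectory models — which assume a parametric
trajectory shape and usually a single informant — struggle to capture.
`trajvade` implements the analysis strategy of clustering *all*
assessments at once, from both the adolescent's self-report and the
caregiver's report, across repeated waves, with a deep generative model
that makes no assumption about trajectory shape and handles missing
data inside the model. It is aimed at epidemiologists and
methodologists who want to apply — or stress-test — this strategy on
longitudinal cohort data, and it ships a synthetic-cohort generator
with known ground truth so every stage of the pipeline can be validated
end to end.

## The model

Each participant contributes a trajectory tensor **x** ∈ R^{T×D}
(T waves × D assessments, z-standardized per assessment across all
waves) with an observedness mask **m**. A recurrent variational deep
embedding (VaDER-type) model is fit:

- unobserved entries are replaced by learned imputation values **B**
  (initialized at observed means — "implicit mean imputation");
- an LSTM encoder maps the sequence to a latent Gaussian
  q(z|x) = N(μ̃, diag σ̃²), z ∈ R^L;
- the latent prior is a K-component Gaussian mixture
  p(z) = Σ_c π_c N(μ_c, diag σ²_c);
- an LSTM decoder reconstructs the sequence from z.

Training minimizes the negative ELBO: the squared reconstruction error
over *observed* cells plus the mixture latent term
Σ_c γ_c KL(q ‖ N(μ_c, σ²_c)) + Σ_c γ_c log(γ_c/π_c), where
γ_c ∝ π_c N(z; μ_c, σ²_c) are the posterior responsibilities. Clusters
are the argmax responsibilities at z = μ̃. The number of clusters is
chosen by prediction strength under repeated 2-fold cross-validation,
and baseline predictors of cluster membership are analyzed by
chained-equation multiple imputation, baseline-category multinomial
logistic regression, and Rubin's-rules pooling (odds ratios with 95%
CIs, Nagelkerke R², VIF).

All gradients (LSTM backpropagation, reparameterization, mixture
parameters) are derived and implemented in the package and verified
against finite differences in the test suite.

## Worked example

```r
library(trajvade)

# a 500-adolescent cohort with 5 planted trajectory classes,
# 14 assessments x 4 waves, realistic missingness
spec   <- cohort_spec(n_participants = 500, within_class_sd = 0.25,
                      random_intercept_sd = 0.1, seed = 11)
cohort <- generate_cohort(spec)
tensor <- standardize(cohort$scale_table)
print(tensor)
#> <trajectory_tensor> 500 participants x 4 waves x 14 assessments, 79.6% observed

model  <- fit_vader(tensor, vader_config(K = 5, L = 8, seed = 1))
labels <- assign_clusters(model, tensor)$labels
adjusted_rand_index(labels, as.integer(cohort$true_labels))
#> [1] 0.9326
cluster_shares(unname(name_clusters(tensor, labels,
                                    spec$class_profiles)[as.character(labels)]))
#>         cluster count share_pct
#> 1    unaffected   298      59.6
#> 2 internalizing    97      19.4
#> 3 externalizing    46       9.2
#> 4    discrepant    39       7.8
#> 5        severe    20       4.0
```

The adjusted Rand index of 0.93 says the model recovered the planted
five-class structure almost exactly; the share table is the synthetic
analog of a cohort's cluster composition (about 60% unaffected, the
rest spread over four affected classes). Bookkeeping helpers reproduce
published-style arithmetic exactly, e.g.

```r
attrition_report(c(T1 = 3171, T2 = 3007, T3 = 2667, T4 = 2616))$followup_pct
#> [1] 100.0  94.8  84.1  82.5
```

`run_pipeline(pipeline_config(...))` chains every stage — simulate,
MissForest item imputation, scoring, standardization, K selection,
clustering, predictor regression — and writes CSV/JSON artifacts plus a
JSON-lines stage log.

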