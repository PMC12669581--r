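# hfclust

Proteomics-based latent-class stratification of heart failure cohorts.

Patients with heart failure and reduced ejection fraction (HFrEF) who look
clinically similar can progress at very different rates. hfclust derives
patient strata from broad plasma-proteomic profiles (samples × proteins
matrices, e.g. aptamer-based panels) and packages the fitted stratification
as a single serializable model that assigns cluster membership to
out-of-sample patients — the property that separates latent class analysis
from heuristic clustering. It is aimed at biostatisticians and
translational researchers running cohort stratification and validating it
externally.

## The method

1. **Reduction** — proteins standardized to mean 0, SD 1 (training
   statistics frozen); principal components summarize the matrix (first 20
   by default, 30 as a sensitivity setting; deterministic sign convention).
2. **Categorization** — component scores discretized under competing
   percentile schemes (quartiles, deciles, 10th/90th and 20th/80th
   groupings); the scheme with the highest relative entropy
   `E = 1 − Σᵢₖ (−τᵢₖ ln τᵢₖ) / (n ln K)` wins; cutpoints are frozen for
   external use.
3. **Latent class analysis** — for indicators `y_ij`, mixing proportions
   `π_k` and item-response probabilities `ρ_jrk` are estimated by
   multistart EM on `Σᵢ ln Σₖ π_k Π_j ρ_{j,y_ij,k}` (compiled core,
   response probabilities floored at 1e-6, classes ordered by decreasing
   π). The number of classes combines BIC with the bootstrap
   likelihood-ratio test: p = (1 + #{LR_b ≥ LR_obs})/(B + 1) over B
   parametric-bootstrap refits (B = 999 by default), stepping up from the
   BIC optimum while p ≤ 0.05. Patients are assigned by maximum posterior
   probability. A Gaussian latent-profile variant avoids categorization.
4. **Clinical-variable selection** — candidate filters (>5% missingness,
   non-baseline, related-variable dedup) and a genetic algorithm over
   variable subsets with a clustering-evidence (BIC-difference) fitness.
5. **Association and explanation** — Kaplan-Meier/log-rank, Cox hazard
   ratios with follow-up truncated at 3 years, Harrell's c-statistic, and
   empirical-Bayes moderated differential expression with
   Benjamini-Hochberg control (flag: adjusted p < 0.05 and |log2FC| ≥ 1;
   flagged proteins assigned to their highest-expression cluster).

A seeded synthetic-cohort generator with known latent structure (protein
modules + factor background, class-conditional clinical variables,
class-dependent exponential survival) stands in for the non-deposited
cohorts and drives all validation.

## Worked example

```r
library(hfclust)

cohort <- generate_cohort(sim_config(n_samples = 1200, n_proteins = 120,
                                     n_informative = 36, seed = 421))
idx <- 1:600
config <- pipeline_config(n_components = 20, k_max = 4, B = 99,
                          n_starts = 12, seed = 5)
model <- derive_model(cohort$proteins[idx, ], config)
model
#> <hfc_model> K = 3 classes | scheme deciles | 20 PCs over 120 proteins
#>   cluster sizes: 235/225/140

adjusted_rand(model$assignments$class, cohort$true_labels[idx])
#> [1] 0.981

app <- apply_model(model, cohort$proteins[-idx, ])    # external cohort
app
#> <hfc_application> 600 samples | shared proteins 100.0% | sizes 219/218/163
adjusted_rand(app$assignments$class, cohort$true_labels[-idx])
#> [1] 0.985

assoc <- run_association(app$assignments, cohort$outcomes[-idx, ])
dplyr::filter(tidy(assoc), endpoint == "major_cv")[, c("cluster", "hr",
  "conf_low", "conf_high", "c_statistic")]
#> # A tibble: 2 × 5
#>   cluster    hr conf_low conf_high c_statistic
#>   <chr>   <dbl>    <dbl>     <dbl>       <dbl>
#> 1 2        2.11     1.49      2.98       0.652
#> 2 3        4.41     3.14      6.17       0.652
```

The derived clusters recover the generating class hazard multipliers
(1 / 2.3 / 5.8) from the proteins alone. Hazard ratios estimated on a
600-sample half-cohort carry sampling noise of this order; the
`scripts/acceptance.R` run below reproduces them within a few percent.

The derivation report (`model$report`) carries the per-K BIC/entropy
table, the bootstrap-test decision trace and the scheme entropy table.

A command-line interface wraps the same functions
(`Rscript inst/cli/hfclust.R <simulate|derive|apply|associate|de|select-vars> ...`;
see `?run_cli`).

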