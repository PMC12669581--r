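---
title: "Proteomic latent-class stratification: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic latent-class stratification: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Heart failure with reduced ejection fraction (HFrEF) is clinically
heterogeneous: patients with indistinguishable presentations progress at very
different rates. hfclust stratifies HFrEF cohorts from broad plasma-proteomic
profiles (thousands of aptamer-based protein measurements per patient) into a
small number of latent classes, and ships the fitted stratification as a
single serializable model that can be applied unchanged to an external cohort
— the property that distinguishes latent class analysis from heuristic
clustering, which has no out-of-sample assignment rule.

# The model chain

## Reduction and categorization

Protein values are standardized per protein to mean 0, SD 1 (sample SD,
denominator n − 1); the training means and SDs are frozen into the model.
Principal components summarize the standardized matrix; the first 20
components are used by default, with a 30-component sensitivity setting.
Component signs follow a fixed convention (the largest-magnitude loading of
each component is positive) so fits are reproducible across platforms.

Latent class analysis takes categorical indicators, so component scores are
discretized under four competing percentile schemes: quartiles (cuts at the
25th/50th/75th percentiles), deciles, and two low/middle/high groupings cut
at the 10th/90th and 20th/80th percentiles. Quantiles use linear
interpolation between order statistics (type 7); cutpoints are computed on
training scores and frozen, which makes external categorization bit-exact.
The scheme is chosen by fitting the latent class model under each scheme at
a fixed candidate class count and keeping the scheme with the highest
relative entropy,

$$E = 1 - \frac{\sum_i \sum_k -\tau_{ik}\,\ln \tau_{ik}}{n \ln K},$$

which is 1 when every posterior row is one-hot and 0 when all are uniform.
Whether entropy should be compared at a fixed K or after a per-scheme class-
number selection is genuinely open; we compare at fixed K (default 3)
because it keeps the scheme comparison orthogonal to the class-number
decision and costs one fit per scheme rather than a full selection loop.

## The latent class engine

For indicators $y_{ij}$ with $R_j$ categories, class proportions $\pi_k$ and
item-response probabilities $\rho_{jrk}$, the log-likelihood is
$\sum_i \ln \sum_k \pi_k \prod_j \rho_{j,y_{ij},k}$, maximized by EM from
random posterior initializations (independent Dirichlet rows; 20 starts by
default). Response probabilities are floored at $10^{-6}$ and renormalized
so empty cells cannot produce infinite log-likelihoods. Classes are
relabeled by decreasing $\pi$ on return, making every reported diagnostic
invariant to label permutation. Convergence is declared when the
log-likelihood gain falls below `tol` ($10^{-8}$); the per-iteration trace
is retained and tested for monotonicity. The EM tolerance, start count and
iteration cap are implementation choices — sensible defaults are given and
every one is a function argument.

The number of classes combines BIC with a bootstrap likelihood-ratio test
(BLRT): models with 1..k_max classes are fitted, the BIC-minimizing count
k* located, and k versus k + 1 tested by refitting both models on B
parametric-bootstrap datasets drawn from the fitted k-class model; the
p-value is the rank statistic (1 + #{LR_b ≥ LR_obs})/(B + 1). While
p ≤ 0.05 the count steps up. B defaults to 999; tests and the acceptance
script use B = 99, which changes the p-value granularity but not the
decision behaviour at the effect sizes involved. The published description
of the BIC/BLRT interplay is two sentences; because the exact interplay is
ambiguous (could the test also step down?), the full decision trace —
per-K fit table and every test performed — is always returned. Bootstrap
refits reuse half the number of starts of the observed-data fits; this is
the dominant cost knob and is documented as such.

Samples are assigned to the class with the highest posterior probability;
ties break to the lowest class index. A latent-profile (Gaussian mixture)
variant with diagonal or shared-full covariance provides the sensitivity
analysis that avoids categorization entirely, under identical posterior,
assignment and BIC contracts.

## Clinical-variable selection

Candidate clinical variables are filtered first: more than 5% missingness,
non-baseline variables, and all but one representative per declared
relatedness group (kept: fewest missing, then name). Continuous variables
are discretized at conventional clinical cutoffs (e.g. body-mass-index 25
and 30) with a half-open upper-bin rule. A genetic algorithm then searches
variable subsets: binary-mask chromosomes, tournament selection (size 2),
uniform crossover, per-bit mutation (default 1/L), elitism, and subset-size
repair. Fitness is the clustering evidence of the subset — BIC of the
one-class (independence) model minus BIC of the K-class latent class model
on the same variables, larger is better — with an entropy alternative
selectable by configuration. None of the GA hyperparameters were published;
all are configuration fields with documented defaults. One property of this
fitness is worth stating plainly: a single categorical variable carries no
clustering evidence on its own (the independence model fits any univariate
margin perfectly), so informative variables are detected through their
associations — the planted-variable test therefore embeds the planted
variable in a cohort whose other baseline variables also carry class
signal.

## Survival association

Follow-up is truncated at 3 years (later times censored at the horizon;
events exactly at the horizon retained). Kaplan-Meier curves and the
unweighted log-rank test compare clusters; Cox proportional-hazards models
(Efron tie handling, via the survival package) estimate hazard ratios
against a reference cluster — by default the cluster with the lowest crude
event rate, mirroring the slowly progressing reference group — and
Harrell's concordance is computed from the Cox linear predictor on the
truncated data. Cluster models are unadjusted (cluster dummies only);
per-protein benchmarking models add age and sex and standardize continuous
covariates so hazard ratios are per SD increase. Whether the published
cluster hazard ratios were covariate-adjusted is not stated; unadjusted is
the default here and adjustment is one argument away.

## Differential expression

Per-protein one-way models on cluster indicators yield one-vs-rest log2
fold changes (cluster mean minus the mean of all remaining samples, on the
standardized scale by default — the scale must be explicit because
clustering operates on standardized values). Residual variances are shrunk
by empirical Bayes: with d residual degrees of freedom,
$e_g = \ln s_g^2 - \psi(d/2) + \ln(d/2)$ has variance
$\psi'(d/2) + \psi'(d_0/2)$, so the prior degrees of freedom $d_0$ come
from a trigamma inversion of $\mathrm{Var}(e) - \psi'(d/2)$ and the prior
variance from the mean of $e$; the moderated variance is
$(d_0 s_0^2 + d s_g^2)/(d_0 + d)$. This closed-form moment matching is the
standard estimator for the moderated-statistics model and is verified in
the tests both against a step-by-step arithmetic oracle and against the
reference implementation in limma. The overall test is a moderated F;
flagging requires both a Benjamini-Hochberg adjusted p below 0.05 and a
maximum absolute log2 fold change of at least 1.0 (the 0.7 preset used
upstream of enrichment analyses is available); flagged proteins are
assigned to the cluster with the highest mean expression.

# The synthetic cohort generator

No cohort data are deposited, so the package ships a seeded generator whose
cohorts exercise every stage end-to-end: a latent class label per sample
expressed in three coupled layers — proteins, categorical clinical
variables, and time-to-event outcomes.

The protein layer adds class mean shifts to two disjoint "module" blocks of
informative proteins over a factor-structured correlated background plus
unit Gaussian noise. The geometry of the class mean shifts is deliberate,
and was designed from first principles about the reduction chain rather
than tuned freely: for K classes the between-class covariance has rank
K − 1, so principal components concentrate all class signal into exactly
K − 1 components — for K = 3, two informative components, however many
proteins are informative. The class positions on those two axes are
therefore chosen (i) in the eigenbasis of the weighted between-class
covariance (weighted mean zero, weighted cross-moment zero), so the
realized component axes match the designed axes instead of rotating
arbitrarily from seed to seed; (ii) with complementary pairwise gaps — the
pair least separated on one axis is the best separated on the other; and
(iii) with unequal module sizes, which separates the two signal
eigenvalues structurally (eigenvalues saturate with signal strength, so
position scaling alone cannot keep them apart) and pins the axes. The
default effect size puts adjacent-class gaps at roughly three to four
within-class SDs on the informative components: the regime where the
categorize-then-cluster chain recovers labels reliably. Much weaker
signal mixes with the factor background; much stronger signal makes
single extreme items decisive and lets the likelihood favour splitting the
largest class instead of the true partition.

Clinical variables are drawn from class-conditional categorical
distributions (defaults emulate age bands, aetiology and comorbidity
histories, plus deliberately uninformative nulls), with
completely-at-random missingness. Survival times are exponential with
hazard `baseline_hazard * class_hazard_ratios[class]`; the default
multipliers (1, 2.3, 5.8) mirror the hazard-ratio magnitudes reported for
proteomic clusters, the default baseline (0.12/year) reflects the event
counts observed over the cohort's follow-up, and censoring is an
independent exponential whose rate is solved by root finding so the overall
censored fraction (including administrative truncation at 3 years) hits the
target. All randomness flows from one root seed through a fixed
stream-splitting rule (child seeds are a fixed pseudo-random stream from
the root), so cohorts are bit-reproducible and adding a consumer never
perturbs earlier draws.

What the generator does not emulate: assay plate effects and vendor
normalization, longitudinal sampling, competing risks, informative
censoring, and the heavy-tailed intensity distributions of real aptamer
data. Passing tests on these cohorts therefore demonstrate the pipeline's
internal correctness and its behaviour under a known ground truth — not
performance on real SomaScan data.

# Problem sizes and runtime

The test-suite and acceptance problem sizes are chosen to exercise each
claim at desk scale: categorical-design simulations with n = 400–1500 and
8–10 items for the engine and selection properties; protein cohorts of a
few hundred samples by 100–150 proteins for the end-to-end contracts;
B = 99 bootstrap replicates for the likelihood-ratio test (the package
default remains 999); 20 seeded replicates for selection consistency; and
200 null fits for confidence-interval coverage. The full suite and the
acceptance script each run in well under half an hour on one core.

# Known limitations

- The categorize-then-cluster chain discards within-category information;
  the latent-profile variant exists precisely to check that conclusions
  survive without categorization.
- Entropy measures assignment crispness, not correctness. A coarse
  low/middle/high scheme can admit a maximum-likelihood solution that is a
  perfectly deterministic function of the code geometry — relative entropy
  exactly 1 — without matching the latent classes, and the highest-entropy
  rule will then select it over a finer scheme whose (correct) solution has
  entropy 0.99. On synthetic cohorts this occurs on a minority of seeds;
  the per-scheme entropy table in the derivation report exists so such
  selections can be audited. (Comparing entropies at each scheme's
  BIC-optimal class count instead does not help: at these sample sizes BIC
  under the 10-category scheme can prefer one class outright, collapsing
  the comparison — one reason the fixed-K comparison is the default.)
- Conditional independence is the engine's core assumption. Correlated
  indicators within a class (for example, from shared latent factors that
  leak into several retained components) bias it toward carving continua
  rather than recovering classes; the generator documents this regime and
  the null-safety tests bound it.
- The GA fitness measures clustering evidence, not outcome association;
  a variable can be selected for strong class structure that is clinically
  uninteresting.
- BIC-then-BLRT step-up is one reading of a two-sentence published
  description; the decision trace is always emitted so any other reading
  can be audited against the same fits.
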