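# wordtraits

Inducing **behavior-based linguistic traits** (BLTs) from open-vocabulary
social-media language, and putting them through a full psychometric
evaluation battery.

Questionnaire-based personality models (the Big Five and relatives) measure
people through self-report items. This package implements the complementary
approach: derive the latent dimensions of individual difference directly
from *what people write*. It is aimed at computational social scientists and
psychometricians who want a tested, reproducible reference pipeline for
language-based trait induction — and at methodologists who want every stage
of such a pipeline to be verifiable by parameter recovery on synthetic data
with planted ground truth.

## The model

Given a user-term matrix $M$ ($n$ users × $V$ words, standardized relative
frequencies), the traits are an exploratory factor model

$$M = F L^\top + E, \qquad \mathrm{Cov}(E) = \Psi \ \text{(diagonal)},$$

estimated by maximum likelihood (EM on the correlation matrix,
deterministic principal-axis initialization), then rotated with an oblique
**promax rotation on top of an equamax solution**. Users — including
held-out users — are scored with Thurstone regression weights
$W = \Sigma^{-1} L \Phi$. Around this core the package provides:

* **Corpus construction** — tokenization, user filtering (≥ 1000 words,
  age/country metadata), stopword removal, top-K vocabulary, relative
  frequency + column z-scoring, calendar windowing;
* **Differential language analysis** — per-word Pearson correlates of each
  factor with Benjamini–Hochberg FDR control and frequency tiers;
* **Generalizability** — NMF clustering of user likes into binary targets,
  cross-validated ridge / logistic prediction of outcomes (mean Pearson r /
  AUC over 10 random splits), demographic covariates and residualization,
  best/worst target rankings;
* **Stability** — test-retest correlations of factor scores across 6-month
  windows, and dropout reliability over repeated refits with 20% of
  training users removed, factors matched across refits by the Hungarian
  algorithm on $1 - |r|$;
* **Synthetic data** — a generator with planted correlated traits, AR(1)
  temporal dynamics, softmax word-use link over a Zipf baseline, linear
  outcomes with known theoretical R², and block-structured likes, so every
  stage above is testable by recovery.

## A worked example

```r
library(wordtraits)

# a synthetic population with 3 planted traits, and its message corpus
cfg <- synth_config(n_users = 500, vocab_size = 200, n_factors = 3, seed = 1)
pop <- generate_population(cfg)
corpus <- generate_messages(pop)

# corpus -> vocabulary -> user-term matrix -> ML factor model -> promax
model <- corpus |>
  filter_users(min_words = 1000) |>
  induce_traits(k = 3, top_k = 200, rotation = "promax")
model
#> <factor_model> k = 3, ml_fa estimation, promax(equamax, m=4) rotation, 500 users x 200 terms
#>   log-likelihood -116749.94 after 6 EM iterations

# how well do the learned scores recover the planted traits?
truth <- pop$traits[[1]]
rownames(truth) <- pop$demographics$user_id
align_factors(model$scores, truth)
#> <factor_alignment> k = 3, mean |r| = 0.980
#>   permutation: 1 2 3  signs: + + +
```

The mean aligned |r| of 0.98 says the three learned factors are nearly
perfect stand-ins for the three planted traits (sign and order of factors
are arbitrary, so alignment is by optimal assignment on absolute
correlations). Differential language analysis then surfaces the planted
marker words:

```r
utm <- build_user_term_matrix(corpus, model$vocabulary)
dla <- correlate_words(utm, model$scores)
top_words(dla, factor = 1, n = 5)
#> # A tibble: 5 × 3
#>   term      r freq_tier
#>   <chr> <dbl> <chr>
#> 1 w0001 0.963 frequent
#> 2 w0011 0.907 frequent
#> 3 w0021 0.870 frequent
#> 4 w0031 0.832 frequent
#> 5 w0041 0.781 frequent

# predictive validity of scores + demographics for a synthetic log income
outcomes <- generate_outcomes(pop)
feats <- add_covariates(model$scores, outcomes)
evaluate_regression(feats,
                    outcomes$log_income[match(rownames(feats), outcomes$user_id)],
                    outcome_name = "log_income", feature_name = "FA3+Demog",
                    seed = 2)
#> # A tibble: 1 × 7
#>   outcome    features  metric     mean     sd n_splits splits
#>   <chr>      <chr>     <chr>     <dbl>  <dbl>    <int> <list>
#> 1 log_income FA3+Demog pearson_r 0.441 0.0857       10 <dbl [10]>
```

The cross-validated r of 0.44 sits near this outcome's theoretical ceiling
(its generator R² is 0.23, i.e. a best-case r of about 0.48, reduced by
estimation noise at 500 users). `test_retest()` and
`dropout_reliability()` complete the battery; `autoplot()` methods and
broom-style `tidy()` / `glance()` accessors are available for every result
type.

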