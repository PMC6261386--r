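---
title: "Inducing behavior-based linguistic traits from open-vocabulary language use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inducing behavior-based linguistic traits from open-vocabulary language use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordtraits)
```

## The model

`wordtraits` induces latent dimensions of individual difference — *behavioral
linguistic traits* (BLTs) — directly from how people use words, instead of
from questionnaire items. The observed data are per-user word frequencies.
Let $M$ be the $n \times V$ user-term matrix of standardized relative word
frequencies. The trait model is an exploratory factor analysis

$$M = F L^\top + E,$$

with $F$ the $n \times k$ user trait scores, $L$ the $V \times k$ loading
matrix relating words to traits, and $E$ heteroscedastic residuals with
variances $\Psi = \mathrm{diag}(\psi_1, \dots, \psi_V)$. Factor analysis is
preferred over a plain truncated SVD because it attributes only *common*
variance to the traits; the SVD is recovered exactly as the special case of
isotropic residuals, which the package verifies numerically
(`fit_factor_analysis(..., method = "svd")` and the subspace test in the
acceptance suite).

Estimation is maximum likelihood under the Gaussian factor model, by
expectation-maximization on the sample correlation matrix. Numerical
choices that matter:

* **Initialization** is deterministic: a principal-axis start from the
  spectral decomposition of the correlation matrix. No randomness enters the
  fit, so refits on the same matrix are bit-reproducible.
* **Convergence** is declared when the relative change of the
  log-likelihood falls below `tol` (default `1e-6`); exceeding `max_iter`
  is an error, never a silent truncation.
* **Residual variances** are floored at `psi_floor` (default `1e-4`) as
  Heywood-case protection; fitting on the correlation matrix (rather than a
  covariance) is the default because the columns of $M$ are already
  z-scored, and it keeps communalities interpretable on a 0–1 scale.

After estimation the solution is rotated. Orthogonal rotations (varimax,
equamax) are members of the orthomax family, maximized by the iterative
SVD algorithm with Kaiser row normalization. The headline configuration is
an oblique **promax rotation applied on top of an equamax solution**: the
equamax criterion spreads variance evenly across factors, and promax then
relaxes orthogonality toward the element-wise power of that solution
(`promax_power = 4`), returning pattern loadings and a factor correlation
matrix $\Phi$. The phrase "promax with equamax" admits two readings — promax
*initialized by* equamax, or a choice *between* them — so the initial
orthogonal rotation is a flag (`initial_orthogonal`), with equamax the
default. Every rotation leaves the fitted covariance
$L \Phi L^\top + \Psi$ unchanged; the test suite asserts this to
$10^{-8}$ for all methods.

**Scoring.** New users are scored with Thurstone regression weights
$W = \Sigma^{-1} L \Phi$, computed from the model-implied covariance
$\Sigma = L\Phi L^\top + \Psi$ through the Woodbury identity. Using the
model-implied rather than the sample covariance keeps $W$ well-defined when
$V$ approaches $n$ and makes scoring exactly self-consistent: scoring the
training matrix reproduces the fitted scores. A held-out matrix must be
built with the model's vocabulary and is standardized with the model's
stored column means and standard deviations — never its own.

**How many factors?** `suggest_n_factors()` implements the scree
acceleration rule: with eigenvalues $\lambda_1 \ge \lambda_2 \ge \dots$ of
the correlation matrix, the acceleration
$a_i = (\lambda_{i+1} - \lambda_i) - (\lambda_i - \lambda_{i-1})$ locates
the sharpest elbow, and the suggestion is $\arg\max_i a_i - 1$ (ties toward
the smaller index; a flat spectrum returns 1 flagged low-confidence). The
rule finds the planted count on clean spectra with factors of comparable
strength; when one factor dominates (for example under strong factor
correlation), the largest curvature can sit after the first eigenvalue —
a known property of acceleration-based scree rules, not a defect of the
implementation. The default `k = 5` mirrors the convention of comparing
against five questionnaire factors; 3, 10 and 30 are documented presets.

## From raw messages to the user-term matrix

`tokenize()` lowercases, splits on whitespace, strips punctuation but keeps
word-internal apostrophes and emoticon-like tokens. `filter_users()`
retains users with at least 1000 posted words (the strict reading:
*fewer than* 1000 drops), at most 65 years of age and from the required
country when metadata is present. `build_vocabulary()` removes a packaged
English stopword list (overridable) and keeps the `top_k` remaining terms
by corpus frequency with lexicographic tie-breaks. `build_user_term_matrix()`
computes per-user relative frequencies over the retained vocabulary and
z-scores columns.

The cell statistic is a genuinely open choice: relative frequency with
column z-scoring is the convention of open-vocabulary language analysis and
the default here; a square-root variance-stabilizing transform is available
behind `transform = "relfreq_sqrt"`. Whether factor analysis should consume
z-scored columns or raw frequencies is likewise exposed rather than
hard-coded (z-scoring is the default; Pearson correlations in the
differential analysis are identical either way, since correlation is
affine-invariant).

Calendar windows (`window_corpus()`) are consecutive half-open intervals of
6 months anchored at the corpus minimum timestamp — anchoring is otherwise
arbitrary, and this choice is deterministic and reproducible; a message on
a boundary instant belongs to the later window. Users below 1000 words
inside a window are dropped for that window only.

## The evaluation battery

**Differential language analysis** (`correlate_words()`): every term's
relative frequency is Pearson-correlated with every factor score; p-values
come from the t distribution and are Benjamini–Hochberg adjusted. The FDR
family is per-factor by default (each factor's word list controls its own
FDR, matching how per-factor word clouds are read); a global family is one
flag away. Constant term columns are flagged degenerate and excluded from
the family. Frequency terciles (low / moderate / frequent) reproduce the
three-color encoding of word-cloud figures as a tabular attribute.

**Predictive validity** (`evaluate_regression()`,
`evaluate_classification()`): ridge and L2-logistic models with the penalty
grid-searched over $10^{-3}..10^{3}$ (13 log-spaced points) by inner 3-fold
cross-validation, evaluated over 10 random 75/25 train/test splits — the
75/25 fraction mirrors the corpus split used in the stability analysis,
since the predictive-validity split size is not otherwise pinned down.
Performance is mean Pearson r (continuous) or mean AUC over targets and
splits (binary), with per-split values retained so every reported mean is
recomputable. Income-style outcomes are modelled on the log scale
throughout, in both generator and evaluator. Demographic covariates enter
as z-scored age and a 0/1 gender indicator (`add_covariates()`), and
`residualize()` replaces scores by their least-squares residuals on those
covariates.

**Likes targets** (`cluster_likes()`): the binary user-likes matrix is
restricted to the most popular items and factorized by NMF (multiplicative
Frobenius updates, seeded random start, rank 20 by default). The binary
per-user targets are derived by an above-median rule on the user-side
weights: the derivation of 20 binary targets from an NMF is not otherwise
specified, and a median split guarantees near-balanced targets, which AUC
handles gracefully.

**Stability.** `test_retest()` splits messages 75/25 *within* each user
(stratified, so every user can appear in both portions — windowed retest
requires held-out text for the same people), fits on the training portion,
scores each test window with the fixed model, and correlates lag-t scores
with window-0 scores over per-lag common users. `dropout_reliability()`
refits the model 100 times (configurable) with a random 20% of training
users removed each time, scores a fixed held-out test set, and aligns every
unordered pair of refits with the Hungarian algorithm on the cost
$1 - |r|$; factor sign is arbitrary, so alignment quality is the mean
absolute matched correlation, with matched signs reported separately.
Dropout refits reuse the tokenized matrix and drop rows (re-standardizing
on the retained users) rather than re-tokenizing text: statistically
equivalent and much faster.

## The synthetic generator: what it emulates and what it does not

Every stage above is validated by parameter recovery on corpora with known
ground truth. `synth_config()` fixes the generative model:

* **Traits**: zero-mean unit-variance multivariate normal with a common
  inter-factor correlation (default 0.25 — oblique, as promax expects);
  across 6-month windows they follow a stationary AR(1) with coefficient
  `stability_rho`, so `cor(trait_t, trait_0) = rho^t` exactly in
  expectation.
* **Word use**: user word distributions are
  `softmax(baseline + L_true %*% trait)` over a Zipf baseline
  (exponent 1.07). The softmax link guarantees a valid distribution and
  makes marker-word enrichment monotone in the trait. Marker placement is a
  *structural* property of the configuration — markers are spread
  deterministically across the frequency spectrum and interleaved across
  factors — so populations drawn with different seeds share one word-trait
  structure and can serve as training and held-out samples. Words are drawn
  i.i.d. and cut into messages of random length; message-level topicality
  is deliberately absent because every evaluated statistic aggregates to
  the user level.
* **Effect size**: `loading_magnitude = 0.5` with 40 markers per factor.
  The literature reports no effect-size scale for language-trait
  associations, so the default was calibrated on the generator itself to
  make recovery strong but not trivial: per-marker word-trait correlations
  land roughly between 0.3 and 0.8 across the frequency spectrum at the
  default word budget, and end-to-end recovery of planted traits reaches
  mean |r| ≈ 0.95–0.98 at 2000 users — clearly below 1, clearly above what
  unstructured data yields (≈ 0.5 in the dropout contrast).
* **Demographics**: 62.8% female; ages from a shifted log-normal whose
  parameters are solved numerically so the *truncated* (13–65)
  distribution has median 22 and mean 25.49.
* **Word budgets**: per user and window, log-normal with median 3500
  (sd-log 0.6), resampled to at least 1000 — the retention threshold used
  for real corpora; 3500 words corresponds to a typical multi-year posting
  history at a few dozen words per status.
* **Outcomes**: linear in traits and demographics plus Gaussian noise, with
  each outcome's theoretical R² stored alongside; binary outcomes threshold
  the latent value at its median.
* **Likes**: items in blocks, users assigned to the block their traits
  project on most; like probability `within_p` inside the own block,
  `background_p` elsewhere.

What the generator does **not** emulate: non-English text, spam and
copy-paste meme dynamics, message-level topical structure, network effects
among users, or any nonlinearity in trait-outcome links. Passing recovery
tests therefore show that the pipeline's estimators are correct and stable
under the stated model — not that real social-media language satisfies that
model.

## Problem sizes and degenerate inputs

The shipped validation uses 2000 training and 1000 held-out users at a
500-word vocabulary for recovery; 300 users over three 6-month windows for
retest; 20 resampled refits for the dropout contrast; 200 Monte-Carlo
corpora of 1000 terms for FDR control; and 20,000 users for the null
prediction checks, where the spurious-fit scale $\sqrt{p/n}$ must sit well
inside the tolerance bands. These sizes are chosen so each property is
measured with comfortable statistical margin at desk scale.

Degenerate inputs are handled explicitly rather than silently: constant
term columns (flagged, excluded from FDR), constant score columns in
alignment (correlation treated as 0 with a warning), single-class targets
(skipped with a warning), degenerate covariates (dropped with a warning),
flat scree spectra (low-confidence flag), users with no in-vocabulary
tokens (dropped with a warning), and non-convergent EM (an error naming the
iteration cap).

## Known limitations

* The EM estimator returns one local maximum; the deterministic
  principal-axis start makes it reproducible and, on the tested problems,
  at least as good as 200 random restarts, but global optimality is not
  guaranteed.
* Acceleration-based scree selection is sensitive to unequal factor
  strength (see above); the factor count is a scientist's decision that the
  function only informs.
* The NMF uses multiplicative updates with a fixed seed; like all NMF it is
  non-convex, and different seeds can find different (usually equivalent)
  block structures.
* Likes targets, covariate handling and residualization assume users are
  exchangeable rows; no user network or temporal drift in demographics is
  modelled.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg <- synth_config(n_users = 500, vocab_size = 200, n_factors = 3, seed = 1)
pop <- generate_population(cfg)
corpus <- generate_messages(pop)

model <- corpus |>
  filter_users(min_words = 1000) |>
  induce_traits(k = 3, top_k = 200, rotation = "promax")

# recovery of the planted traits
truth <- pop$traits[[1]]
rownames(truth) <- pop$demographics$user_id
align_factors(model$scores, truth)

# differential language analysis
utm <- build_user_term_matrix(corpus, model$vocabulary)
dla <- correlate_words(utm, model$scores)
top_words(dla, factor = 1, n = 10)

# predictive validity with demographic covariates
outcomes <- generate_outcomes(pop)
feats <- add_covariates(model$scores, outcomes)
evaluate_regression(feats, outcomes$log_income[match(rownames(feats),
                                                     outcomes$user_id)],
                    outcome_name = "log_income", feature_name = "FA3+Demog")
```
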