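# newsworthy

Which published health science articles get a press release from their
journal, and which get picked up by mainstream news? `newsworthy` is an R
package for studying both questions quantitatively from article content
alone. It is aimed at health-communication and biomedical-NLP researchers
who have (or can construct) corpora of citations — title, abstract, MeSH
headings — labeled by press-release issuance (PR) or news coverage (NC).

## What it implements

**Matched case-control corpora.** Negatives are sampled for each positive
from the same journal and issue (or year/volume), up to a per-positive cap
(10 for PR-style corpora, 20 for large NC-style corpora), uniformly without
replacement and globally deduplicated, so venue and time are controlled and
only content varies.

**Prefixed n-gram featurization.** Sparse counts of uni- and bigrams from
titles (`TI-` prefixed, also emitted plain), abstracts (plain), and MeSH
headings (`MH-` prefixed, e.g. `MH-great-britain`, with bigrams over
adjacent headings). Stop words are removed before n-gram formation;
features must appear in ≥ 2 documents; at most the 50,000 most frequent
are kept.

**Regularized logistic regression with nested cross-validated AUC.** The
model minimizes

    1/2 ||w||² + λ · Σᵢ log(1 + exp(−yᵢ (wᵀXᵢ + w₀))),   yᵢ ∈ {−1, +1}

with an unpenalized intercept — note that *smaller* λ means *stronger*
regularization. Performance is the five-fold cross-validated AUC with λ
chosen per fold by nested cross-validation over the logarithmic grid
10⁻⁵ … 10². The solver is a sparse Newton-CG (liblinear-style), verified
in the tests against an independent dense Newton oracle and glmnet.

**Bootstrap feature ranking.** 1000 document resamples, a refit per
resample, normal-approximation 95% intervals (mean ± 1.96 SD), and
ranking by CI *lower* bound (positive features) or *upper* bound (negative
features), reporting the top 25 of each plus kernel density summaries of
replicate coefficients.

**Supervised topic model (sLDA).** A K = 20-topic model in which each
document's label is drawn from a softmax over its empirical topic
frequencies z̄ (`softmax_c(η_cᵀ z̄)`), fit by variational EM with a
monotone evidence lower bound; each topic is reported with its response
coefficient, prevalence, and 10 most probable words.

**Seeded synthetic corpora** (`make_discriminative_corpus()`,
`make_slda_corpus()`) emulate the statistical shape of the study corpora —
title/abstract lengths of 13 (5) / 214 (67) words, Zipf-tailed
vocabularies, 5–14% positive rates — with planted, recoverable signals, so
every stage is testable without the original datasets.

## Worked example

Generate a small planted-signal corpus, evaluate the classifier, and rank
robust features:

```r
library(newsworthy)

spec <- discriminative_spec(n_pos = 60, n_neg = 340, vocab_abstract = 800,
                            abstract_len = c(80, 20), seed = 42)
corpus <- make_discriminative_corpus(spec)
corpus
#> <news_corpus> 400 citations (60 positive, 340 negative, 0 unlabeled)
#>   task: PR, feature source: article

vocab <- build_vocabulary(corpus, feature_config())
X <- vectorize(corpus, vocab)
cv <- cross_validate(X, corpus$citations$label, k = 5, seed = 1)
cv
#> <cv_result> 5-fold mean AUC 0.779 (SD 0.089; range 0.694-0.908)
#>   selected lambda per fold: 100, 100, 10, 100, 100

lam <- select_lambda(X, corpus$citations$label, seed = 2)
bs <- bootstrap_coefficients(X, corpus$citations$label, lambda = lam,
                             B = 200, seed = 3)
rank_features(bs, "positive", top_n = 5)
#> # A tibble: 5 × 6
#>    rank feature          mean     sd ci_lower ci_upper
#>   <int> <chr>           <dbl>  <dbl>    <dbl>    <dbl>
#> 1     1 alcohol         1.35  0.123     1.11     1.59
#> 2     2 MH-mass-media   1.13  0.135     0.871    1.40
#> 3     3 TI-breakthrough 0.977 0.0925    0.796    1.16
#> 4     4 breakthrough    0.977 0.0925    0.796    1.16
#> 5     5 aw0002 alcohol  0.386 0.108     0.174    0.597
```

The three planted features (`alcohol` in abstracts, the `mass media` MeSH
heading, `breakthrough` in titles) head the ranking: their CI lower bounds
sit far above every background feature, which is exactly how the method
separates robust predictors from noise. The mean AUC of 0.78 on this small
corpus reflects a ~0.93 Bayes ceiling (label noise is part of the
generative design) minus estimation loss at 400 documents; the cap of the
λ grid being selected indicates weak regularization wins when the signal
is sparse and strong.

`run_pipeline()` ties the stages together (CV report, top-25 positive and
negative feature tables, coefficient densities, sLDA topic report, and a
JSON manifest with every seed recorded), and `read_corpus()` /
`sample_matched_negatives()` build labeled corpora from JSONL, CSV or
MEDLINE exports of your own citation data.

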