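# soclisten

Analytics core for taxonomy-driven social listening during health
emergencies, for infodemic managers, epidemiologists and computational
social scientists who need to turn large volumes of public social posts
into category-level insight: *what* people are talking about, *who* is
talking, *whether* they are asking questions, and *when* a topic suddenly
accelerates.

## What it does

**Categorization.** Posts are classified into a configurable public-health
taxonomy (topics → categories → seed keyword phrases) by keyword-seeded
semisupervised learning. Posts become nodes of a similarity graph (cosine
similarity of tf-idf unigram vectors, k-nearest-neighbor sparsified), posts
matching seed keywords receive seed distributions
`r_i(c) = hits_i(c) / Σ_c hits_i(c)`, and **measure propagation** diffuses
probability distributions over categories across the graph by alternating
closed-form minimization of

```
C(p,q) = Σ_{i∈S} KL(r_i ‖ q_i) + μ Σ_{ij} w′_ij KL(p_i ‖ q_j) + ν Σ_i KL(p_i ‖ u)
```

Each post gets one category (max posterior, deterministic tie-break) or
`NOISE` when it fails the content prefilter (hashtag/mention-only) or its
distribution stays indistinguishable from uniform — no category signal
reached it.

**Baseline and evaluation.** A Boolean OR-query baseline fed exactly the
same keywords; per-category and macro precision/recall/F1 with explicit
degenerate-denominator flags; a paired Hotelling T² omnibus comparison of
two methods on per-category (precision, recall) vectors; a seeded
annotation-sampling helper.

**Segmentation.** Pluggable author-type/gender classification (rule-based
default: organization cue lexicon, then gendered given-name lookup) and
question-intent detection (rule-based default: `?` outside URLs and quoted
spans, with an ad/headline blocklist).

**Velocity alerts.** ISO-week volumes per country × category (optionally ×
segment × question), velocity `V_i = (Vol_i − m_i)/m_i` against the
trailing 4-week mean `m_i`, flagged when `V_i ≥ 0.15`.

**Synthetic corpora.** A generator with planted category vocabulary,
ambient-only noise posts, deterministic weekly volumes with spike
schedules, known gender/organization/question proportions, and a spike
ledger of the (category, week) pairs that must alert — so every stage is
testable without platform data.

## Worked example

```r
library(soclisten)

spec <- synthetic_spec(seed = 2024)      # 3 categories, 20% noise, one 3x spike
b <- generate_corpus(spec)

res <- classify_corpus(b$posts, b$taxonomy)
res
#> <classification_result: 1188 posts, 90.7% categorized>

ev <- evaluate_predictions(b$gold, res, category_ids(b$taxonomy))
metrics_report(list(en = list(algorithm = ev$macro)))
#> # A tibble: 1 × 5
#>   language method    precision_pct recall_pct f1_pct
#> 1 en       algorithm          88.0       99.2   93.2
```

90.7% of posts were categorized (the planted noise fraction is 20%; the
rest is dismissed by the noise rule), and the propagation recovers the
planted categories at macro-F1 93.2%. The Boolean baseline on the same
keywords reaches only F1 71.1% (perfect precision on this separable
corpus, but recall 55.2% — it can only find posts that literally contain a
keyword, while propagation labels their graph neighbors too).

```r
labeled <- dplyr::inner_join(b$posts, res$assignments, by = c(id = "post_id")) |>
  dplyr::rename(category = label)
labeled$post_id <- labeled$id
alerts <- velocity_alerts(aggregate_weekly(labeled, by = c("country", "category")))
alerts[alerts$flagged, ]
#> # A tibble: 1 × 8
#>   country category week       volume baseline_mean velocity flagged new_topic
#> 1 GB      cat01    2021-03-01     82            31     1.65 TRUE    FALSE
```

The single flagged week is exactly the generator's planted spike
(category `cat01`, week 9): volume 82 against a trailing 4-week mean of
31 gives velocity +165%, far above the 15% alert threshold.

See the methods vignette (`vignettes/social-listening-methods.Rmd`) for
the model, parameter defaults and their rationale, and what the synthetic
tests do and do not establish.

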