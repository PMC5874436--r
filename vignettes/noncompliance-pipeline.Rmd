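---
title: "Detecting medication noncompliance in forum posts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting medication noncompliance in forum posts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonadh)
```

`nonadh` detects forum posts in which patients describe noncompliant
behavior toward a drug — stopping the treatment on their own, or changing
its dose without medical advice. The pipeline is unsupervised: a topic model
clusters the corpus, a human labels the topics from their leading terms, and
messages associated with noncompliance-labeled topics are extracted. This
vignette documents the model, its tunable parameters, the numerical and
design choices, what the synthetic benchmark does and does not show, and the
known limitations.

## Preprocessing

Raw messages pass through six steps, in this order:

1. **Dosage standardization.** Every maximal match of
   *number (+ optional decimal with `.` or `,`) + optional space + dosage
   unit* is replaced by the literal token `dosemilligrams`
   (`standardize_dosage()`). The unit list (`mg`, `milligramme(s)`, `g`,
   `mcg`, `µg`, `ml`, ...) is configurable. This runs *before* tokenization,
   because the number and the unit are separated by a space that
   tokenization would split; digits embedded in words (`b12`) are not
   treated as doses.
2. **Lower-casing and tokenization.** Unicode punctuation, symbols and
   separators (including non-breaking spaces) become spaces; apostrophes
   separate, so French elisions split (`l'arrêt` → `l`, `arrêt`).
   Lower-casing is locale-independent (explicit accent mapping).
3. **Stopword removal.** Exact membership against a configurable list; a
   standard French function-word list ships with the package
   (`default_stopwords()`) and is fully overridable.
4. **Drug-name removal.** The drug used to build the corpus appears in
   every message, so it carries no topical signal and is removed. Matching
   is exact; misspellings are retained (fuzzy matching is out of scope).
5. **Stemming.** The Snowball French stemmer, implemented in the package
   (`stem_french()`): vowel marking, RV/R1/R2 regions, standard-suffix
   step, the two verb-suffix steps, residual suffixes, undoubling and
   accent removal. The classic algorithm variant is implemented (without
   the later `ë`/`ï` revision, which only affects a handful of rare words).
   The French variant is the right member of the Porter family for these
   corpora; the token `dosemilligrams` is protected from stemming.
6. **n-grams.** Unigrams plus adjacent bigrams joined with `_`, with
   adjacency measured *after* filtering and stemming, so collocations such
   as `effet_secondair` survive stopword removal.

Steps 1–4 are idempotent and all steps are deterministic; stemming, like
every Porter-family stemmer, is not guaranteed idempotent on its own output,
which is why the bigram stage works from a single stemming pass.

## Document–term matrix and vocabulary selection

`build_dtm()` produces a sparse documents × terms matrix of occurrence
counts. Counts (not 0/1 indicators) are kept because both TF–IDF and the
multinomial topic-model likelihood need frequencies; the 0/1 view appears
only where it belongs, in the document frequencies and sparsity
computations.

Vocabulary selection (`select_vocabulary()`) scans candidate per-term
sparsity thresholds downward from 0.9995 to 0.80 in steps of 0.00025. At
each candidate, terms whose per-term sparsity (fraction of documents lacking
the term) exceeds the candidate are dropped and the overall sparsity of the
reduced matrix is computed; the scan stops at the first (largest) candidate
whose reduced matrix reaches the target overall sparsity (default 0.97).
The target is an *upper bound crossed from above*: the returned matrix's
sparsity is typically just below it. This removes rare tokens — mostly
misspellings, one-off bigrams and abbreviations — while keeping vocabulary
the patients actually share. Documents emptied by the reduction are dropped
and logged (`drop_empty_documents()`).

TF–IDF weighting is `w_dv = (x_dv / n_d) · log2(D / df_v)`: term frequency
normalized by document length times base-2 log inverse document frequency,
the convention of the classic R text-mining stack. A term present in every
document weighs zero everywhere.

## MAP-EM estimation of the topic model

`lda_map()` maximizes the LDA posterior over θ (document–topic weights) and
φ (topic–term probabilities) with symmetric Dirichlet priors. The objective
includes the full normalized Dirichlet log densities, so log-posterior
values are comparable across different K. The EM updates are

- E-step: responsibilities `r_dvk ∝ θ_dk φ_kv`, normalized over topics;
- M-step: `θ_dk ∝ Σ_v x_dv r_dvk + (α_θ − 1)` and
  `φ_kv ∝ Σ_d x_dv r_dvk + (α_φ − 1)`, each floored at `1e-12` before
  normalization.

Numerical choices:

- **Hyperparameters** default to `α_θ = α_φ = 1.1`. Values strictly above 1
  make the MAP estimate strictly interior (the `α − 1` pseudo-counts are
  positive), so no topic or term probability collapses to zero and the
  closed-form M-step is exact.
- **Initialization.** θ starts uniform; φ rows are drawn from a symmetric
  Dirichlet(1.5) with the run seed (restart *i* uses `seed + i − 1`).
  Randomizing only φ breaks the label symmetry while keeping fits exactly
  equivariant under document permutation — permuting the input rows permutes
  θ and leaves φ unchanged at the same seed, which a per-document random
  initialization could not guarantee.
- **Convergence** when the relative log-posterior change drops below `tol`
  (default `1e-6`) or after `max_iter` (200) iterations; the trace is
  non-decreasing by the EM ascent property and is stored in the fit.
- **K = 1** uses the exact closed form (prior-smoothed corpus term
  frequencies; θ ≡ 1).
- **Degenerate inputs**: all-zero document rows are rejected with a pointer
  to `drop_empty_documents()`; `K > V` warns.
- **TF–IDF input mode**: the multinomial likelihood is defined for counts,
  so TF–IDF weights are scaled ×10 and rounded to integer pseudo-counts.
  Both the count route (default) and the weighted route are provided; which
  a given study used is rarely recoverable, and the count route is the
  statistically cleaner default.

## Choosing the number of topics

`select_num_topics()` fits every K in the grid and compares approximate log
marginal likelihoods through the log Bayes factor
`BF(K) = log m(K) − log m(1)` against the one-topic model; the selected K
maximizes BF, and the one-topic model wins when no BF is positive. The
marginal likelihood uses a BIC/Laplace-style surrogate — maximized log
posterior minus `(df/2)·log N`, `df = K(V−1) + D(K−1)`, N the token count.
Any consistent penalized-likelihood surrogate preserves the selection
semantics; this one is simple, deterministic and testable. On synthetic
corpora the selector finds K = 1 on single-topic data and the planted K on
well-separated mixtures; on preprocessed *text* (where bigrams add
correlated structure on top of the planted unigram process) it tends toward
the upper end of the grid, which is why the benchmark labels fitted topics
rather than assuming a one-to-one match with the planted ones.

## Message–topic association and extraction

The association of a single token occurrence with a topic is its MAP topic
under the fitted model, `argmax_k θ_dk φ_kv` (ties to the lowest index).
A message is associated with topic k when the fraction of its in-vocabulary
token occurrences with MAP topic k reaches τ (default 0.25, set empirically;
at most `⌊1/τ⌋` topics per message can pass). Repeated occurrences count
multiply — "25% of the tokens" reads as token occurrences — and
out-of-vocabulary tokens are excluded from the denominator because the model
carries no information about them. Raising τ never enlarges an assignment
set. Documents outside the training set are folded in by EM over θ with φ
fixed.

Topic labels are external input (`read_topic_labels()`): topics are
interpreted by a human from their first 15 terms (`top_terms()`, ties broken
alphabetically) and the labels `treatment_cessation` and `dosage_variation`
mark the noncompliance topics. `extract_flagged()` collects the message ids
per noncompliance label, their intersection, and the union.

## Evaluation arithmetic

`precision_pct()` and `recall_pct()` report percentages rounded
half-away-from-zero to one decimal (the convention of published annotation
tables); corpus-level rates (`noncompliance_rate()`) use two decimals.
`cohen_kappa()` is the standard chance-corrected agreement,
`κ = (p_o − p_e)/(1 − p_e)` with expected agreement from the marginal
products. `sample_for_review()` draws a seeded simple random sample of
`⌈fraction · n⌉` ids; the ceiling rule is chosen because it reproduces the
conventional review-set sizes for 20% sampling at both n = 1723 (345) and
n = 3246 (650), which round-to-nearest does not. Manual verdicts enter
through a reviewed-outcomes CSV; the package never infers truth labels.

## The synthetic benchmark

Real patient-forum corpora cannot be redistributed, so every end-to-end test
runs on `generate_corpus()`: posts drawn from the LDA generative process
with `D` documents, a content vocabulary of `V` synthetic stems (`w001`,
...), `K_true` planted topics drawn from a sharply peaked Dirichlet
(`topic_peakedness = 0.05`), document-topic weights from
`Dirichlet(alpha_doc = 0.3)` (short posts dominated by one or two themes),
and Poisson(60) lengths. Two planted topics carry curated French-like seed
stems — cessation (`arret`, `stop`, `cess`, ...) and dosage (`dos`,
`augment`, `baiss`, ..., plus a dosage symbol rendered as literal strings
like `10 mg`). Rendering inserts the drug name exactly once per post,
stopwords at rate 0.3, and sentence punctuation. The gold noncompliance flag
is generative: a document is gold-flagged when its true mass on any
noncompliance topic reaches 0.5 — ground truth is unambiguous and
independent of surface wording.

The default generator settings (`D = 500`, `V = 200`, `K_true = 5`, Poisson
mean length 60) are the package's standard benchmark conditions; the test
suite uses them for the topic-recovery and end-to-end properties, smaller
instances (`D = 400, V = 150, K_true = 3` over 20 seeds; `D = 200, V = 100,
K_true = 1`) for model selection, and a 10,000-message corpus for the
preprocessing grep checks. The benchmark labels fitted topics automatically
by greedy cosine matching against the planted topic-term vectors in stem
space (`planted_phi_stems()`, `match_topics()`) — every fitted topic whose
closest planted topic is a noncompliance topic inherits its label, so splits
of a planted topic are labeled the way a human reading the top terms would
label them.

What passing these tests shows: the estimator recovers well-separated planted
structure, the selection criterion behaves sensibly, and the full pipeline
finds planted noncompliance posts with high recall (precision is reported,
not bounded — the approach is screening, not classification). What it does
not show: performance on real French, which has grammar, spelling noise,
topic drift, multiple experiencers and temporal qualifiers that the
generator deliberately omits (no misspelling simulation, no annotator
disagreement, no realistic syntax). Real deployments still require the
manual review step.

## Known limitations

- Token-level topic association is a modeling decision (per-token MAP under
  the fitted model); other definitions of "token associated to a topic"
  would shift the 25% rule's behavior.
- The marginal-likelihood surrogate is asymptotic; on text with heavy bigram
  structure it favors larger K, so the K grid's upper end should be chosen
  with the corpus size in mind.
- The stemmer implements the classic Snowball French algorithm; words
  relying on the later `ë`/`ï` handling stem slightly differently.
- Precision is intrinsically low: dose talk and stop words-of-speech
  ("j'arrête", "stopper") occur in many compliant contexts; flagged sets are
  candidate sets for review, not final classifications.
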