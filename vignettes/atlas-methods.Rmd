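---
title: "Corpus atlases with litmap: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus atlases with litmap: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmap)
```

This vignette explains the science behind each stage of the pipeline, the
parameters that matter, and the design choices made where several
reasonable options existed. It states no empirical numbers beyond what the
code below computes.

## The problem

A corpus of bibliographic records — titles, abstracts, journal names,
publication years, author names — is turned into an n × 2 map in which
nearby points are topically related papers. Because the map is a lossy
projection, every substantive claim made on it (a literature is isolated,
a field drifts toward another, retractions cluster in a region) must be
backed by statistics computed in the *high-dimensional* representation,
with the map used for navigation and discovery. litmap therefore ships the
embedding and the evaluation machinery together.

## Ingestion and filtering

Records arrive from a MEDLINE-style XML dialect (`read_medline_xml()`) or
delimited text. Cleaning and filtering follow fixed rules:

* structured abstracts are flattened to one paragraph, dropping section
  labels;
* the legacy `"(ABSTRACT TRUNCATED AT <n> WORDS)"` phrase is removed and
  the remaining text analysed as usual;
* records are rejected when non-English, empty, shorter than 250 or longer
  than 4,000 characters (inclusive bounds are kept), or *unfinished* — not
  ending with `.`, `?` or `!`. Unfinished abstracts matter because
  truncated texts otherwise co-embed into artifact clusters;
* duplicated pmids keep their first occurrence. Deduplication is a
  correctness choice here; it can be disabled with `dedupe = FALSE`.

Character counts are taken on the *cleaned* text, so the truncation-phrase
removal happens before the length filter. Rejections are returned as data
(a per-reason log), never raised as errors, and filtering is idempotent.

Labels come from journal titles: a record is labelled with a keyword
(default: the built-in 38 discipline terms) iff the title contains it,
matched case-insensitively — a deliberate superset of "term or Capitalized
term" that treats ALL-CAPS journal titles uniformly; `word_boundary = TRUE`
is available because raw substring matching is a dialect choice, not a
fact. Multi-keyword titles are resolved by a seeded uniform draw, so
labelling is deterministic given the seed and seed-independent without
ties.

## Gender inference

Forenames are the first whitespace-delimited word of the ForeName field
after hyphen replacement; single characters (initials) are discarded.
Gender is looked up in a (name, year) table of proportion-female values,
with years clamped to the covered range (1930–2012 for the packaged
table) — naming practices drift, so the year matters. The packaged table
is **synthetic**: a hand-built set of 26 forenames with plausible
trajectories (including names whose majority gender flips over the
century), sufficient for testing the machinery. Real analyses should
supply registry-derived tables via `name_gender_table()`. The majority
rule is `female iff proportion > threshold` (default 0.5); an exact tie is
called male, a documented convention rather than a claim.

## Vectorization

TF-IDF uses logarithmic count scaling and smoothed inverse document
frequency; zero counts stay exactly zero, so sparsity is preserved, and
rows are scaled to unit l2 norm. The tokenizer (lowercase, runs of ≥ 2
word characters, no stop-word removal) is configurable; tokenization
details change vocabulary size substantially but affect neighbourhood
structure little.

`reduce_svd()` computes the top-d singular subspace with a dense SVD —
adequate at the scales this package targets (tens of thousands of
documents); the contract is the output up to component sign, which is
canonicalized by making each component's largest-magnitude loading
positive. Optional row normalization of the reduced scores makes Euclidean
search equivalent to cosine similarity, which tends to help TF-IDF-derived
spaces. `transform_vectors()` offers centering and PCA whitening (with an
eigenvalue floor of 1e-10 relative for rank-deficient input) because
whitening is a common preprocessing question for transformer vectors; it
is an option, not a recommendation.

## The embedding

Standard t-SNE calibrates a per-point Gaussian bandwidth to a target
perplexity. At corpus scale this is expensive and unnecessary: *uniform
affinities* place weight 1/k on each of the k = 10 nearest neighbours and
symmetrize, giving a sparse graph with total mass 1. The low-dimensional
kernel is the Student-t; the loss is the KL divergence.

Optimization choices, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| k | 10 | matches the evaluation statistics; denser graphs mostly add memory |
| iterations | 2,250 = 250 + 2,000 | extended run for convergence on large graphs |
| exaggeration ρ | anneals 12 → 1 over 250 iters | annealing avoids the abrupt-switch shock; 12 is the conventional start; the annealing curve is linear, the simplest monotone choice |
| learning rate | n/12 | scales the step with graph mass |
| init | first 2 PCs, sd(PC1) = 1e-4 | preserves global structure; small scale keeps early exaggeration stable |
| momentum | 0.5 then 0.8 | standard optimizer phases |
| gains | ±0.2 / ×0.8, floor 0.01 | standard per-coordinate adaptation |

Repulsion is exact O(n²) by default (`repulsion = "exact"`), the reference
implementation at desk scale; `repulsion = "bh"` switches to a Barnes–Hut
quadtree (θ = 0.5), which the test suite holds to within 5% of the exact
optimizer's final KL. The KL trace is logged every iteration (computed
with the current partition function, so in BH mode it is itself an
approximation) plus one final entry. Approximate nearest neighbours
(NN-descent) are available for graph construction and are held to ≥ 95%
recall against exact search.

Numerical notes: distance ties in kNN search break towards the lower
index; the optimizer is deterministic given the initialization; embeddings
are recentred each iteration. The t-SNE loss is invariant to rotations and
sign flips of the *output*, so `align_orientation()` exhaustively checks
the four axis-sign combinations against a reference embedding and keeps
the one maximizing summed per-axis Pearson correlation — sufficient
because t-SNE runs initialized from (sign-canonicalized) PCA differ
essentially by flips, not arbitrary rotations.

## Evaluation statistics

All statistics use exact k = 10 nearest neighbours and never let a point
be its own neighbour. Majority-vote ties go to the nearest neighbour whose
label is among the tied labels — deterministic and documented. Default
metric is squared Euclidean; cosine is available and is what
row-normalized SVD effectively uses.

* **Accuracy** is measured on a random test set of labelled points, with
  neighbours searched among the remaining labelled points. The chance
  baseline predicts by sampling from the training label distribution, so
  its expectation is the sum of squared label proportions.
* **Year RMSE** averages neighbour years; for k iid neighbours with
  within-cluster year s.d. σ the error is σ√(1 + 1/k), a closed form the
  suite checks at 10% tolerance. The chance mode draws k random training
  papers, giving σ_pop√(1 + 1/k).
* **Recall** is the mean overlap of high-D and 2D neighbour sets; a random
  layout gives the hypergeometric mean k/(n−1).
* **Isolatedness** is the mean fraction of a corpus member's neighbours
  (searched over the whole dataset) inside the corpus, estimated on up to
  5,000 sampled members by default.
* **Overlap-by-year** samples up to 500 source papers per year (all of
  them when fewer exist) and averages the fraction of their neighbours
  carrying the target label; smoothing is the trends module's job.
* **Region fractions** count flagged and total points inside a box or
  polygon, boundary inclusive. Region geometry is user input — published
  inset regions are rarely specified exactly, so the package takes
  arbitrary polygons rather than guessing.

## Trends

`yearly_fraction()` returns per-year numerators, denominators, fractions
and Wilson 95% intervals; the terminal year can be excluded because the
newest year of a bibliographic snapshot is systematically incomplete. For
authorship trends the denominator should be the gender-resolved papers
only (`denominator =`), matching the "among those resolved" convention.

`fit_trend()` fits a penalized-spline GAM with year as sole predictor:
Gaussian-identity with 6 cubic regression spline basis functions for
continuous responses (e.g. overlap series), binomial-logit with 12 for
binary responses (e.g. mentions a term; female first author). The penalty
is selected by generalized cross-validation, the R-side equivalent of a
cross-validated grid search; `smoothing = "fixed"` pins it. Intervals are
pointwise 95%, computed on the link scale and back-transformed, so
binomial curves stay in (0, 1). Two numerical facts worth knowing: the
penalty's null space is *linear*, so the infinite-smoothing limit is the
least-squares line, not a constant; and `n_splines` caps the basis, with
the penalty choosing effective smoothness below it.

## The synthetic test bed

`generate_records()` emulates exactly the features the pipeline consumes:

* **abstracts** are per-topic multinomials over a topic vocabulary mixed
  (45/55) with shared stop-words — the minimal structure TF-IDF can
  separate; at least 250 characters, ending with a period;
* **journal titles** embed the topic's keyword into one of five templates,
  so journal-based labelling can recover the topic;
* **years** are per-topic Gaussians rounded to integers and truncated to
  the configured range (default 1970–2021), reproducing per-topic age
  structure;
* **author forenames** are drawn from the name table conditional on a
  Bernoulli gender draw with the topic's female-proportion-by-year
  function, so gender inference recovers configured trajectories;
* **retraction flags** are per-topic Bernoulli draws; the default topic
  set gives one topic a 5% rate against a 0.5–1% background, emulating a
  retraction-enriched field.

`generate_vector_mixture()` skips text and emits unit-variance spherical
Gaussians at regular-simplex vertices scaled so centres are pairwise
`cluster_separation` within-cluster standard deviations apart (exact when
the dimension is at least the number of topics minus one; lower dimensions
place centres on a sphere of matching radius). Separation is the one knob
that matters: 0 gives chance-level structure, 8–10 gives essentially
perfect recoverability, and kNN accuracy is monotone in between.

Reproducibility: one master seed feeds per-stage child seeds
(`child_seeds()`), so each stage is independently reproducible and the
caller's RNG state is never disturbed.

**What passing tests show — and what they do not.** The generators produce
well-separated, isotropic, stationary clusters with clean metadata. Real
abstracts have heavy-tailed vocabularies, overlapping topics, hub
structure in the kNN graph, label noise from interdisciplinary journals,
and missing metadata. Passing the suite therefore certifies the
*machinery* — formulas, invariants, limits, convergence behaviour — not
the empirical performance figures any particular real corpus would yield.

## Problem sizes

The suite exercises the full 2,250-iteration pipeline at n = 5,000 /
d = 100 / 10 topics (Barnes–Hut), oracle comparisons at 200–500 points,
closed-form checks at n = 10,000–50,000, and the remaining unit tests at a
few hundred points each — sizes chosen so the whole suite documents the
method's behaviour while running comfortably on a laptop. The end-to-end
script (`scripts/acceptance.R`) uses 8,000 papers for the same reason.

## Known limitations

* Dense SVD and O(n²) or BH-quadtree kernels target desk scale (up to
  ~10⁵ points), not the tens of millions the same design supports in
  optimized implementations.
* The packaged name-gender table is synthetic; substantive gender analyses
  require registry data supplied by the user.
* Journal-keyword labels are a proxy, not ground truth: interdisciplinary
  journals are unlabeled by construction, so 100% kNN accuracy is not the
  ceiling on real corpora.
* The BH-mode KL trace uses the approximate partition function; compare
  embeddings across modes with an exact evaluation pass (a 0-iteration
  schedule) as the test suite does.
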