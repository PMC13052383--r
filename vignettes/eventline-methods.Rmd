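---
title: "From fragmented life stories to event timelines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fragmented life stories to event timelines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventline)
```

## The problem

Reminiscence interviews with older adults produce transcripts that are
fragmented (one life event per short segment, narrated out of order),
redundant (the same wedding retold across sessions), and temporally vague
(explicit years, "three years ago", references to public history, or no
time cue at all). Caregivers need those narratives as a chronological event
timeline. `eventline` implements that transformation end to end, together
with the metrics to judge the result and a synthetic-corpus generator so
every stage can be validated without access to any sensitive interview
data.

## Event representation and extraction

Each event is the 6-tuple (type, trigger, time, location, participants,
summary). Extraction is template-driven: a template names an event type,
its trigger lexicon, and regular-expression patterns for the time,
location, and participant slots. Every trigger occurrence yields one event;
when several templates claim the same trigger, *all* matches are reported
and the ambiguity is recorded, because silently picking a winner would hide
a modelling decision from the user.

Coreference linking compares candidate mentions (maximal capitalized word
runs) pairwise by embedding cosine, inside a sliding window of 512 tokens,
accepting links at similarity ≥ 0.8; chains are the transitive closure of
accepted links and each chain is represented by its earliest mention.
Transitive closure is chosen for determinism — pairwise thresholds alone do
not induce a partition.

Summaries are extractive: candidate sentences are scored for salience (the
shipped scorer is TF-IDF-centroid cosine; any scorer can be substituted)
and up to three are selected by maximal marginal relevance. The MMR
trade-off `diversity_weight` defaults to 0.7 — the selection rule is
specified exactly, the trade-off value is not, and 0.7 is the conventional
"mostly relevance, penalize redundancy" operating point. With
`diversity_weight = 1` the selection provably reduces to top-k salience,
which the tests assert.

The neural sentence encoder behind the published system is abstracted to an
embedder contract (`dimension`, `embed()`); the shipped implementation is a
deterministic hashed bag-of-tokens embedder. That keeps the whole package
dependency-free and reproducible, at the cost of purely lexical similarity
— a paraphrase with disjoint vocabulary will not link. Tests and the
synthetic generator are designed within that limitation, and a stronger
encoder can be plugged in unchanged.

## The relevance model

Event features `Φ` (n × m) feed a graph model whose graph is thresholded
cosine similarity: direct neighbors above `τ1 = 0.6`, and second-hop
neighbors reachable through a direct neighbor with similarity above
`τ2 = 0.8`. Attention scores `θ_ij = LeakyReLU(aᵀ[Wh_i ‖ Wh_j])` are
softmax-normalized over the *union* of direct and indirect neighbors, which
is the multi-hop extension: influence reaches two hops while the thresholds
keep the graph sparse. Nodes with no neighbors fall back to self-attention.
Multi-head attention averages the per-head pre-activations before the
output nonlinearity (exponential linear unit by default; the source
formulation never names σ, and ELU is smooth and sign-preserving for
attention sums — it is configurable).

The compression stream is a stack of logistic layers
`h⁺ = sigmoid(Wv + b)`. The two streams interleave: round r feeds the
concatenation of the previous attention output and hidden state back into
the next attention layer, two rounds by default.

Self-supervision follows deep embedded clustering: hidden features get a
Student-t soft assignment `D` against k centroids (exponent `−(v_c+1)/2`,
`v_c = 1` — the standard kernel; the printed exponent in the source
formulation is ambiguous after text extraction), the sharpened target is
`p_ij ∝ d_ij²/f_j` with cluster frequency `f_j = Σ_i d_ij`, and the joint
loss is

`L = λ1·KL(P‖K) + λ2·KL(P‖D)`, `λ1 = 0.7`, `λ2 = 0.3`,

where `K` is a row-softmax linear head on the final attention output — the
minimal construction making the attention stream emit a row-stochastic
distribution to be supervised by `P`. Optimization is AdamW (weight decay
0.01 on weights only), linear warmup over the first 10% of steps then
linear decay, dropout 0.5 on attention coefficients. Gradients are central
finite differences over the flattened parameter vector: the model is
desk-scale by design (tens of events, tens of parameters per layer), the
finite-difference step (1e-4) is far below the loss curvature at these
scales, and it keeps the loss definition itself the single source of truth
instead of a second hand-derived backprop implementation. Runs are
bit-reproducible for a fixed seed, which the tests assert.

Two schedule choices matter:

* **P is refrozen at every epoch boundary** (the usual DEC alternation).
  Consequently the loss is only monotone *within* an epoch; the acceptance
  test for the "loss decreases" property is therefore asserted within each
  of the first two epochs against their own frozen targets.
* **The similarity graph is built once from `Φ` and kept fixed.** An
  earlier revision recomputed it each epoch from current hidden features,
  but logistic outputs concentrate near 0.5, their cosine matrix is ≈ 1
  everywhere, and the recomputed graph degenerates to a complete graph that
  mixes clusters (planted-blob recovery fell from 1.0 to chance). The
  source describes the neighborhoods as dynamic without fixing a schedule;
  fixed-from-input is the variant that preserves the structure the
  attention is supposed to exploit.

k is chosen by mean silhouette with an elbow (second difference of
within-cluster sum of squares) tie-break, then smaller k; constant features
degrade to k = 2 with a warning.

## Correlation fusion

Two clustering views of the learned features become the final correlation
matrix. The k-means view scores co-clustered events by
`1 − ‖h_i−h_j‖ / (2·r_max)` with `r_max` the cluster's maximal
member-to-centroid distance — the "relative centroid distance" made
scale-free and bounded in [0, 1] (the exact mapping is interpretive; this
normalized-radius form is documented as such). The DBSCAN view scores
same-cluster events by `1/(1 + hops)` on the eps-neighborhood graph, so
direct density neighbors score 1/2; noise points and cross-cluster pairs
score 0 in both views, which preserves the stated "zero correlation for
non-co-clustered pairs" rule through the fusion `Rel = w·C_km + (1−w)·C_db`
(`w = 0.5`; no value is stated). DBSCAN defaults are
`eps = 0.5 × median pairwise distance`, `min_pts = 4` — unstated in the
source; the median-based eps adapts to the feature scale and `min_pts = 4`
is the classic 2·dim rule-of-thumb for low-dimensional embeddings. A fully
noisy density view falls back to the k-means view with a warning rather
than halving all correlations.

## Timeline generation

Temporal normalization maps 4-digit years to absolute timestamps, "N years
ago" (digits, English number words, Chinese numerals with 年前) against the
narration reference year, and everything else — including vague adverbs
like "back then" — to *unknown*, to be sequenced by relevance. Events still
undated are compared against a historical anchor database: best cosine
similarity above 0.85 assigns the anchor's year outright; similarity in
[0.70, 0.85] assigns it *flagged for human review* with confidence equal to
the similarity (flagged anchors do enter the backbone by default and carry
the flag into the output; `exclude_flagged` reroutes them to the undated
pool instead — the source leaves this open).

Dated events sort into the backbone (stable tie-break by narrative order).
Undated events are inserted greedily in transcript order: gap i (with
virtual start and end nodes whose relevance is 0 — the only reading that
makes the boundary gaps well-defined) scores
`α·Rel(e_i, e_u) + (1−α)·Rel(e_u, e_{i+1})`, ties resolved by narrative
proximity of the flanking real events, then by the earlier gap. `α = 0.5`
(symmetric; the parameter is introduced but never assigned). Insertions
extend the timeline immediately and never reorder the backbone — an
invariant under property test. Near-duplicate events are *not* merged:
reproducing the published method includes reproducing its documented
redundancy failure mode; duplicates appear and are reported.

## Metrics

Two SLEU readings are printed in the source and both ship under distinct
names:

* `sleu_hgram()`: h-grams are length-h *subsequences* (`choose(n, h)` of
  them; 6 two-grams in a 4-sentence storyline). A predicted h-gram matches
  a reference h-gram when every position-aligned sentence pair exceeds the
  match threshold (0.2); matching is greedy in lexicographic order without
  reuse from each side (the alignment rule is unstated; this one is
  deterministic and symmetric in expectation), `p_h = min(matched)/C(n,h)`,
  `SLEU = exp(Σ w_h log p_h)`, zero if any `p_h` is zero.
* `sleu_positional()`: `Σ_{h≤3} (1/h)·exp(−0.5·mean|Δrank|)`, normalized by
  `Σ 1/h` so the perfect timeline scores exactly 1 — the printed formula is
  not self-normalizing, and the hop index does not enter the deviation
  term, so the per-event mean deviation reading is used; both choices are
  interpretive and flagged here.

Timeline identity: absolute position deviation is the mean |rank
difference| in raw rank units by default (published values of 2.8–4.5 are
only consistent with raw ranks; normalized i/N mode is available), and
relative order is Kendall τ-a by pair counting. `relative_reduction()`
reproduces workload-table arithmetic; note that one published cell (overall
workload, 37.4) is not reproducible from its own printed means, which give
37.3 — the tests assert the recomputed value.

## The synthetic world

`generate_story()` emulates the structural properties the algorithms
consume, not real linguistic statistics: one event per segment, strictly
increasing ground-truth years over a life course starting at a 1940 birth
year, narration reference year 2023, four thematic life phases sharing
vocabulary (so same-phase events are textually similar under the lexical
embedder), and quota-sampled time modes — defaults 30% undated, 15%
relative, 10% historical, 10% redundant retellings, matching the stated
evaluation conditions (n = 20, 30% undated) and otherwise a plausible mix
of temporal vagueness for oral histories. Quota (not Bernoulli) sampling
makes counts exact and assertable. Historical references embed an anchor
description nearly verbatim, which under the lexical embedder lands at
similarity ≈ 0.83 — inside the human-review band, so flagged anchoring is
exercised on every such corpus. Redundant retellings drop the date token,
reproducing the date-in-one-segment/details-in-another failure input. The
shipped historical table is synthetic (invented names, 1900–2000 years) and
is labelled as such.

A green end-to-end test on this world establishes that extraction,
normalization, anchoring, sorting, and insertion compose correctly — it
does not establish robustness to real ASR noise, paraphrase beyond shared
vocabulary, or genuinely conflicting element mentions.

## Numerical choices

Distributions are floored at 1e-12 before logarithms; KL is computed as
`Σ p log(p/q)` with zero-mass terms contributing zero. Cosine similarity of
a zero-norm row is a validation error in the relevance model (the graph is
undefined) and 0 in lenient contexts (empty text embeddings). Attention
rows with empty neighborhoods use self-attention. k-means re-seeds once on
an empty cluster, then errors. All tie-breaks (backbone years, insertion
gaps, k selection) are deterministic and documented above.

## Known limitations

Lexical embeddings bound coreference and anchoring quality; the
finite-difference trainer is O(#params) per step and is not meant beyond a
few hundred parameters; no deduplication pass (by design, see above); the
h-gram SLEU enumerates `choose(n, h)` subsequences and errors beyond 1e5 of
them rather than sampling.
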