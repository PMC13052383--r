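# eventline

Structuring fragmented life-story narratives into chronological event
timelines.

Reminiscence therapy works from a person's life story, but interview
transcripts arrive fragmented, redundant, and temporally vague: one segment
says "we married in 1962", another retells the wedding without a date, a
third only remembers "it was during the flood". `eventline` turns such
transcripts into an ordered event timeline for caregivers, and ships the
evaluation metrics and a ground-truth synthetic corpus generator needed to
validate every stage offline.

## What it implements

1. **Structured event extraction** — template-driven extraction of the
   event 6-tuple *(type, trigger, time, location, participants, summary)*,
   with embedding-based coreference linking (cosine ≥ 0.8 inside a
   512-token window) and maximal-marginal-relevance summary selection
   (top 3 sentences).
2. **Event relevance model** — a multi-hop graph attention network over the
   thresholded cosine similarity graph (direct neighbors at τ₁ = 0.6,
   second-hop at τ₂ = 0.8):

   α_ij = softmax_j( LeakyReLU(aᵀ[Wh_i ‖ Wh_j]) ) over N_i ∪ I_i

   interleaved with logistic compression layers, trained with the
   deep-embedded-clustering self-supervision loss
   L = λ₁·KL(P‖K) + λ₂·KL(P‖D), λ₁ = 0.7, λ₂ = 0.3
   (Student-t soft assignment D, sharpened target P, attention-head
   distribution K; AdamW, weight decay 0.01, 10% linear warmup,
   dropout 0.5).
3. **Correlation fusion** — k-means (relative centroid distance) and DBSCAN
   (1/(1+path length)) views fused into a symmetric correlation matrix with
   zeros for never-co-clustered pairs.
4. **Timeline generation** — temporal normalization ("1962",
   "three years ago", "三年前", vague → unknown), historical anchoring
   (accept > 0.85, human-review flag in [0.70, 0.85]), chronological
   backbone, and relevance-based greedy insertion of undated events at
   argmax over gaps of α·Rel(e_i, e_u) + (1−α)·Rel(e_u, e_{i+1}) with
   virtual endpoints and narrative-proximity tie-breaks.
5. **Metrics** — SLEU in both published forms (h-gram matching with
   p_h = min(matches)/C(n,h), and positional decay Σ wₕ·exp(−λ·|Δpos|)),
   timeline-identity absolute deviation and Kendall-τ relative order, plus
   ROUGE-N/L and workload-table arithmetic.
6. **Synthetic data** — `generate_story()` builds a fragmented,
   quota-sampled life story (undated / relative / historical / redundant
   mentions) with known ground truth; `generate_clustered_features()`
   plants Gaussian blobs for the relevance model.

## Worked example

```r
library(eventline)

story <- generate_story(sim_config(n_events = 10, undated_fraction = 0.2,
                                   redundancy_rate = 0, seed = 2,
                                   shuffle = TRUE))
story$segments$text[1:2]
#> [1] "In 1961 I celebrated with Little Hua in Nanjing and the family banquet stayed with me."
#> [2] "In 1976 I married with Little Hua in Nanjing and the red lanterns stayed with me."

res <- run_pipeline(story$segments, "run1",
                    config = pipeline_config(
                      training = list(epochs = 1L, steps_per_epoch = 2L),
                      seed = 7),
                    historical_db = story$historical_db,
                    reference_timeline = story$truth_timeline$segment_id)
#> [extract] 0.07s n_segments=10 n_events=10
#> [normalize] 0.09s n_dated=8
#> [train] 2.56s k=3 final_loss=0.03439
#> [relevance] 2.81s n=10
#> [timeline] 2.82s n_positions=10 n_anchored=8
#> [evaluate] 2.82s timid_rp=0.777777777777778

str(res$report[c("n_dated", "timid_ap", "timid_rp", "sleu_positional")])
#> List of 4
#>  $ n_dated        : int 8
#>  $ timid_ap       : num 1
#>  $ timid_rp       : num 0.778
#>  $ sleu_positional: num 0.607

head(as.data.frame(res$timeline), 3)
#>    event_id              kind value confidence flagged anchored position_score
#> 1 ev-000010 historical_mapped  1949  0.7721873    TRUE     TRUE             NA
#> 2 ev-000007           unknown    NA  1.0000000   FALSE    FALSE      0.1468720
#> 3 ev-000008           unknown    NA  1.0000000   FALSE    FALSE      0.1120894
```

Reading the output: 8 of 10 events carried a resolvable time cue (one via a
flagged historical anchor at confidence 0.77 — between the 0.70 review
floor and the 0.85 acceptance bar, so a human should confirm it); the two
undated events were inserted by learned relevance, and the produced order
correlates with the ground truth at Kendall τ = 0.78 (τ = 1.0 when every
event is dated; the insertion of undated events through purely lexical
relevance is the hard part, and the reported score quantifies exactly
that). `timid_ap = 1` means events sit on average one rank from their true
position.

Artifacts land in the run directory: `events.jsonl`, `rel.tsv`,
`timeline.jsonl`, `report.json`, and a `manifest.json` logging the resolved
configuration and seed.

A command-line front end ships at `inst/cli/eventline.R`:

```sh
Rscript inst/cli/eventline.R simulate --out-dir sim/ --seed 1
Rscript inst/cli/eventline.R run --segments sim/segments.jsonl \
  --historical-db sim/historical_db.tsv --out-dir run1/ \
  --ref-timeline sim/truth_timeline.jsonl
```

## Documentation

The methods vignette (`vignettes/eventline-methods.Rmd`) documents the
model, every tunable parameter with its default and provenance, the
synthetic world and what a green test does and does not establish, and all
numerical and interpretive choices.
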