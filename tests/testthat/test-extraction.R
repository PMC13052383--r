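# Coreference, template extraction, MMR summaries, event embedding.

test_that("coreference links identical mentions and respects the window", {
  emb <- hash_embedder(32)
  segs <- narrative_segments(c("s1", "s2"),
                             text = c("I met Wei Lan at the market.",
                                      "Wei Lan cooked dinner that night."))
  links <- resolve_coreference(segs, emb)
  expect_true(nrow(links) >= 1)
  pair <- links[links$similarity > 0.999, ]
  expect_true(nrow(pair) >= 1)  # identical strings link at similarity 1

  # mentions farther apart than the window are never compared
  far <- narrative_segments(
    c("a", "b"),
    text = c(paste(c("Old Chen spoke.", rep("word", 30)), collapse = " "),
             "Old Chen answered."))
  none <- resolve_coreference(far, emb, window_tokens = 10)
  expect_equal(nrow(none), 0)
  # ... but a window wide enough to span them links them
  some <- resolve_coreference(far, emb, window_tokens = 512)
  expect_true(nrow(some) >= 1)
})

test_that("coreference equals the brute-force all-pairs filter", {
  emb <- hash_embedder(32)
  segs <- narrative_segments(
    sprintf("s%d", 1:3),
    text = c("Teacher Wang met Old Chen in Shanghai.",
             "Later Teacher Wang wrote to Mother.",
             "Old Chen and Mother stayed in Chuzhou."))
  links <- resolve_coreference(segs, emb, window_tokens = 512,
                               threshold = 0.8)
  mentions <- attr(links, "mentions")
  embm <- emb$embed(mentions$text)
  expected <- 0
  for (i in seq_len(nrow(mentions) - 1)) {
    for (j in (i + 1):nrow(mentions)) {
      if (abs(mentions$token_offset[j] - mentions$token_offset[i]) > 512)
        next
      if (cos_pair(embm[i, ], embm[j, ]) >= 0.8) expected <- expected + 1
    }
  }
  expect_equal(nrow(links), expected)

  # relabeling segments (order preserved) leaves the link set unchanged
  segs2 <- segs
  segs2$segment_id <- sprintf("z%d", 1:3)
  links2 <- resolve_coreference(segs2, emb, 512, 0.8)
  expect_equal(nrow(links2), nrow(links))
  expect_equal(links2$similarity, links$similarity)
})

test_that("template extraction fills elements and canonicalizes chains", {
  segs <- narrative_segments("s1", text = "We married in 1962.")
  tpl <- list(event_template("marriage", "married",
                             patterns = list(time = "\\b(1[89][0-9]{2})\\b")))
  evs <- extract_events(segs, tpl)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$trigger, "married")
  expect_equal(evs[[1]]$time_raw, "1962")
  expect_equal(evs[[1]]$time$kind, "unknown")  # normalization comes later

  none <- extract_events(narrative_segments("s2", text = "Just a day."), tpl)
  expect_length(none, 0)

  # two trigger hits across segments share a chain representative
  emb <- hash_embedder(32)
  segs2 <- narrative_segments(
    c("a", "b"),
    text = c("I married with Wei Lan in Nanjing.",
             "We had a wedding with Wei Lan again."))
  tpl2 <- list(event_template(
    "marriage", c("married", "wedding"),
    patterns = list(participant = "\\bwith ([A-Z][a-z]+(?: [A-Z][a-z]+)?)")))
  links <- resolve_coreference(segs2, emb)
  evs2 <- extract_events(segs2, tpl2, links)
  expect_length(evs2, 2)
  expect_equal(evs2[[1]]$participants, evs2[[2]]$participants)

  expect_error(extract_events(segs, list()), "non-empty")
})

test_that("competing templates report all matches and the ambiguity", {
  segs <- narrative_segments("s1", text = "They married young.")
  tpls <- list(event_template("marriage", "married"),
               event_template("union", "married"))
  evs <- extract_events(segs, tpls)
  expect_length(evs, 2)
  amb <- attr(evs, "ambiguities")
  expect_length(amb, 1)
  expect_setequal(amb[[1]]$event_types, c("marriage", "union"))
})

test_that("MMR selection matches stepwise brute force and reduces to top-k", {
  sents <- c("the red house by the river",
             "a red house near the river bank",
             "grandmother cooked noodle soup",
             "the factory shift started early",
             "noodle soup on cold mornings",
             "trains left the northern station")
  sal <- c(0.9, 0.85, 0.7, 0.6, 0.65, 0.5)
  ev <- make_event("e1")
  for (dw in c(0.3, 0.5, 0.7, 0.9)) {
    got <- select_summary(ev, sents, sal, k = 3, diversity_weight = dw)
    exp <- oracle_mmr(sents, sal, 3, dw, eventline:::.bow_cosine)
    expect_equal(got, exp, info = paste("dw =", dw))
  }
  # diversity_weight = 1 is exactly top-k by salience
  top <- select_summary(ev, sents, sal, k = 3, diversity_weight = 1)
  expect_equal(top, sents[order(-sal)][1:3])
  expect_equal(select_summary(ev, "only one", 1, k = 3), "only one")
  expect_equal(select_summary(ev, character(), numeric(), k = 3),
               character())
})

test_that("event embedding is deterministic and row-equivariant", {
  emb <- hash_embedder(32)
  evs <- list(make_event("e1", trigger = "married"),
              make_event("e2", trigger = "retired"),
              make_event("e3", trigger = "married"))
  m <- embed_events(evs, emb)
  expect_equal(dim(unclass(m)), c(3L, 32L))
  expect_equal(m[1, ], m[3, ])  # identical events embed identically
  # permuting events permutes rows identically
  m2 <- embed_events(evs[c(2, 3, 1)], emb)
  expect_equal(unname(m2[3, ]), unname(m[1, ]))
  # deterministic across calls
  expect_identical(unclass(embed_events(evs, emb)), unclass(m))
})

test_that("templates read back from JSON config", {
  p <- system.file("extdata", "event_templates.json", package = "eventline")
  tpls <- read_templates(p)
  expect_true(length(tpls) >= 3)
  expect_true(all(vapply(tpls, inherits, logical(1), "event_template")))
  expect_true("married" %in% tpls[[2]]$triggers)
})
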