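# Storyline metrics, timeline-identity metrics, table arithmetic, ROUGE.

test_that("h-gram counting is the binomial coefficient", {
  expect_equal(count_hgrams(4, 2), 6L)   # the printed worked example
  expect_equal(count_hgrams(5, 1), 5L)
  expect_equal(count_hgrams(6, 3), 20L)
  expect_equal(count_hgrams(6, 3), nrow(t(combn(6, 3))))  # enumeration
  # binomial symmetry
  for (n in 2:8) for (h in 1:(n - 1))
    expect_equal(count_hgrams(n, h), count_hgrams(n, n - h))
  expect_error(count_hgrams(3, 4), "exceed")
})

test_that("h-gram SLEU: limits and the exhaustive-oracle fixture", {
  story <- c("we married in spring", "the factory shift began",
             "floods took the house", "we moved to the city")
  exact <- function(a, b) as.numeric(identical(a, b))
  expect_equal(sleu_hgram(story, story, similarity = exact), 1)
  # total mismatch scores 0
  other <- c("x1", "x2", "x3", "x4")
  expect_equal(sleu_hgram(story, other, similarity = exact), 0)
  # hand-specified similarity table: pairs (1,1), (2,2), (4,4) match
  S <- matrix(0, 4, 4)
  S[1, 1] <- 1; S[2, 2] <- 1; S[3, 3] <- 0.1; S[4, 4] <- 1
  got <- sleu_hgram(story, story, similarity = S,
                    match_threshold = 0.2,
                    weights = c("1" = 0.5, "2" = 0.5))
  # p_1 = 3/4, p_2 = 3/6: SLEU = exp(0.5 log .75 + 0.5 log .5) = sqrt(.375)
  expect_equal(got, sqrt(0.375), tolerance = 1e-12)
  expect_equal(got, oracle_sleu_hgram(S, 0.2, c("1" = 0.5, "2" = 0.5)),
               tolerance = 1e-12)
  # random similarity tables agree with the oracle
  for (s in 1:15) {
    set.seed(1000 + s)
    Sr <- matrix(runif(25), 5, 5)
    w <- c("1" = 0.4, "2" = 0.3, "3" = 0.3)
    expect_equal(sleu_hgram(letters[1:5], letters[1:5], similarity = Sr,
                            weights = w),
                 oracle_sleu_hgram(Sr, 0.2, w), tolerance = 1e-12,
                 info = paste("seed", s))
  }
  # raising the threshold never raises the score
  th <- seq(0, 0.9, by = 0.15)
  vals <- vapply(th, function(t)
    sleu_hgram(story, story, similarity = S, match_threshold = t), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(sleu_hgram(character(), character()), "empty")
})

test_that("positional SLEU is 1 at zero deviation and decays monotonically", {
  expect_equal(sleu_positional(1:6, 1:6), 1)
  # single displaced event: score decreases monotonically in displacement
  scores <- vapply(1:8, function(d) {
    pred <- c(1 + d, 2:9)
    sleu_positional(pred, 1:9)
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  # 5-event fixture with deviations (0,1,0,2,1): mean 0.8, frozen value
  pred <- c(1, 3, 3, 6, 6); ref <- c(1, 2, 3, 4, 5)
  got <- sleu_positional(pred, ref, H = 3, decay = 0.5)
  w <- 1 / (1:3)
  expect_equal(got, sum(w * exp(-0.5 * 0.8)) / sum(w), tolerance = 1e-12)
  expect_equal(got, exp(-0.4), tolerance = 1e-12)
  expect_error(sleu_positional(setNames(1:3, c("a", "b", "c")),
                               setNames(1:3, c("a", "b", "x"))),
               "different event sets")
})

test_that("timeline-identity absolute deviation matches hand arithmetic", {
  ids <- sprintf("e%d", 1:4)
  expect_equal(timid_absolute(ids, ids), 0)
  expect_equal(timid_absolute(rev(ids), ids), 2.0)  # (3+1+1+3)/4
  ten <- sprintf("e%d", 1:10)
  swapped <- ten; swapped[3:4] <- swapped[4:3]
  expect_equal(timid_absolute(swapped, ten), 0.2)
  expect_equal(timid_absolute(rev(ids), ids, normalized = TRUE), 0.5)
  expect_error(timid_absolute(ids, c("a", "b", "c", "d")), "different")
})

test_that("Kendall tau equals the pair-counting oracle and stats::cor", {
  ids <- sprintf("e%d", 1:7)
  expect_equal(timid_relative(ids, ids), 1)
  expect_equal(timid_relative(rev(ids), ids), -1)
  for (s in 1:20) {
    set.seed(1100 + s)
    perm <- sample(ids)
    got <- timid_relative(perm, ids)
    rp <- match(ids, perm); rr <- seq_along(ids)
    expect_equal(got, oracle_kendall(rp, rr), tolerance = 1e-12)
    expect_equal(got, unname(cor(rp, rr, method = "kendall")),
                 tolerance = 1e-12)
    # antisymmetry under reversal
    expect_equal(timid_relative(rev(perm), ids), -got, tolerance = 1e-12)
  }
})

test_that("relative reduction reproduces printed-table arithmetic", {
  expect_equal(relative_reduction(76.0, 47.5), 37.5)
  expect_equal(relative_reduction(77.0, 49.0), 36.4)
  expect_equal(relative_reduction(73.5, 42.0), 42.9)
  expect_equal(relative_reduction(10, 10), 0.0)
  expect_error(relative_reduction(0, 5), "positive")
})

test_that("ROUGE agrees with a hand-computed unigram fixture", {
  cand <- "the cat sat on the mat"
  ref <- "the cat lay on the mat"
  # unigram overlap: the(2), cat, on, mat -> 5 of 6 both sides, F1 = 5/6
  expect_equal(rouge_n(cand, ref, 1), 5 / 6, tolerance = 1e-12)
  # bigrams: "the cat", "on the", "the mat" -> 3 of 5, F1 = 3/5
  expect_equal(rouge_n(cand, ref, 2), 3 / 5, tolerance = 1e-12)
  # LCS = "the cat on the mat" (5 tokens)
  expect_equal(rouge_l(cand, ref), 5 / 6, tolerance = 1e-12)
  expect_equal(rouge_l(cand, cand), 1)
  expect_equal(rouge_n("", ref, 1), 0)
})

test_that("evaluate_timeline bundles the metrics coherently", {
  ids <- sprintf("e%d", 1:6)
  rep_same <- evaluate_timeline(ids, ids)
  expect_equal(rep_same$timid_rp, 1)
  expect_equal(rep_same$timid_ap, 0)
  expect_equal(rep_same$sleu_positional, 1)
  expect_equal(rep_same$sleu_hgram, 1)
  rep_rev <- evaluate_timeline(rev(ids), ids)
  expect_equal(rep_rev$timid_rp, -1)
})
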