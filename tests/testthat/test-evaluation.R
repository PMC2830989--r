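mk_hit <- function(start, end, strand = "+", score = 1000, id = 1L,
                   identity = 100, coverage = 100, target = "chr1") {
  data.frame(candidate_id = id, target_name = target, target_start = start,
             target_end = end, strand = strand, score = score,
             identity_pct = identity, query_coverage_pct = coverage,
             is_self = FALSE, stringsAsFactors = FALSE)
}

test_that("self-hit identification uses reciprocal overlap, not score", {
  cand <- list(id = 1L, start = 1000, end = 1499)
  # exact self only
  h <- identify_self_hit(cand, mk_hit(1000, 1499), "chr1")
  expect_true(h$is_self)
  # equal-scoring distal copy does not confuse the choice
  h2 <- identify_self_hit(cand, rbind(mk_hit(5000, 5499, score = 2500),
                                      mk_hit(1000, 1499, score = 2500)),
                          "chr1")
  expect_equal(which(h2$is_self), 2L)
  # minus-strand overlap does not qualify
  expect_error(
    identify_self_hit(cand, mk_hit(1000, 1499, strand = "-"), "chr1"),
    "QA failure")
  # distal copy only -> QA failure naming the candidate
  expect_error(identify_self_hit(cand, mk_hit(5000, 5499), "chr1"),
               "QA failure.*candidate 1")
  expect_error(identify_self_hit(cand, mk_hit(1000, 1499)[0, ], "chr1"),
               "QA failure")
})

test_that("score ratio arithmetic and the unique sentinel", {
  expect_equal(score_ratio(3000, 300), 10)
  expect_identical(score_ratio(2500), Inf)
  expect_equal(blotprobe:::format_ratio(c(Inf, 9.8912)), c("unique", "9.89"))
})

test_that("evaluation picks the best off-target and is order-independent", {
  cand <- data.frame(id = 1L, start = 1000, end = 1499, length = 500L,
                     seq = strrep("A", 500), masked_pct = 0)
  attr(cand, "spec") <- NULL
  hits <- rbind(mk_hit(1000, 1499, score = 2500),
                mk_hit(7000, 7400, score = 400, identity = 80,
                       coverage = 60),
                mk_hit(9000, 9300, score = 300, identity = 90,
                       coverage = 40))
  ev1 <- evaluate_candidates(cand, hits, seq_name = "chr1")
  ev2 <- evaluate_candidates(cand, hits[c(3, 1, 2), ], seq_name = "chr1")
  expect_identical(ev1, ev2)
  expect_equal(ev1$self_score, 2500)
  expect_equal(ev1$second_score, 400)
  expect_equal(ev1$score_ratio, 2500 / 400)
  expect_equal(ev1$second_identity_pct, 80)
  expect_equal(ev1$second_coverage_pct, 60)
  expect_true(ev1$qa_passed)

  # a single self hit means a unique candidate
  ev3 <- evaluate_candidates(cand, mk_hit(1000, 1499, score = 2500),
                             seq_name = "chr1")
  expect_identical(ev3$score_ratio, Inf)
  expect_true(is.na(ev3$second_score))
})

test_that("exact whole-probe duplication gives score ratio exactly 1", {
  set.seed(21)
  probe <- random_dna(400)
  g <- masked_seq("g", paste0(random_dna(600), probe, random_dna(900),
                              probe, random_dna(600)))
  cand <- data.frame(id = 1L, start = 601L, end = 1000L, length = 400L,
                     seq = probe, masked_pct = 0)
  hits <- search_probe(probe, g, alignment_params(), candidate_id = 1L)
  ev <- evaluate_candidates(cand, hits, seq_name = "g")
  expect_equal(ev$score_ratio, 1.0)
  expect_equal(ev$second_identity_pct, 100)
})
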