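mk_ev <- function(ratio, masked, start = 1000, len = 500, self = 5 * len) {
  n <- length(ratio)
  data.frame(candidate_id = seq_len(n), start = start,
             end = start + len - 1, length = len, masked_pct = masked,
             self_score = self,
             second_score = ifelse(is.infinite(ratio), NA, self / ratio),
             score_ratio = ratio, second_identity_pct = NA_real_,
             second_coverage_pct = NA_real_, qa_passed = TRUE,
             stringsAsFactors = FALSE)
}

test_that("classification bins by inclusive score-ratio and masked thresholds", {
  ev <- mk_ev(ratio = c(30, Inf, 10.0, 9.99, Inf, 12),
              masked = c(3, 2, 5.0, 1, 8, 5.1))
  r <- classify_probes(ev, 10, 5)
  expect_equal(r$evaluations$bin,
               c("passed", "unique", "passed", "failed", "failed", "failed"))
  # thresholds are inclusive: ratio exactly 10 and masked exactly 5 pass
  expect_equal(r$evaluations$bin[3], "passed")
  # unique requires the masked criterion too
  expect_equal(r$evaluations$bin[5], "failed")
  expect_equal(sum(r$counts), nrow(ev))
})

test_that("bin partition and threshold monotonicity hold on random evaluation sets", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    ratio <- ifelse(runif(n) < 0.2, Inf, exp(runif(n, 0, 4)))
    ev <- mk_ev(ratio, masked = runif(n, 0, 30),
                start = sample(1:5000, n, replace = TRUE),
                len = sample(300:800, n, replace = TRUE))
    r1 <- classify_probes(ev, 10, 5)
    expect_equal(sum(r1$counts), n)  # partition
    expect_setequal(unique(r1$evaluations$bin),
                    intersect(c("unique", "passed", "failed"),
                              r1$evaluations$bin))
    # relaxing either cut-off never shrinks the accepted set
    r2 <- classify_probes(ev, 7.5, 5)
    r3 <- classify_probes(ev, 10, 10)
    acc <- function(r) sum(r$counts[c("unique", "passed")])
    expect_gte(acc(r2), acc(r1))
    expect_gte(acc(r3), acc(r1))
  }
})

test_that("contained worse probes are filtered as redundant, transitively", {
  ev <- mk_ev(ratio = c(20, 40), masked = c(1, 1))
  ev$start <- c(100, 100); ev$end <- c(700, 1100)
  ev$length <- c(601, 1001)
  r <- remove_redundant(classify_probes(ev, 10, 5))
  expect_equal(r$evaluations$bin, c("redundant", "passed"))

  # non-overlapping probes are both retained
  ev2 <- mk_ev(ratio = c(20, 40), masked = c(1, 1))
  ev2$start <- c(100, 1200); ev2$end <- c(700, 1800)
  ev2$length <- c(601, 601)
  r2 <- remove_redundant(classify_probes(ev2, 10, 5))
  expect_equal(sort(r2$evaluations$bin), c("passed", "passed"))

  # chain A in B in C with increasing ratio: only C survives
  ev3 <- mk_ev(ratio = c(12, 20, 30), masked = c(1, 1, 1))
  ev3$start <- c(300, 200, 100); ev3$end <- c(600, 700, 800)
  ev3$length <- c(301, 501, 701)
  r3 <- remove_redundant(classify_probes(ev3, 10, 5))
  expect_equal(r3$evaluations$bin, c("redundant", "redundant", "passed"))

  # a contained probe in a BETTER bin is kept (unique inside passed)
  ev4 <- mk_ev(ratio = c(Inf, 40), masked = c(1, 1))
  ev4$start <- c(300, 100); ev4$end <- c(700, 1100)
  ev4$length <- c(401, 1001)
  r4 <- remove_redundant(classify_probes(ev4, 10, 5))
  expect_equal(r4$evaluations$bin, c("unique", "passed"))
})

test_that("cut-offs relax on schedule until something passes", {
  # ratios in [7,9]: the first ratio step (10 -> 7.5) admits the 9s
  ev <- mk_ev(ratio = c(7.2, 9, 8.5), masked = c(2, 3, 4))
  r <- relax_and_reclassify(ev, design_spec("c", 1, 2000, min_len = 400))
  expect_true(r$relaxed)
  expect_equal(unname(r$criteria_used["min_score_ratio"]), 7.5)
  expect_equal(unname(r$criteria_used["max_masked_pct"]), 5)
  expect_equal(r$evaluations$bin, c("failed", "passed", "passed"))
  expect_equal(nrow(r$relaxation_trail), 2L)

  # an already-passing set never triggers relaxation
  ev2 <- mk_ev(ratio = c(Inf, 5), masked = c(1, 1))
  r2 <- relax_and_reclassify(ev2, design_spec("c", 1, 2000, min_len = 400))
  expect_false(r2$relaxed)
  expect_equal(nrow(r2$relaxation_trail), 1L)

  # ratio 1, masked 90%: accepted only once the masked cut-off reaches 90
  ev3 <- mk_ev(ratio = rep(1.0, 3), masked = rep(90, 3))
  r3 <- relax_and_reclassify(ev3, design_spec("c", 1, 2000, min_len = 400))
  expect_true(r3$relaxed)
  expect_equal(unname(r3$criteria_used["max_masked_pct"]), 90)
  expect_equal(sum(r3$evaluations$bin == "passed"), 3L)

  # nothing can ever pass (masked unknown): explicit error at the floor
  ev4 <- mk_ev(ratio = 5, masked = NA_real_)
  expect_error(relax_and_reclassify(ev4,
                                    design_spec("c", 1, 2000, min_len = 400)),
               "fully relaxed")
})

test_that("ranking orders by bin, ratio, length then start", {
  ev <- mk_ev(ratio = c(40, Inf, 23, 12, 23), masked = rep(1, 5))
  ev$start <- c(100, 900, 300, 400, 200)
  ev$length <- c(1300, 600, 700, 800, 800)
  ev$end <- ev$start + ev$length - 1
  r <- classify_probes(ev, 10, 5)
  ranked <- rank_probes(r)
  # unique first despite lower length than the ratio-40 passed probe
  expect_equal(ranked$candidate_id, c(2L, 1L, 5L, 3L, 4L))
})
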