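test_that("a probe occurring once yields exactly its perfect self alignment", {
  set.seed(11)
  g <- masked_seq("g", random_dna(8000))
  probe <- slice_seq(g, 2001, 2500)
  for (method in c("full", "seeded")) {
    h <- search_probe(probe, g, alignment_params(), method = method)
    expect_equal(nrow(h), 1L)
    expect_equal(h$score, 5 * 500)
    expect_equal(h$identity_pct, 100)
    expect_equal(h$query_coverage_pct, 100)
    expect_equal(c(h$target_start, h$target_end), c(2001L, 2500L))
    expect_equal(h$strand, "+")
  }
})

test_that("two exact genomic copies give two equal-scoring hits", {
  set.seed(12)
  probe <- random_dna(400)
  g <- masked_seq("g", paste0(random_dna(1000), probe, random_dna(2000),
                              probe, random_dna(1000)))
  h <- search_probe(probe, g, alignment_params())
  expect_equal(nrow(h), 2L)
  expect_equal(h$score[1], h$score[2])
  expect_equal(h$score[1], 5 * 400)
  expect_setequal(h$target_start, c(1001L, 3401L))
  # no hit can out-score the perfect self-hit
  expect_true(all(h$score <= 5 * 400))
})

test_that("hit scores equal the full affine-gap dynamic-programming oracle", {
  set.seed(13)
  for (i in 1:10) {
    probe <- random_dna(300)
    identity <- runif(1, 0.8, 1.0)
    g <- plant_copy(random_dna(4000), probe, at = sample(500:3500, 1),
                    identity = identity)
    h <- search_probe(probe, masked_seq("g", g), alignment_params())
    expect_gt(nrow(h), 0L)
    expect_equal(h$score[1], oracle_best_score(probe, g))
  }
})

test_that("reverse-complemented copies are reported on the minus strand with equal score", {
  set.seed(14)
  probe <- random_dna(350)
  ident <- 0.9
  copy <- mutate_dna(probe, 1 - ident)
  g_fwd <- masked_seq("g", paste0(random_dna(800), copy, random_dna(800)))
  g_rev <- masked_seq("g", revcomp(g_fwd$residues))
  hf <- search_probe(probe, g_fwd, alignment_params())
  hr <- search_probe(probe, g_rev, alignment_params())
  expect_equal(nrow(hf), 1L)
  expect_equal(nrow(hr), 1L)
  expect_equal(hf$strand, "+")
  expect_equal(hr$strand, "-")
  expect_equal(hf$score, hr$score)
  expect_equal(hf$identity_pct, hr$identity_pct)
  # coordinates mirror through the reverse complement
  n <- seq_length(g_fwd)
  expect_equal(hr$target_start, n - hf$target_end + 1L)
  expect_equal(hr$target_end, n - hf$target_start + 1L)
})

test_that("seeded search agrees with exhaustive search on divergent planted copies", {
  set.seed(15)
  for (i in 1:5) {
    probe <- random_dna(300)
    g <- masked_seq("g", plant_copy(random_dna(5000), probe,
                                    at = sample(1000:4000, 1),
                                    identity = runif(1, 0.85, 1)))
    hf <- search_probe(probe, g, alignment_params(), method = "full")
    hs <- search_probe(probe, g, alignment_params(), method = "seeded")
    expect_equal(hs$score, hf$score)
    expect_equal(hs$target_start, hf$target_start)
  }
})

test_that("soft-masking never changes alignment scores", {
  set.seed(16)
  probe <- random_dna(300)
  g_up <- paste0(random_dna(500), probe, random_dna(500))
  # lowercase half the genome
  v <- strsplit(g_up, "", fixed = TRUE)[[1]]
  idx <- sample(length(v), length(v) %/% 2)
  v[idx] <- tolower(v[idx])
  h1 <- search_probe(probe, masked_seq("g", g_up), alignment_params())
  h2 <- search_probe(probe, masked_seq("g", paste(v, collapse = "")),
                     alignment_params())
  expect_equal(h1$score, h2$score)
  expect_equal(h1$target_start, h2$target_start)
})

test_that("an all-N probe is rejected as unalignable", {
  g <- masked_seq("g", random_dna(1000))
  expect_error(search_probe(strrep("N", 200), g), "unalignable")
})

test_that("external alignment reports are normalised into hits", {
  d <- withr::local_tempdir()
  # tab dialect: 0-based half-open coordinates
  tab <- file.path(d, "hits.tsv")
  writeLines(c("1\tchr2\t1000\t1500\t+\t2400\t100\t100",
               "1\tchr5\t200\t640\t-\t310\t71.5\t88"), tab)
  h <- parse_external_alignments(tab, "tab")
  expect_equal(nrow(h), 2L)
  expect_equal(h$target_start, c(1001L, 201L))  # +1 on start only
  expect_equal(h$target_end, c(1500L, 640L))
  expect_equal(h$score, c(2400, 310))
  expect_equal(h$strand, c("+", "-"))

  # vulgar dialect, forward and reverse target strands
  vul <- file.path(d, "hits.vulgar")
  writeLines(c(
    "vulgar: 7 0 500 + chr1 1000 1500 + 2500 M 500 500",
    "vulgar: 7 0 450 + chr3 900 450 - 1800 M 450 450",
    "# comment"), vul)
  hv <- parse_external_alignments(vul, "vulgar",
                                  query_lengths = c("7" = 500))
  expect_equal(hv$target_start, c(1001L, 451L))
  expect_equal(hv$target_end, c(1500L, 900L))
  expect_equal(hv$strand, c("+", "-"))
  expect_equal(hv$query_coverage_pct, c(100, 90))

  # empty report is an empty collection, not an error
  empty <- file.path(d, "empty.tsv")
  writeLines(character(), empty)
  expect_equal(nrow(parse_external_alignments(empty, "tab")), 0L)

  # malformed lines carry their line number
  bad <- file.path(d, "bad.tsv")
  writeLines(c("1\tchr2\t1000\t1500\t+\t2400\t100\t100", "oops"), bad)
  expect_error(parse_external_alignments(bad, "tab"), "line 2")
})
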