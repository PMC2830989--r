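make_window <- function(len, start = 1L, name = "chrT") {
  masked_seq(name, random_dna(len))
}

test_that("tiling matches brute-force enumeration across parameter space", {
  set.seed(7)
  cases <- list(
    list(wlen = 3000L, min = 500L, max = 1300L, frac = 0.05, dec = 50L),
    list(wlen = 1000L, min = 500L, max = 600L, frac = 0.05, dec = 50L),
    list(wlen = 2500L, min = 300L, max = 900L, frac = 0.10, dec = 100L),
    list(wlen = 700L, min = 200L, max = 1300L, frac = 0.05, dec = 50L),
    list(wlen = 640L, min = 600L, max = 600L, frac = 0.01, dec = 25L))
  for (cs in cases) {
    w <- make_window(cs$wlen)
    spec <- design_spec("chrT", 1L, cs$wlen, min_len = cs$min,
                        max_len = cs$max, step_fraction = cs$frac,
                        length_decrement = cs$dec)
    cand <- generate_candidates(spec, w)
    oracle <- naive_tiling_spans(cs$wlen, cs$min, cs$max, cs$frac, cs$dec)
    expect_equal(nrow(cand), nrow(oracle))
    expect_setequal(paste(cand$start, cand$end),
                    paste(oracle[, 1], oracle[, 2]))
    # structural invariants
    expect_true(all(cand$start >= 1 & cand$end <= cs$wlen))
    expect_true(all(cand$end - cand$start + 1 == cand$length))
    for (p in unique(cand$length)) {
      expect_equal(min(cand$start[cand$length == p]), 1L)
    }
    # longest first, ids sequential
    expect_true(all(diff(cand$length) <= 0))
    expect_equal(cand$id, seq_len(nrow(cand)))
  }
})

test_that("window equal to the single allowed length forces one candidate", {
  w <- make_window(800L)
  spec <- design_spec("chrT", 1L, 800L, min_len = 800L, max_len = 800L)
  cand <- generate_candidates(spec, w)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(1L, 800L))
  expect_identical(cand$seq, w$residues)
})

test_that("1000 bp window, 500-600 range matches the closed form", {
  w <- make_window(1000L)
  spec <- design_spec("chrT", 1L, 1000L, min_len = 500L, max_len = 600L,
                      step_fraction = 0.05, length_decrement = 50L)
  cand <- generate_candidates(spec, w)
  expected <- sum(vapply(c(600L, 550L, 500L), function(p) {
    (1000L - p) %/% max(1L, as.integer(floor(0.05 * p))) + 1L
  }, 0L))
  expect_equal(nrow(cand), expected)
})

test_that("candidate counts grow monotonically and near-linearly with window size", {
  wlens <- seq(2000L, 10000L, by = 1000L)
  counts <- vapply(wlens, function(n) {
    w <- masked_seq("chrT", strrep("A", n))
    nrow(generate_candidates(design_spec("chrT", 1L, n), w))
  }, 0L)
  expect_true(all(diff(counts) > 0))
  fit <- lm(counts ~ wlens)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("candidate coordinates honour the window offset and export conventions", {
  set.seed(3)
  g <- masked_seq("chr9", random_dna(2000))
  spec <- design_spec("chr9", 501L, 1500L, min_len = 400L, max_len = 500L,
                      step_fraction = 0.1, length_decrement = 100L)
  cand <- generate_candidates(spec, slice_seq(g, 501L, 1500L))
  expect_true(all(cand$start >= 501L & cand$end <= 1500L))
  # sequence content matches the genome at the recorded coordinates
  i <- sample(nrow(cand), 5L)
  expect_identical(cand$seq[i],
                   substring(g$residues, cand$start[i], cand$end[i]))
  d <- withr::local_tempdir()
  candidates_to_bed(cand, file.path(d, "c.bed"))
  bed <- read.table(file.path(d, "c.bed"), sep = "\t")
  expect_equal(bed$V2, cand$start - 1L)  # BED is 0-based half-open
  expect_equal(bed$V3, cand$end)
  candidates_to_fasta(cand, file.path(d, "c.fa"))
  fa <- load_fasta(file.path(d, "c.fa"))
  expect_length(fa, nrow(cand))
  expect_identical(unname(vapply(fa, `[[`, "", "residues")), cand$seq)
})

test_that("windows below the minimum probe length are rejected", {
  w <- make_window(300L)
  expect_error(design_spec("chrT", 1L, 300L, min_len = 500L),
               "window too small")
  spec <- design_spec("chrT", 1L, 300L, min_len = 200L, max_len = 250L)
  expect_error(generate_candidates(spec, make_window(100L)), "length")
})
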