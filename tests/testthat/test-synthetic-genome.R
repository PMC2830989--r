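test_that("generation is deterministic and masked content matches construction", {
  cfg <- synthetic_genome_config(length = 10000, seed = 5,
                                 repeat_families = list(list(length = 200,
                                                             copies = 3,
                                                             divergence = 0.1)),
                                 low_complexity = list(list(length = 100,
                                                            count = 2)))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome$residues, g2$genome$residues)
  # masked fraction is exactly the planted masked length over genome length
  expect_equal(masked_fraction(g1$genome), 100 * (3 * 200 + 2 * 100) / 10000)

  # byte-identical FASTA for identical seeds
  d <- withr::local_tempdir()
  f1 <- write_genome(g1, cfg, file.path(d, "a"))
  f2 <- write_genome(g2, cfg, file.path(d, "b"))
  expect_identical(readLines(f1[["fasta"]])[-1], readLines(f2[["fasta"]])[-1])

  # a different seed gives a different genome
  g3 <- generate_genome(synthetic_genome_config(length = 10000, seed = 6))
  expect_false(identical(g1$genome$residues, g3$genome$residues))
})

test_that("a featureless genome is unmasked; truth intervals tile the mask", {
  g <- generate_genome(synthetic_genome_config(length = 5000, seed = 1))
  expect_equal(masked_fraction(g$genome), 0)
  expect_equal(nrow(g$truth), 0L)

  cfg <- synthetic_genome_config(length = 20000, seed = 2,
                                 duplications = list(list(length = 1000,
                                                          identity = 0.9,
                                                          count = 1)),
                                 repeat_families = list(list(length = 300,
                                                             copies = 4,
                                                             divergence = 0.05)),
                                 low_complexity = list(list(length = 60,
                                                            count = 3)))
  gen <- generate_genome(cfg)
  tr <- gen$truth
  # intervals are non-overlapping
  tr <- tr[order(tr$start), ]
  expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
  # every lowercase base lies in a masked feature and vice versa
  low <- which(strsplit(gen$genome$residues, "", fixed = TRUE)[[1]] %in%
                 letters)
  masked_iv <- tr[tr$kind %in% c("repeat", "low_complexity"), ]
  in_feature <- unlist(Map(seq, masked_iv$start, masked_iv$end))
  expect_setequal(low, in_feature)
  # duplications are NOT masked
  dup_iv <- tr[tr$kind == "duplication_copy", ]
  expect_false(any(seq(dup_iv$start, dup_iv$end) %in% low))
})

test_that("planted duplication identity is honoured", {
  # exact copy at identity 1
  cfg <- synthetic_genome_config(length = 15000, seed = 9,
                                 duplications = list(list(length = 2000,
                                                          identity = 1.0,
                                                          count = 1)))
  gen <- generate_genome(cfg)
  tr <- gen$truth
  src <- tr[tr$kind == "duplication_source", ]
  cp <- tr[tr$kind == "duplication_copy", ]
  s_seq <- substring(gen$genome$residues, src$start, src$end)
  c_seq <- substring(gen$genome$residues, cp$start, cp$end)
  expect_identical(s_seq, c_seq)

  # at identity 0.85 the realised identity concentrates within +/- 3 points
  cfg2 <- synthetic_genome_config(length = 15000, seed = 10,
                                  duplications = list(list(length = 1000,
                                                           identity = 0.85,
                                                           count = 1)))
  gen2 <- generate_genome(cfg2)
  tr2 <- gen2$truth
  s2 <- strsplit(substring(gen2$genome$residues,
                           tr2$start[tr2$kind == "duplication_source"],
                           tr2$end[tr2$kind == "duplication_source"]),
                 "")[[1]]
  c2 <- strsplit(substring(gen2$genome$residues,
                           tr2$start[tr2$kind == "duplication_copy"],
                           tr2$end[tr2$kind == "duplication_copy"]),
                 "")[[1]]
  realised <- mean(s2 == c2)
  expect_lt(abs(realised - 0.85), 0.03)
})

test_that("infeasible packing is rejected", {
  cfg <- synthetic_genome_config(length = 1000, seed = 1,
                                 duplications = list(list(length = 400,
                                                          identity = 1,
                                                          count = 2)))
  expect_error(generate_genome(cfg), "infeasible packing")
})
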