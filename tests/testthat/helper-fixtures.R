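# Shared fixtures and independent oracles, all built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base substitution at `rate`, never to the same base
mutate_dna <- function(seq, rate) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     "")
  }
  paste(v, collapse = "")
}

# brute-force tiling enumeration, written independently of the package's
# vectorised implementation: explicit nested loops over lengths and starts
naive_tiling_spans <- function(wlen, min_len, max_len, frac, dec) {
  spans <- list()
  p <- max_len
  while (p >= min_len) {
    if (p <= wlen) {
      step <- max(1L, as.integer(floor(frac * p)))
      s <- 1L
      while (s + p - 1L <= wlen) {
        spans[[length(spans) + 1L]] <- c(s, s + p - 1L)
        s <- s + step
      }
    }
    p <- p - dec
  }
  unique(do.call(rbind, spans))
}

# independent full affine-gap Smith-Waterman oracle (Biostrings dynamic
# programming); sequences must be pure ACGT
oracle_best_score <- function(q, t, params = alignment_params()) {
  m <- matrix(params$mismatch, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- params$match
  as.numeric(Biostrings::pairwiseAlignment(
    toupper(q), toupper(t), type = "local", substitutionMatrix = m,
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend),
    scoreOnly = TRUE))
}

# genome string with a mutated copy of `probe` planted at `at` (1-based)
plant_copy <- function(genome, probe, at, identity) {
  copy <- mutate_dna(probe, 1 - identity)
  paste0(substr(genome, 1, at - 1), copy,
         substr(genome, at + nchar(probe), nchar(genome)))
}
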