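#' Configuration for a synthetic soft-masked test genome
#'
#' Describes a genome with (i) unique i.i.d. background at a given GC content,
#' (ii) planted segmental duplications of controlled sequence identity
#' (uppercase: duplications are unique-sequence paralogy, not masked repeats),
#' (iii) interspersed repeat families (divergent copies of a consensus) and
#' (iv) low-complexity homopolymer/dinucleotide runs. Repeat-family and
#' low-complexity features are written lowercase when `mask_planted` is TRUE,
#' emulating RepeatMasker/DUST soft-masking.
#'
#' @param length Genome length in bp.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   genome.
#' @param gc GC content of the background, fraction in `[0, 1]`.
#' @param duplications List of `list(length=, identity=, count=)`: each entry
#'   plants one source segment plus `count` copies derived from it by per-base
#'   substitution at rate `1 - identity` (no indels).
#' @param repeat_families List of `list(length=, copies=, divergence=)`.
#' @param low_complexity List of `list(length=, count=)`.
#' @param mask_planted Lowercase the repeat/low-complexity features?
#' @return A `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(length = 100000L, seed = 1L, gc = 0.5,
                                    duplications = list(),
                                    repeat_families = list(),
                                    low_complexity = list(),
                                    mask_planted = TRUE) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  chk <- function(lst, fields) {
    for (x in lst) stopifnot(all(fields %in% names(x)))
  }
  chk(duplications, c("length", "identity", "count"))
  chk(repeat_families, c("length", "copies", "divergence"))
  chk(low_complexity, c("length", "count"))
  for (d in duplications) stopifnot(d$identity >= 0, d$identity <= 1)
  for (r in repeat_families) stopifnot(r$divergence >= 0, r$divergence <= 1)
  structure(list(length = as.integer(length), seed = as.integer(seed),
                 gc = gc, duplications = duplications,
                 repeat_families = repeat_families,
                 low_complexity = low_complexity,
                 mask_planted = isTRUE(mask_planted)),
            class = "synthetic_genome_config")
}

#' Generate a synthetic soft-masked genome with ground truth
#'
#' @param config A [synthetic_genome_config()].
#' @param name Sequence name for the generated contig.
#' @return List with elements `genome` (a `masked_seq`) and `truth` (a
#'   data.frame of planted features: `start`, `end` 1-based inclusive, `kind`
#'   in `{duplication_source, duplication_copy, repeat, low_complexity}`,
#'   `feature` pairing id, and `identity`, the requested copy identity).
#' @export
generate_genome <- function(config, name = "synth1") {
  stopifnot(inherits(config, "synthetic_genome_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  L <- config$length
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
          (1 - config$gc) / 2)
  res <- sample(bases, L, replace = TRUE, prob = pr)

  # required feature segments, in declaration order
  segs <- list()
  for (i in seq_along(config$duplications)) {
    d <- config$duplications[[i]]
    segs[[length(segs) + 1L]] <- list(kind = "duplication_source",
                                      len = d$length, feature = sprintf("dup%d", i),
                                      identity = 1)
    for (k in seq_len(d$count)) {
      segs[[length(segs) + 1L]] <- list(kind = "duplication_copy",
                                        len = d$length,
                                        feature = sprintf("dup%d", i),
                                        identity = d$identity)
    }
  }
  for (i in seq_along(config$repeat_families)) {
    r <- config$repeat_families[[i]]
    for (k in seq_len(r$copies)) {
      segs[[length(segs) + 1L]] <- list(kind = "repeat", len = r$length,
                                        feature = sprintf("rep%d", i),
                                        identity = 1 - r$divergence)
    }
  }
  for (i in seq_along(config$low_complexity)) {
    lc <- config$low_complexity[[i]]
    for (k in seq_len(lc$count)) {
      segs[[length(segs) + 1L]] <- list(kind = "low_complexity",
                                        len = lc$length,
                                        feature = sprintf("lc%d", i),
                                        identity = 1)
    }
  }

  iv <- place_intervals(vapply(segs, `[[`, 0, "len"), L)

  mask <- rep(FALSE, L)
  truth <- data.frame(start = integer(), end = integer(), kind = character(),
                      feature = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  dup_source <- list()  # feature id -> source residues
  rep_consensus <- list()
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    s <- iv$start[i]; e <- iv$end[i]
    if (sg$kind == "duplication_source") {
      dup_source[[sg$feature]] <- res[s:e]
    } else if (sg$kind == "duplication_copy") {
      src <- dup_source[[sg$feature]]
      res[s:e] <- mutate_copy(src, 1 - sg$identity, bases)
    } else if (sg$kind == "repeat") {
      if (is.null(rep_consensus[[sg$feature]])) {
        rep_consensus[[sg$feature]] <- sample(bases, sg$len, replace = TRUE,
                                              prob = pr)
      }
      res[s:e] <- mutate_copy(rep_consensus[[sg$feature]], 1 - sg$identity,
                              bases)
      mask[s:e] <- TRUE
    } else {  # low_complexity: homopolymer or dinucleotide tract
      if (runif(1) < 0.5) {
        res[s:e] <- sample(bases, 1L)
      } else {
        di <- sample(bases, 2L)
        res[s:e] <- rep_len(di, e - s + 1L)
      }
      mask[s:e] <- TRUE
    }
    truth <- rbind(truth, data.frame(start = s, end = e, kind = sg$kind,
                                     feature = sg$feature,
                                     identity = sg$identity,
                                     stringsAsFactors = FALSE))
  }

  if (config$mask_planted && any(mask)) {
    res[mask] <- tolower(res[mask])
  }
  list(genome = masked_seq(name, paste(res, collapse = "")), truth = truth)
}

# Random non-overlapping placement of segments with >= 1 bp gaps between
# features (so truth intervals and mask runs stay distinct).
place_intervals <- function(lens, L, max_tries = 2000L) {
  if (length(lens) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (sum(lens) + length(lens) + 1L > L) {
    stop("infeasible packing: planted features exceed genome length",
         call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    starts <- integer(length(lens))
    occupied <- data.frame(start = integer(), end = integer())
    ok <- TRUE
    for (i in seq_along(lens)) {
      placed <- FALSE
      for (k in seq_len(50L)) {
        s <- sample.int(L - lens[i] + 1L, 1L)
        e <- s + lens[i] - 1L
        # require a 1 bp buffer around every feature
        if (!any(occupied$start <= e + 1L & occupied$end >= s - 1L)) {
          starts[i] <- s
          occupied <- rbind(occupied, data.frame(start = s, end = e))
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      return(data.frame(start = starts, end = starts + lens - 1L))
    }
  }
  stop("infeasible packing: could not place features without overlap",
       call. = FALSE)
}

mutate_copy <- function(src, rate, bases) {
  out <- src
  if (rate > 0) {
    hit <- runif(length(src)) < rate
    if (any(hit)) {
      out[hit] <- vapply(src[hit],
                         function(b) sample(setdiff(bases, b), 1L), "")
    }
  }
  out
}

#' Write a synthetic genome, its ground truth BED and config JSON
#'
#' The BED file uses the 0-based half-open convention with the feature kind in
#' the name column.
#'
#' @param gen Result of [generate_genome()].
#' @param config The [synthetic_genome_config()] used.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_genome <- function(gen, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "truth.bed")
  js <- file.path(dir, "config.json")
  write_fasta(gen$genome, fa)
  tr <- gen$truth
  bed_df <- data.frame(chrom = gen$genome$name, start = tr$start - 1L,
                       end = tr$end, name = paste0(tr$kind, ":", tr$feature))
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(config), js, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, bed = bed, config = js)
}
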