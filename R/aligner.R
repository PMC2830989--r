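#' Local alignment scoring parameters
#'
#' Affine-gap local alignment scoring in the exonerate `affine:local`
#' convention: a gap of length L costs `|gap_open| + L * |gap_extend|`.
#' Defaults (+5/-4/-12/-4) are the standard DNA defaults of that model; with
#' them a perfect full-length match of an 800-mer scores 4000. `N` bases
#' always score as mismatches, even against `N`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening score (< 0), charged once per gap.
#' @param gap_extend Gap extension score (< 0), charged per gap base.
#' @param min_score Minimum score for a reported hit.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = -12,
                             gap_extend = -4, min_score = 150) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            min_score > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score),
            class = "alignment_params")
}

empty_hits <- function() {
  data.frame(candidate_id = integer(), target_name = character(),
             target_start = integer(), target_end = integer(),
             strand = character(), score = numeric(),
             identity_pct = numeric(), query_coverage_pct = numeric(),
             is_self = logical(), stringsAsFactors = FALSE)
}

#' Search a probe against a genome
#'
#' Returns every sufficiently scoring local alignment of the probe against
#' the genome, on both strands. Hits are extracted greedily: the best local
#' alignment is taken, its genomic span masked out, and the search repeated
#' until the best remaining score falls below `min_score`; returned hits on
#' the same strand therefore never overlap. Alignment is case-insensitive
#' (soft-masking does not alter scoring; it is consumed only by
#' [masked_fraction()]).
#'
#' Two search methods are available. `"full"` runs the exhaustive
#' Smith-Waterman/Gotoh scan over every target position. `"seeded"` first
#' finds exact k-mer matches (default k = 12) between probe and genome and
#' restricts the scan to windows around them; it is guaranteed to recover
#' alignments that contain at least one exact k-mer match and lie within one
#' probe length of it, which in practice is every alignment above ~80%
#' identity. Highly diverged copies without any exact 12-mer can be missed by
#' the seeded method; use `"full"` when that matters.
#'
#' @param probe A `masked_seq` or character string (the candidate probe).
#' @param genome A `masked_seq` or list of them.
#' @param params [alignment_params()].
#' @param method `"seeded"` (k-mer seeded, scalable) or `"full"` (exhaustive).
#' @param k Seed length for the seeded method.
#' @param candidate_id Optional id recorded in the `candidate_id` column.
#' @return data.frame of hits with columns `candidate_id`, `target_name`,
#'   `target_start`, `target_end` (1-based inclusive, plus-strand
#'   coordinates), `strand`, `score`, `identity_pct` (matches over aligned
#'   columns, including gap columns), `query_coverage_pct` (aligned probe
#'   span over probe length) and `is_self` (always `FALSE` here; set by
#'   [identify_self_hit()]). Sorted by descending score, ties by
#'   `(target_name, target_start)`.
#' @export
search_probe <- function(probe, genome, params = alignment_params(),
                         method = c("seeded", "full"), k = 12L,
                         candidate_id = NA_integer_) {
  method <- match.arg(method)
  pres <- if (inherits(probe, "masked_seq")) probe$residues else probe
  if (!nzchar(gsub("[Nn]", "", pres))) {
    stop("unalignable probe: sequence is all N", call. = FALSE)
  }
  if (inherits(genome, "masked_seq")) genome <- list(genome)
  stopifnot(length(genome) >= 1L)
  qlen <- nchar(pres)
  qrc <- revcomp(pres)
  rows <- list()
  for (contig in genome) {
    tres <- contig$residues
    tlen <- nchar(tres)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") pres else qrc
      windows <- if (method == "seeded") {
        cpp_kmer_windows(q, tres, as.integer(k), qlen)
      } else {
        matrix(c(0L, tlen - 1L), nrow = 1L)
      }
      if (nrow(windows) == 0L) next
      mask <- rep(FALSE, tlen)
      for (w in seq_len(nrow(windows))) {
        w0 <- windows[w, 1L]; w1 <- windows[w, 2L]
        repeat {
          sc <- cpp_best_local(q, tres, w0, w1, mask, params$match,
                               params$mismatch, abs(params$gap_open),
                               abs(params$gap_extend))
          if (sc[1L] < params$min_score) break
          r0 <- max(w0, as.integer(sc[2L]) - 3L * qlen)
          hit <- cpp_align_region(q, tres, r0, as.integer(sc[2L]), mask,
                                  params$match, params$mismatch,
                                  abs(params$gap_open),
                                  abs(params$gap_extend))
          if (hit[1L] < params$min_score) break
          ts <- as.integer(hit[4L]) + 1L; te <- as.integer(hit[5L]) + 1L
          mask[ts:te] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            candidate_id = candidate_id, target_name = contig$name,
            target_start = ts, target_end = te, strand = strand,
            score = hit[1L],
            identity_pct = 100 * hit[6L] / hit[7L],
            query_coverage_pct = 100 * (hit[3L] - hit[2L] + 1) / qlen,
            is_self = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$target_name, hits$target_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Search every candidate probe against the genome
#'
#' @param candidates A `candidate_set` from [generate_candidates()].
#' @param genome A `masked_seq` or list of them.
#' @param params [alignment_params()].
#' @inheritParams search_probe
#' @return One hits data.frame (see [search_probe()]) with `candidate_id`
#'   filled in.
#' @export
search_candidates <- function(candidates, genome,
                              params = alignment_params(),
                              method = c("seeded", "full"), k = 12L) {
  method <- match.arg(method)
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    search_probe(candidates$seq[i], genome, params, method, k,
                 candidate_id = candidates$id[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Import hits from an external aligner report
#'
#' Adapter for alignment results produced outside the package. Two
#' line-oriented dialects are supported:
#'
#' * `"tab"`: one hit per line with tab-separated fields `query_id`,
#'   `target`, `start`, `end` (0-based half-open), `strand`, `score`,
#'   `identity_pct`, `coverage_pct`. Start coordinates are shifted by +1 on
#'   import.
#' * `"vulgar"`: exonerate-style `vulgar:` summary lines
#'   (`vulgar: qid qstart qend qstrand tid tstart tend tstrand score ...`),
#'   0-based in-between coordinates; on the reverse target strand exonerate
#'   reports `tstart > tend`. Identity is not recoverable from vulgar lines
#'   and is returned as `NA`; coverage is computed when `query_lengths`
#'   supplies the probe length.
#'
#' @param path Report file path.
#' @param dialect `"tab"` or `"vulgar"`.
#' @param query_lengths Optional named vector of probe lengths (names =
#'   query ids), used to compute query coverage for the vulgar dialect.
#' @return Hits data.frame as from [search_probe()]; empty if the report has
#'   no hit lines.
#' @export
parse_external_alignments <- function(path, dialect = c("tab", "vulgar"),
                                      query_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (dialect == "tab") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) != 8L) {
        stop("malformed report line ", i, ": expected 8 tab-separated fields",
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(f[c(3, 4, 6, 7, 8)]))
      if (anyNA(num) || !(f[5] %in% c("+", "-"))) {
        stop("malformed report line ", i, call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = suppressWarnings(as.integer(f[1])),
        target_name = f[2], target_start = as.integer(num[1]) + 1L,
        target_end = as.integer(num[2]), strand = f[5], score = num[3],
        identity_pct = num[4], query_coverage_pct = num[5], is_self = FALSE,
        stringsAsFactors = FALSE)
    } else {
      if (!startsWith(ln, "vulgar:")) next
      f <- strsplit(ln, "[[:space:]]+")[[1L]]
      if (length(f) < 10L) {
        stop("malformed vulgar line ", i, call. = FALSE)
      }
      qid <- f[2]
      qs <- suppressWarnings(as.integer(f[3]))
      qe <- suppressWarnings(as.integer(f[4]))
      ts <- suppressWarnings(as.integer(f[7]))
      te <- suppressWarnings(as.integer(f[8]))
      score <- suppressWarnings(as.numeric(f[10]))
      if (anyNA(c(qs, qe, ts, te, score))) {
        stop("malformed vulgar line ", i, call. = FALSE)
      }
      tstrand <- f[9]; qstrand <- f[5]
      span <- if (tstrand == "-") c(te + 1L, ts) else c(ts + 1L, te)
      strand <- if (qstrand == tstrand) "+" else "-"
      cov <- NA_real_
      if (!is.null(query_lengths) && qid %in% names(query_lengths)) {
        cov <- 100 * abs(qe - qs) / query_lengths[[qid]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = suppressWarnings(as.integer(qid)),
        target_name = f[6], target_start = span[1L], target_end = span[2L],
        strand = strand, score = score, identity_pct = NA_real_,
        query_coverage_pct = cov, is_self = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$target_name, hits$target_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
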