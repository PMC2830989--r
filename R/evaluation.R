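#' Identify the on-target ("self") hit for a candidate probe
#'
#' The quality-assurance check of the pipeline: every genome search must
#' produce an on-target hit back to the candidate's own source coordinates.
#' The self hit is the plus-strand hit whose genomic span reciprocally
#' overlaps the candidate's `[start, end]` by at least 95% (of both spans);
#' if several qualify the highest-scoring one is taken.
#'
#' @param candidate One-row data.frame (or list) with `start`, `end` and the
#'   candidate's `id`.
#' @param hits Hits data.frame for this candidate (see [search_probe()]).
#' @param seq_name Contig the candidate lives on; only hits on it qualify.
#' @return `hits` with `is_self` set to `TRUE` on the self hit.
#' @export
identify_self_hit <- function(candidate, hits, seq_name = NULL) {
  if (nrow(hits) == 0L) {
    stop("QA failure: no hits at all for candidate ", candidate$id,
         call. = FALSE)
  }
  clen <- candidate$end - candidate$start + 1
  ov_lo <- pmax(hits$target_start, candidate$start)
  ov_hi <- pmin(hits$target_end, candidate$end)
  ov <- pmax(0, ov_hi - ov_lo + 1)
  span <- hits$target_end - hits$target_start + 1
  ok <- hits$strand == "+" & ov / clen >= 0.95 & ov / span >= 0.95
  if (!is.null(seq_name)) ok <- ok & hits$target_name == seq_name
  if (!any(ok)) {
    stop("QA failure: no on-target hit for candidate ", candidate$id,
         " at ", candidate$start, "-", candidate$end, call. = FALSE)
  }
  sel <- which(ok)[which.max(hits$score[ok])]
  hits$is_self <- FALSE
  hits$is_self[sel] <- TRUE
  hits
}

#' Self/second-hit score ratio
#'
#' The pipeline's uniqueness statistic: the on-target alignment score divided
#' by the best off-target alignment score. A candidate with no off-target hit
#' at all is "unique", represented as `Inf` (formatted as `"unique"` at
#' output boundaries).
#'
#' @param self_score On-target alignment score.
#' @param offtarget_score Best off-target score, or `NA` if none.
#' @return Ratio (>= 1 under this scoring scheme), or `Inf` when unique.
#' @export
score_ratio <- function(self_score, offtarget_score = NA) {
  if (is.na(offtarget_score)) return(Inf)
  self_score / offtarget_score
}

#' Evaluate candidate probes from their genome hits
#'
#' For every candidate: identifies the self hit, takes the highest-scoring
#' remaining hit anywhere in the genome as the best off-target match, and
#' derives the uniqueness and repeat-content metrics.
#'
#' @param candidates A `candidate_set`.
#' @param hits Combined hits data.frame (from [search_candidates()] or the
#'   external adapter) keyed by `candidate_id`.
#' @param seq_name Contig name of the design window (defaults to the spec
#'   attached to `candidates`).
#' @param on_qa_fail `"error"` stops at the first candidate without an
#'   on-target hit; `"flag"` marks it `qa_passed = FALSE` and continues.
#' @return data.frame of class `probe_evaluations`: `candidate_id`, `start`,
#'   `end`, `length`, `masked_pct`, `self_score`, `second_score` (`NA` when
#'   unique), `score_ratio` (`Inf` when unique), `second_identity_pct`,
#'   `second_coverage_pct`, `qa_passed`.
#' @export
evaluate_candidates <- function(candidates, hits, seq_name = NULL,
                                on_qa_fail = c("error", "flag")) {
  on_qa_fail <- match.arg(on_qa_fail)
  if (is.null(seq_name)) {
    spec <- attr(candidates, "spec")
    if (!is.null(spec)) seq_name <- spec$seq_name
  }
  n <- nrow(candidates)
  out <- data.frame(candidate_id = candidates$id, start = candidates$start,
                    end = candidates$end, length = candidates$length,
                    masked_pct = candidates$masked_pct,
                    self_score = NA_real_, second_score = NA_real_,
                    score_ratio = NA_real_, second_identity_pct = NA_real_,
                    second_coverage_pct = NA_real_, qa_passed = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    h <- hits[hits$candidate_id == candidates$id[i], , drop = FALSE]
    h <- tryCatch(
      identify_self_hit(candidates[i, ], h, seq_name),
      error = function(e) {
        if (on_qa_fail == "error") stop(e)
        NULL
      })
    if (is.null(h)) next
    self <- h[h$is_self, , drop = FALSE]
    off <- h[!h$is_self, , drop = FALSE]
    out$self_score[i] <- self$score[1L]
    out$qa_passed[i] <- TRUE
    if (nrow(off) > 0L) {
      b <- which.max(off$score)
      out$second_score[i] <- off$score[b]
      out$score_ratio[i] <- self$score[1L] / off$score[b]
      out$second_identity_pct[i] <- off$identity_pct[b]
      out$second_coverage_pct[i] <- off$query_coverage_pct[b]
    } else {
      out$score_ratio[i] <- Inf
    }
  }
  class(out) <- c("probe_evaluations", "data.frame")
  out
}

#' Write evaluations as TSV
#'
#' Column layout mirrors the calibration-table convention: probe name,
#' length, score ratio (3 significant figures, `"unique"` when there is no
#' off-target hit), second-hit identity and query coverage, soft-masked
#' content (1 decimal place).
#'
#' @param evaluations A `probe_evaluations` data.frame.
#' @param path Output path.
#' @param names Optional probe names (default `probe_<id>`).
#' @return `path`, invisibly.
#' @export
evaluations_to_tsv <- function(evaluations, path, names = NULL) {
  if (is.null(names)) names <- sprintf("probe_%d", evaluations$candidate_id)
  df <- data.frame(
    probe = names,
    length = evaluations$length,
    score_ratio = format_ratio(evaluations$score_ratio),
    second_identity_pct = round(evaluations$second_identity_pct, 1),
    second_coverage_pct = round(evaluations$second_coverage_pct, 1),
    masked_pct = round(evaluations$masked_pct, 1),
    stringsAsFactors = FALSE)
  if ("bin" %in% names(evaluations)) df$bin <- evaluations$bin
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# score ratios print at 3 significant figures; Inf prints as "unique"
format_ratio <- function(x) {
  out <- ifelse(is.infinite(x), "unique",
                ifelse(is.na(x), "NA", signif(x, 3)))
  as.character(out)
}
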