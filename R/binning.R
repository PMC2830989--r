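#' Classify evaluated candidates into unique / passed / failed bins
#'
#' Acceptance criteria (both thresholds inclusive):
#' * `unique`: no off-target hit at all at the search score threshold, and
#'   soft-masked content within `max_masked_pct` — the ideal single-hit probe.
#' * `passed`: score ratio at least `min_score_ratio` and soft-masked content
#'   within `max_masked_pct` (and not unique).
#' * `failed`: everything else. Candidates whose masked content is unknown
#'   (`NA`) cannot satisfy the repeat criterion and fail.
#'
#' @param evaluations A `probe_evaluations` data.frame (all rows QA-passed).
#' @param min_score_ratio Minimum self/second-hit score ratio.
#' @param max_masked_pct Maximum soft-masked base content, percent.
#' @param spec Optional [design_spec()] recorded in the result.
#' @return A `design_result`: list with `evaluations` (with a `bin` column),
#'   `counts`, `criteria_used`, `relaxed` (`FALSE`), `relaxation_trail`,
#'   `qa_passed`.
#' @export
classify_probes <- function(evaluations, min_score_ratio = 10,
                            max_masked_pct = 5, spec = NULL) {
  stopifnot(is.data.frame(evaluations))
  ev <- evaluations
  masked_ok <- !is.na(ev$masked_pct) & ev$masked_pct <= max_masked_pct
  uniq <- is.infinite(ev$score_ratio) & masked_ok
  pass <- !uniq & masked_ok & !is.na(ev$score_ratio) &
    ev$score_ratio >= min_score_ratio
  ev$bin <- ifelse(uniq, "unique", ifelse(pass, "passed", "failed"))
  new_design_result(ev, c(min_score_ratio = min_score_ratio,
                          max_masked_pct = max_masked_pct),
                    relaxed = FALSE, trail = NULL, spec = spec)
}

new_design_result <- function(ev, criteria, relaxed, trail, spec) {
  res <- list(spec = spec, evaluations = ev, counts = bin_counts(ev),
              criteria_used = criteria, relaxed = relaxed,
              relaxation_trail = trail,
              qa_passed = all(ev$qa_passed))
  class(res) <- "design_result"
  res
}

bin_counts <- function(ev) {
  bins <- c("unique", "passed", "failed", "redundant")
  counts <- vapply(bins, function(b) sum(ev$bin == b), 0L)
  names(counts) <- bins
  counts
}

#' @export
print.design_result <- function(x, ...) {
  tot <- nrow(x$evaluations)
  cat("<design_result> ", tot, " candidates\n", sep = "")
  for (b in names(x$counts)) {
    cat(sprintf("  %-9s %d/%d\n", b, x$counts[[b]], tot))
  }
  cat(sprintf("  criteria: score ratio >= %s, masked <= %s%%%s\n",
              format(x$criteria_used[["min_score_ratio"]]),
              format(x$criteria_used[["max_masked_pct"]]),
              if (x$relaxed) " (relaxed)" else ""))
  invisible(x)
}

# rank order over accepted candidates: unique before passed, then score
# ratio descending (Inf = unique sentinel sorts first), length descending,
# start ascending
rank_order <- function(ev) {
  bin_rank <- match(ev$bin, c("unique", "passed", "failed", "redundant"))
  order(bin_rank, -ev$score_ratio, -ev$length, ev$start)
}

#' Remove redundant accepted probes
#'
#' An accepted (unique or passed) candidate whose span is completely
#' contained in a longer, better-ranked accepted candidate is moved to the
#' `redundant` bin. Containment is transitive, so one comparison against the
#' pre-filter accepted set reaches the fixpoint.
#'
#' @param result A `design_result` with bins assigned.
#' @return The `design_result` with redundant probes re-binned.
#' @export
remove_redundant <- function(result) {
  ev <- result$evaluations
  acc <- which(ev$bin %in% c("unique", "passed"))
  if (length(acc) > 1L) {
    ord <- rank_order(ev)
    rankpos <- integer(nrow(ev))
    rankpos[ord] <- seq_along(ord)
    for (i in acc) {
      for (j in acc) {
        if (ev$length[j] > ev$length[i] &&
            ev$start[j] <= ev$start[i] && ev$end[j] >= ev$end[i] &&
            rankpos[j] < rankpos[i]) {
          ev$bin[i] <- "redundant"
          break
        }
      }
    }
  }
  result$evaluations <- ev
  result$counts <- bin_counts(ev)
  result
}

#' Classify with automatic cut-off relaxation
#'
#' Applies the design criteria; if no candidate is unique or passed, the
#' cut-offs are relaxed stepwise — score ratio multiplied by
#' `ratio_factor` (floored at 1), then, if still empty, the masked-content
#' ceiling raised by `masked_step` (capped at 100), alternating — until at
#' least one candidate is accepted or the fully relaxed criteria `(1, 100)`
#' are reached. The relaxation trail is recorded in the result.
#'
#' @param evaluations A `probe_evaluations` data.frame.
#' @param spec A [design_spec()] carrying the starting criteria.
#' @param ratio_factor Multiplier applied to the score-ratio cut-off per
#'   relaxation step.
#' @param masked_step Increment (percentage points) of the masked-content
#'   cut-off per relaxation step.
#' @return A `design_result`; `relaxed` is `TRUE` iff the criteria actually
#'   applied differ from the spec's.
#' @export
relax_and_reclassify <- function(evaluations, spec, ratio_factor = 0.75,
                                 masked_step = 5) {
  ratio <- spec$min_score_ratio
  masked <- spec$max_masked_pct
  res <- classify_probes(evaluations, ratio, masked, spec = spec)
  n_acc <- function(r) sum(r$counts[c("unique", "passed")])
  trail <- data.frame(min_score_ratio = ratio, max_masked_pct = masked,
                      n_accepted = n_acc(res))
  if (n_acc(res) > 0L) {
    res$relaxation_trail <- trail
    return(res)
  }
  repeat {
    ratio <- max(1, ratio_factor * ratio)
    res <- classify_probes(evaluations, ratio, masked, spec = spec)
    trail <- rbind(trail, data.frame(min_score_ratio = ratio,
                                     max_masked_pct = masked,
                                     n_accepted = n_acc(res)))
    if (n_acc(res) > 0L) break
    masked <- min(100, masked + masked_step)
    res <- classify_probes(evaluations, ratio, masked, spec = spec)
    trail <- rbind(trail, data.frame(min_score_ratio = ratio,
                                     max_masked_pct = masked,
                                     n_accepted = n_acc(res)))
    if (n_acc(res) > 0L) break
    if (ratio <= 1 && masked >= 100) {
      stop("no candidate passes even at fully relaxed cut-offs (1, 100%): ",
           "all candidates failed quality assurance", call. = FALSE)
    }
  }
  res$relaxed <- TRUE
  res$relaxation_trail <- trail
  res
}

#' Rank accepted probes
#'
#' Total order over the unique and passed bins: unique before passed, then
#' score ratio descending (the `"unique"` sentinel sorts above every finite
#' ratio), then length descending, then start ascending.
#'
#' @param result A `design_result`.
#' @return The accepted evaluations, ordered best-first.
#' @export
rank_probes <- function(result) {
  ev <- result$evaluations
  ev <- ev[rank_order(ev), , drop = FALSE]
  ev <- ev[ev$bin %in% c("unique", "passed"), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
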