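#' Design Southern blot probes in a genomic window
#'
#' End-to-end, in-memory pipeline: slice the design window from the
#' soft-masked genome, enumerate candidate probes by fractional-step tiling,
#' search every candidate against the full genome with the affine-gap local
#' aligner, evaluate uniqueness (self/second-hit score ratio) and
#' repetitive content (soft-masked base fraction), classify into
#' unique/passed/failed bins with automatic cut-off relaxation at difficult
#' loci, remove redundant probes, rank the survivors and pick PCR recovery
#' primers for the best of them.
#'
#' @param genome Path to a soft-masked FASTA, a `masked_seq`, or a list of
#'   them.
#' @param seq_name Contig holding the design window (defaults to the first
#'   contig).
#' @param window_start,window_end 1-based inclusive window coordinates.
#' @param spec A [design_spec()]; if supplied, the window/tuning arguments
#'   are ignored.
#' @param method,k Search method and seed length, see [search_probe()].
#' @param n_primers Number of top-ranked probes to design primers for.
#' @param primer_cons [primer_constraints()].
#' @param ... Further arguments to [design_spec()] (`min_len`, `max_len`,
#'   `step_fraction`, `length_decrement`, `min_score`, `min_score_ratio`,
#'   `max_masked_pct`).
#' @return An object of class `probe_design` (extending `design_result`):
#'   fields `spec`, `candidates`, `hits`, `evaluations` (with `bin`),
#'   `counts`, `criteria_used`, `relaxed`, `relaxation_trail`, `qa_passed`,
#'   `ranked`, `primers`, `profile`.
#' @seealso [print.probe_design()], [summary.probe_design()],
#'   [plot.probe_design()], [render_report()]
#' @export
design_probes <- function(genome, seq_name = NULL, window_start, window_end,
                          spec = NULL, method = c("seeded", "full"), k = 12L,
                          n_primers = 5L,
                          primer_cons = primer_constraints(), ...) {
  method <- match.arg(method)
  if (is.character(genome) && length(genome) == 1L) {
    genome <- load_fasta(genome)
  }
  if (inherits(genome, "masked_seq")) genome <- list(genome)
  names(genome) <- vapply(genome, `[[`, "", "name")
  if (is.null(spec)) {
    if (is.null(seq_name)) seq_name <- genome[[1L]]$name
    spec <- design_spec(seq_name, window_start, window_end, ...)
  }
  contig <- genome[[spec$seq_name]]
  if (is.null(contig)) stop("sequence '", spec$seq_name,
                            "' not found in genome", call. = FALSE)
  window <- slice_seq(contig, spec$window_start, spec$window_end)

  candidates <- generate_candidates(spec, window)
  params <- alignment_params(min_score = spec$min_score)
  hits <- search_candidates(candidates, genome, params, method, k)
  evaluations <- evaluate_candidates(candidates, hits,
                                     seq_name = spec$seq_name,
                                     on_qa_fail = "flag")
  qa_all <- all(evaluations$qa_passed)
  result <- relax_and_reclassify(evaluations[evaluations$qa_passed, ,
                                             drop = FALSE], spec)
  result <- remove_redundant(result)
  ranked <- rank_probes(result)

  primers <- list()
  n_p <- min(n_primers, nrow(ranked))
  for (i in seq_len(n_p)) {
    id <- ranked$candidate_id[i]
    cand <- candidates[candidates$id == id, ]
    primers[[sprintf("probe_%d", id)]] <- tryCatch(
      pick_primers(cand$seq, cand$start, primer_cons),
      error = function(e) NULL)
  }

  design <- result
  design$spec <- spec
  design$qa_passed <- qa_all
  design$candidates <- candidates
  design$hits <- hits
  design$ranked <- ranked
  design$primers <- primers
  design$profile <- frequency_profile(result)
  class(design) <- c("probe_design", "design_result")
  design
}

#' @export
print.probe_design <- function(x, ...) {
  spec <- x$spec
  tot <- nrow(x$evaluations)
  cat(sprintf("Southern blot probe design: %s:%d-%d\n", spec$seq_name,
              spec$window_start, spec$window_end))
  cat(sprintf("  %d candidates (%d-%d bp)   QA %s\n", nrow(x$candidates),
              spec$min_len, spec$max_len,
              if (isTRUE(x$qa_passed)) "passed" else "FAILED"))
  for (b in c("unique", "passed", "failed", "redundant")) {
    cat(sprintf("  %-9s %d/%d\n", b, x$counts[[b]], tot))
  }
  cat(sprintf("  criteria: score ratio >= %s, masked <= %s%%%s\n",
              format(x$criteria_used[["min_score_ratio"]]),
              format(x$criteria_used[["max_masked_pct"]]),
              if (x$relaxed) " (relaxed)" else ""))
  if (nrow(x$ranked) > 0L) {
    b <- x$ranked[1L, ]
    cat(sprintf("  best probe: probe_%d %s:%d-%d (%d bp, ratio %s, masked %.1f%%)\n",
                b$candidate_id, spec$seq_name, b$start, b$end, b$length,
                format_ratio(b$score_ratio), b$masked_pct))
  } else {
    cat("  no probe accepted: difficult locus\n")
  }
  invisible(x)
}

#' Summarize a probe design
#'
#' @param object A `probe_design`.
#' @param ... Unused.
#' @return data.frame of per-metric mean and standard error over the
#'   evaluated candidates (see [summarize_evaluations()]), invisibly;
#'   printed together with the bin counts.
#' @export
summary.probe_design <- function(object, ...) {
  print(object)
  s <- summarize_evaluations(object$evaluations)
  cat("\nCandidate metrics (mean +/- SE):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s %8.1f +/- %.1f  (n=%d)\n", s$metric[i], s$mean[i],
                s$se[i], s$n[i]))
  }
  invisible(s)
}

#' Plot the per-base bin frequency profile
#'
#' Coverage of each design-window base by unique, passed and failed
#' candidates, the plot rendered in the static design report.
#'
#' @param x A `probe_design`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.probe_design <- function(x, ...) {
  p <- x$profile
  graphics::matplot(p$position, cbind(p$unique, p$passed, p$failed),
                    type = "l", lty = 1, lwd = 2,
                    col = c("goldenrod", "forestgreen", "firebrick"),
                    xlab = sprintf("position on %s", x$spec$seq_name),
                    ylab = "candidates covering base", ...)
  graphics::legend("topright", legend = c("unique", "passed", "failed"),
                   col = c("goldenrod", "forestgreen", "firebrick"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
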