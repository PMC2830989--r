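#' Summary statistics over probe evaluations
#'
#' Mean and standard error (sample SD / sqrt(n)) of probe length, score
#' ratio, second-hit identity, second-hit query coverage and soft-masked
#' content. Each metric uses its pairwise-complete n: missing values are
#' dropped, and for the score ratio the `"unique"` sentinel (`Inf`) is not a
#' number and is likewise excluded. With fewer than two values the SE is
#' reported absent.
#'
#' @param evaluations A data.frame with columns `length`, `score_ratio`,
#'   `second_identity_pct`, `second_coverage_pct`, `masked_pct`.
#' @return data.frame with columns `metric`, `n`, `mean`, `se`.
#' @export
summarize_evaluations <- function(evaluations) {
  metrics <- c(length = "length", score_ratio = "score_ratio",
               second_identity_pct = "second_identity_pct",
               second_coverage_pct = "second_coverage_pct",
               masked_pct = "masked_pct")
  rows <- lapply(names(metrics), function(m) {
    x <- evaluations[[metrics[[m]]]]
    x <- x[!is.na(x) & is.finite(x)]
    n <- length(x)
    data.frame(metric = m, n = n,
               mean = if (n >= 1L) mean(x) else NA_real_,
               se = if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-base bin coverage profile across the design window
#'
#' For every base of the design window, the number of unique, passed and
#' failed candidates covering it — the data behind the design-report
#' coverage plot.
#'
#' @param result A `design_result` with bins assigned.
#' @return data.frame of class `frequency_profile`: `position` (1-based
#'   genomic), `unique`, `passed`, `failed`.
#' @export
frequency_profile <- function(result) {
  spec <- result$spec
  stopifnot(!is.null(spec))
  pos <- spec$window_start:spec$window_end
  n <- length(pos)
  out <- data.frame(position = pos, unique = 0L, passed = 0L, failed = 0L)
  ev <- result$evaluations
  for (b in c("unique", "passed", "failed")) {
    rows <- ev[ev$bin == b, , drop = FALSE]
    if (nrow(rows) == 0L) next
    delta <- integer(n + 1L)
    s <- pmax(rows$start, spec$window_start) - spec$window_start + 1L
    e <- pmin(rows$end, spec$window_end) - spec$window_start + 1L
    for (i in seq_len(nrow(rows))) {
      delta[s[i]] <- delta[s[i]] + 1L
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
    }
    out[[b]] <- cumsum(delta[seq_len(n)])
  }
  class(out) <- c("frequency_profile", "data.frame")
  out
}

#' Render the static design report
#'
#' Writes the file set a finished design is inspected from: a plain-text
#' report (window coordinates, per-bin counts in `n/total` form, QA status,
#' criteria applied including any relaxation trail, ranked probe table and
#' primer table), the frequency profile as TSV, the ranked probe table as
#' TSV, plus FASTA and BED of the accepted probes when sequences are
#' available. Output is deterministic: re-rendering the same result is
#' byte-identical.
#'
#' @param design A `probe_design` (from [design_probes()]) or
#'   `design_result`.
#' @param dir Output directory, created if needed.
#' @param max_table_rows Ranked probes shown in the text report.
#' @return Named vector of written file paths, invisibly.
#' @export
render_report <- function(design, dir, max_table_rows = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable directory: ", dir, call. = FALSE)
  spec <- design$spec
  ev <- design$evaluations
  tot <- nrow(ev)
  ranked <- rank_probes(design)
  profile <- if (!is.null(design$profile)) design$profile else
    frequency_profile(design)

  lines <- c(
    "Southern blot probe design report",
    "=================================",
    sprintf("Design window : %s:%d-%d (%d bp)", spec$seq_name,
            spec$window_start, spec$window_end,
            spec$window_end - spec$window_start + 1L),
    sprintf("Probe lengths : %d-%d bp, step %.0f%% of probe length, decrement %d bp",
            spec$min_len, spec$max_len, 100 * spec$step_fraction,
            spec$length_decrement),
    sprintf("QA status     : %s",
            if (isTRUE(design$qa_passed)) "PASSED (all searches on-target)"
            else "FAILED (some candidates without on-target hit)"),
    "",
    "Bin counts",
    "----------")
  for (b in c("unique", "passed", "failed", "redundant")) {
    lines <- c(lines, sprintf("  %-9s %d/%d", b, design$counts[[b]], tot))
  }
  lines <- c(lines, "",
             sprintf("Criteria applied: score ratio >= %s, masked <= %s%%%s",
                     format(design$criteria_used[["min_score_ratio"]]),
                     format(design$criteria_used[["max_masked_pct"]]),
                     if (design$relaxed) " (RELAXED from design criteria)"
                     else ""))
  if (design$relaxed && !is.null(design$relaxation_trail)) {
    lines <- c(lines, "Relaxation trail:")
    tr <- design$relaxation_trail
    for (i in seq_len(nrow(tr))) {
      lines <- c(lines, sprintf("  ratio >= %-8s masked <= %-6s accepted %d",
                                format(signif(tr$min_score_ratio[i], 3)),
                                format(tr$max_masked_pct[i]),
                                tr$n_accepted[i]))
    }
  }
  if (nrow(ranked) == 0L) {
    lines <- c(lines, "",
               "No probe accepted even after relaxation: difficult locus.")
  } else {
    lines <- c(lines, "", "Ranked probes (best first)",
               "--------------------------",
               sprintf("%-10s %-6s %-22s %-7s %-11s %-7s", "probe", "bin",
                       "coords", "length", "score_ratio", "masked%"))
    top <- utils::head(ranked, max_table_rows)
    for (i in seq_len(nrow(top))) {
      lines <- c(lines, sprintf(
        "%-10s %-6s %-22s %-7d %-11s %-7s",
        sprintf("probe_%d", top$candidate_id[i]), top$bin[i],
        sprintf("%s:%d-%d", spec$seq_name, top$start[i], top$end[i]),
        top$length[i], format_ratio(top$score_ratio[i]),
        format(round(top$masked_pct[i], 1))))
    }
  }
  if (!is.null(design$primers) && length(design$primers) > 0L) {
    lines <- c(lines, "", "Recovery primers", "----------------")
    for (nm in names(design$primers)) {
      p <- design$primers[[nm]]
      if (is.null(p)) {
        lines <- c(lines, sprintf("  %s: no primers", nm))
      } else {
        lines <- c(lines, sprintf(
          "  %s: %s / %s  product %d bp  Tm %.1f/%.1f",
          nm, p$left_seq, p$right_seq, p$product_length, p$left_tm,
          p$right_tm))
      }
    }
  }
  report <- file.path(dir, "report.txt")
  writeLines(lines, report)

  prof_path <- file.path(dir, "profile.tsv")
  utils::write.table(as.data.frame(profile), prof_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  probes_path <- file.path(dir, "probes.tsv")
  evaluations_to_tsv(ranked, probes_path)
  out <- c(report = report, profile = prof_path, probes = probes_path)

  if (!is.null(design$primers) && length(design$primers) > 0L) {
    out["primers"] <- primers_to_tsv(design$primers,
                                     file.path(dir, "primers.tsv"))
  }
  if (!is.null(design$candidates) && nrow(ranked) > 0L) {
    acc <- design$candidates[design$candidates$id %in% ranked$candidate_id, ,
                             drop = FALSE]
    attr(acc, "spec") <- spec  # [ drops the attribute
    out["fasta"] <- candidates_to_fasta(acc, file.path(dir, "probes.fa"))
    out["bed"] <- candidates_to_bed(acc, file.path(dir, "probes.bed"))
  }
  invisible(out)
}
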