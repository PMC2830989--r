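#' Probe design specification
#'
#' Bundles the design window and every tiling, search and acceptance
#' parameter. Defaults reflect typical Southern blot probe design practice:
#' probes of 500-1300 bp, a tiling step of 5% of the current probe length, a
#' 50 bp length decrement between tiling rounds, an alignment score threshold
#' of 150, acceptance at a self/second-hit score ratio of at least 10 and at
#' most 5% soft-masked (repetitive + low-complexity) bases.
#'
#' @param seq_name Name of the genome sequence holding the design window.
#' @param window_start,window_end 1-based inclusive window coordinates.
#' @param min_len,max_len Probe length range in bp.
#' @param step_fraction Tiling step as a fraction of the current probe length;
#'   the step is `max(1, floor(step_fraction * length))` bp.
#' @param length_decrement Probe length reduction between tiling rounds, bp.
#' @param min_score Minimum local alignment score for a reported genome hit.
#' @param min_score_ratio Minimum self/second-hit score ratio for acceptance.
#' @param max_masked_pct Maximum soft-masked base content (%) for acceptance.
#' @param genome_path Optional path to the genome FASTA (used by the on-disk
#'   pipeline store).
#' @return A `design_spec` list.
#' @export
design_spec <- function(seq_name, window_start, window_end,
                        min_len = 500L, max_len = 1300L,
                        step_fraction = 0.05, length_decrement = 50L,
                        min_score = 150, min_score_ratio = 10,
                        max_masked_pct = 5, genome_path = NULL) {
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  length_decrement <- as.integer(length_decrement)
  wlen <- window_end - window_start + 1L
  stopifnot(window_start >= 1L, window_end >= window_start)
  if (!(min_len > 0L && min_len <= max_len)) {
    stop("need 0 < min_len <= max_len", call. = FALSE)
  }
  if (max_len > wlen) {
    # permitted: tiling simply skips lengths above the window
    if (min_len > wlen) stop("window too small: length ", wlen,
                             " < min_len ", min_len, call. = FALSE)
  }
  stopifnot(step_fraction > 0, step_fraction <= 1, length_decrement >= 1L,
            min_score_ratio >= 1, max_masked_pct >= 0, max_masked_pct <= 100,
            min_score > 0)
  structure(list(seq_name = seq_name, window_start = window_start,
                 window_end = window_end, min_len = min_len,
                 max_len = max_len, step_fraction = step_fraction,
                 length_decrement = length_decrement, min_score = min_score,
                 min_score_ratio = min_score_ratio,
                 max_masked_pct = max_masked_pct,
                 genome_path = genome_path),
            class = "design_spec")
}

#' Enumerate candidate probes by fractional-step tiling
#'
#' Tiles the design window starting from the maximum allowable probe length,
#' moving by `max(1, floor(step_fraction * length))` bp per step; when a
#' length is exhausted the probe length is reduced by `length_decrement` and
#' the window re-tiled, until the minimum probe length would be passed.
#' Lengths exceeding the window are skipped. Candidates are emitted
#' longest-first, left-to-right, with sequential ids; duplicate `(start,end)`
#' spans (possible when the step clamps to 1) collapse to one candidate.
#'
#' @param spec A [design_spec()].
#' @param window `masked_seq` of the design window itself (its first residue
#'   is coordinate `spec$window_start` on the source sequence).
#' @return data.frame of class `candidate_set` with columns `id`, `start`,
#'   `end` (1-based inclusive on the window's contig), `length`, `seq`
#'   (case-preserving residues) and `masked_pct`.
#' @export
generate_candidates <- function(spec, window) {
  stopifnot(inherits(spec, "design_spec"), inherits(window, "masked_seq"))
  wlen <- seq_length(window)
  if (wlen != spec$window_end - spec$window_start + 1L) {
    stop("window sequence length does not match spec coordinates",
         call. = FALSE)
  }
  if (wlen < spec$min_len) stop("window too small: length ", wlen,
                                " < min_len ", spec$min_len, call. = FALSE)
  lens <- seq(spec$max_len, spec$min_len, by = -spec$length_decrement)
  lens <- lens[lens <= wlen]
  starts_all <- integer(0); lens_all <- integer(0)
  for (p in lens) {
    step <- max(1L, as.integer(floor(spec$step_fraction * p)))
    n <- (wlen - p) %/% step + 1L
    st <- seq.int(1L, by = step, length.out = n)
    starts_all <- c(starts_all, st)
    lens_all <- c(lens_all, rep.int(p, n))
  }
  ends_all <- starts_all + lens_all - 1L
  keep <- !duplicated(cbind(starts_all, ends_all))
  starts_all <- starts_all[keep]; ends_all <- ends_all[keep]
  lens_all <- lens_all[keep]
  seqs <- substring(window$residues, starts_all, ends_all)
  out <- data.frame(
    id = seq_along(starts_all),
    start = spec$window_start + starts_all - 1L,
    end = spec$window_start + ends_all - 1L,
    length = lens_all,
    seq = seqs,
    masked_pct = 100 * vapply(seqs, lowercase_count, 0L,
                              USE.NAMES = FALSE) / lens_all,
    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Write candidates as multi-FASTA
#'
#' Headers carry the candidate id and source coordinates, e.g.
#' `>probe_12 chr2:1001-2300`.
#'
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
candidates_to_fasta <- function(candidates, path) {
  spec <- attr(candidates, "spec")
  seqs <- lapply(seq_len(nrow(candidates)), function(i) {
    masked_seq(sprintf("probe_%d %s:%d-%d", candidates$id[i], spec$seq_name,
                       candidates$start[i], candidates$end[i]),
               candidates$seq[i])
  })
  write_fasta(seqs, path)
}

#' Write candidates as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
candidates_to_bed <- function(candidates, path) {
  spec <- attr(candidates, "spec")
  df <- data.frame(chrom = spec$seq_name, start = candidates$start - 1L,
                   end = candidates$end,
                   name = sprintf("probe_%d", candidates$id))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
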