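# On-disk, resumable pipeline store: one directory per design holding JSON
# and TSV artifacts. Mirrors the classic three-step decomposition
# (create -> search -> analyse) with candidate batches that can be searched
# independently, in parallel, and re-run after deletion.

design_json <- function(dir) file.path(dir, "design.json")
batch_file <- function(dir, b) file.path(dir, "batches",
                                         sprintf("hits_%04d.tsv", b))

#' Create a probe design in an on-disk store
#'
#' Tiles the design window and persists the design specification and the
#' candidate probes; searching is grouped into batches for
#' [store_search()].
#'
#' @param spec A [design_spec()] whose `genome_path` points at the
#'   soft-masked genome FASTA.
#' @param dir Design directory (created; must not already hold a design
#'   unless `overwrite`).
#' @param batch_size Candidates per search batch.
#' @param method,k Search method and seed length recorded for
#'   [store_search()].
#' @param overwrite Replace an existing design?
#' @return `dir`, invisibly.
#' @export
store_create <- function(spec, dir, batch_size = 50L,
                         method = c("seeded", "full"), k = 12L,
                         overwrite = FALSE) {
  method <- match.arg(method)
  if (is.null(spec$genome_path) || !file.exists(spec$genome_path)) {
    stop("spec$genome_path must point at the genome FASTA", call. = FALSE)
  }
  if (file.exists(design_json(dir)) && !overwrite) {
    stop("design already exists in ", dir, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(file.path(dir, "batches"), showWarnings = FALSE,
             recursive = TRUE)
  genome <- load_fasta(spec$genome_path)
  contig <- genome[[spec$seq_name]]
  if (is.null(contig)) stop("sequence '", spec$seq_name,
                            "' not found in genome", call. = FALSE)
  window <- slice_seq(contig, spec$window_start, spec$window_end)
  candidates <- generate_candidates(spec, window)
  n_batches <- as.integer(ceiling(nrow(candidates) / batch_size))
  meta <- c(unclass(spec),
            list(batch_size = as.integer(batch_size),
                 n_batches = n_batches, n_candidates = nrow(candidates),
                 method = method, k = as.integer(k)))
  jsonlite::write_json(meta, design_json(dir), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(as.data.frame(candidates), file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

store_meta <- function(dir) {
  if (!file.exists(design_json(dir))) {
    stop("unknown design: no design.json in ", dir, call. = FALSE)
  }
  jsonlite::read_json(design_json(dir), simplifyVector = TRUE)
}

store_spec <- function(meta) {
  design_spec(meta$seq_name, meta$window_start, meta$window_end,
              meta$min_len, meta$max_len, meta$step_fraction,
              meta$length_decrement, meta$min_score, meta$min_score_ratio,
              meta$max_masked_pct, genome_path = meta$genome_path)
}

store_candidates <- function(dir, meta) {
  cand <- utils::read.table(file.path(dir, "candidates.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(seq = "character"))
  attr(cand, "spec") <- store_spec(meta)
  class(cand) <- c("candidate_set", "data.frame")
  cand
}

batch_ids <- function(meta, b) {
  lo <- (b - 1L) * meta$batch_size + 1L
  hi <- min(b * meta$batch_size, meta$n_candidates)
  lo:hi
}

#' Run (or resume) the genome searches of a design
#'
#' Searches the candidates of every batch that has no stored result yet and
#' writes one hits TSV per batch; completed batches are skipped, so an
#' interrupted run resumes where it stopped. Batches are independent: `map`
#' may be a parallel map (e.g. `parallel::mclapply`) with the same contract
#' as `lapply`.
#'
#' @param dir Design directory from [store_create()].
#' @param batches Batch numbers to (re)run; default: all missing ones.
#' @param map A `lapply`-like function used to iterate over batches.
#' @return Integer vector of batch numbers searched, invisibly.
#' @export
store_search <- function(dir, batches = NULL, map = lapply) {
  meta <- store_meta(dir)
  if (is.null(batches)) {
    batches <- Filter(function(b) !file.exists(batch_file(dir, b)),
                      seq_len(meta$n_batches))
  }
  batches <- as.integer(batches)
  if (length(batches) == 0L) return(invisible(integer(0)))
  genome <- load_fasta(meta$genome_path)
  cand <- store_candidates(dir, meta)
  params <- alignment_params(min_score = meta$min_score)
  map(batches, function(b) {
    rows <- cand[batch_ids(meta, b), , drop = FALSE]
    attr(rows, "spec") <- attr(cand, "spec")
    class(rows) <- class(cand)
    hits <- search_candidates(rows, genome, params, meta$method, meta$k)
    utils::write.table(hits, batch_file(dir, b), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    b
  })
  invisible(batches)
}

#' Analyse a searched design
#'
#' Verifies that every search batch has completed (mirroring the pipeline's
#' completeness check), then evaluates, bins (with automatic relaxation),
#' filters redundancy, ranks, picks recovery primers and renders the static
#' report into the design directory.
#'
#' @param dir Design directory.
#' @param n_primers Top-ranked probes to design primers for.
#' @param primer_cons [primer_constraints()].
#' @return The `probe_design` object, invisibly.
#' @export
store_analyse <- function(dir, n_primers = 5L,
                          primer_cons = primer_constraints()) {
  meta <- store_meta(dir)
  missing <- Filter(function(b) !file.exists(batch_file(dir, b)),
                    seq_len(meta$n_batches))
  if (length(missing) > 0L) {
    stop("searches incomplete: missing batches ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cand <- store_candidates(dir, meta)
  hits <- do.call(rbind, lapply(seq_len(meta$n_batches), function(b) {
    utils::read.table(batch_file(dir, b), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c(target_name = "character"))
  }))
  spec <- store_spec(meta)
  evaluations <- evaluate_candidates(cand, hits, seq_name = spec$seq_name,
                                     on_qa_fail = "flag")
  qa_all <- all(evaluations$qa_passed)
  result <- relax_and_reclassify(evaluations[evaluations$qa_passed, ,
                                             drop = FALSE], spec)
  result <- remove_redundant(result)
  ranked <- rank_probes(result)
  primers <- list()
  for (i in seq_len(min(n_primers, nrow(ranked)))) {
    id <- ranked$candidate_id[i]
    cr <- cand[cand$id == id, ]
    primers[[sprintf("probe_%d", id)]] <- tryCatch(
      pick_primers(cr$seq, cr$start, primer_cons),
      error = function(e) NULL)
  }
  design <- result
  design$spec <- spec
  design$qa_passed <- qa_all
  design$candidates <- cand
  design$hits <- hits
  design$ranked <- ranked
  design$primers <- primers
  design$profile <- frequency_profile(result)
  class(design) <- c("probe_design", "design_result")

  evaluations_to_tsv(design$evaluations, file.path(dir, "evaluations.tsv"))
  jsonlite::write_json(
    list(criteria_used = as.list(design$criteria_used),
         relaxed = design$relaxed,
         relaxation_trail = design$relaxation_trail,
         counts = as.list(design$counts), qa_passed = design$qa_passed,
         evaluations = design$evaluations),
    file.path(dir, "result.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  render_report(design, dir)
  invisible(design)
}

#' Load a serialized design result back from the store
#'
#' Round-trips the `result.json` written by [store_analyse()] into a
#' `probe_design` identical (up to floating-point text representation) to
#' the analysed object, sufficient to re-render the report byte-identically.
#'
#' @param dir Design directory.
#' @param n_primers,primer_cons Primer settings used to reconstruct the
#'   primer table deterministically.
#' @return A `probe_design`.
#' @export
store_load_result <- function(dir, n_primers = 5L,
                              primer_cons = primer_constraints()) {
  meta <- store_meta(dir)
  rj <- jsonlite::read_json(file.path(dir, "result.json"),
                            simplifyVector = TRUE)
  spec <- store_spec(meta)
  ev <- rj$evaluations
  ev$score_ratio[is.na(ev$score_ratio) & is.na(ev$second_score) &
                   !is.na(ev$self_score)] <- Inf
  class(ev) <- c("probe_evaluations", "data.frame")
  design <- new_design_result(
    ev, unlist(rj$criteria_used), relaxed = rj$relaxed,
    trail = rj$relaxation_trail, spec = spec)
  design$qa_passed <- rj$qa_passed
  design$candidates <- store_candidates(dir, meta)
  design$ranked <- rank_probes(design)
  primers <- list()
  for (i in seq_len(min(n_primers, nrow(design$ranked)))) {
    id <- design$ranked$candidate_id[i]
    cr <- design$candidates[design$candidates$id == id, ]
    primers[[sprintf("probe_%d", id)]] <- tryCatch(
      pick_primers(cr$seq, cr$start, primer_cons),
      error = function(e) NULL)
  }
  design$primers <- primers
  design$profile <- frequency_profile(design)
  class(design) <- c("probe_design", "design_result")
  design
}

#' Delete a design from the store
#' @param dir Design directory.
#' @return `TRUE` invisibly.
#' @export
store_delete_design <- function(dir) {
  store_meta(dir)  # errors on unknown design
  unlink(dir, recursive = TRUE)
  invisible(TRUE)
}

#' Delete one search batch so it can be re-run
#' @param dir Design directory.
#' @param batch Batch number.
#' @return `TRUE` invisibly.
#' @export
store_delete_batch <- function(dir, batch) {
  meta <- store_meta(dir)
  f <- batch_file(dir, as.integer(batch))
  if (!file.exists(f)) stop("no results stored for batch ", batch,
                            call. = FALSE)
  unlink(f)
  invisible(TRUE)
}

#' Progress counters for a design
#'
#' @param dir Design directory.
#' @return List: candidate count, batches total/done, hits parsed so far,
#'   analysed flag.
#' @export
store_stats <- function(dir) {
  meta <- store_meta(dir)
  done <- Filter(function(b) file.exists(batch_file(dir, b)),
                 seq_len(meta$n_batches))
  nhits <- sum(vapply(done, function(b) {
    max(0L, length(readLines(batch_file(dir, b), warn = FALSE)) - 1L)
  }, 0L))
  list(n_candidates = meta$n_candidates, n_batches = meta$n_batches,
       batches_done = length(done), hits = nhits,
       analysed = file.exists(file.path(dir, "result.json")))
}
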