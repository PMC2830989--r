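#' Soft-masked nucleotide sequence
#'
#' Constructs a `masked_seq`: a named DNA sequence in which lowercase residues
#' mark soft-masked bases (repetitive or low-complexity sequence, as annotated
#' by RepeatMasker/DUST-style screening of the assembly). Only the residues
#' `A,C,G,T,N` in either case are permitted; any other IUPAC nucleotide code
#' is converted to `N` (case preserved), and anything beyond IUPAC is an
#' error.
#'
#' All coordinates in the package are 1-based and fully inclusive (Ensembl
#' convention).
#'
#' @param name Sequence identifier.
#' @param residues Single character string of residues.
#' @return An object of class `masked_seq` with fields `name` and `residues`.
#' @examples
#' s <- masked_seq("chr1", "ACgtA")
#' seq_length(s)
#' masked_fraction(s)
#' @export
masked_seq <- function(name, residues) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- normalize_residues(residues)
  structure(list(name = name, residues = residues), class = "masked_seq")
}

# Map IUPAC ambiguity codes to N (case preserved); reject non-IUPAC symbols.
normalize_residues <- function(residues) {
  bad <- gsub("[ACGTNacgtn]", "", residues)
  if (nzchar(bad)) {
    iupac <- "RYSWKMBDHVUryswkmbdhvu"
    noniupac <- gsub(sprintf("[%s]", iupac), "", bad)
    if (nzchar(noniupac)) {
      stop("non-nucleotide residue(s) in sequence: '",
           substr(noniupac, 1L, 10L), "'", call. = FALSE)
    }
    residues <- chartr("RYSWKMBDHVUryswkmbdhvu",
                       paste(c(rep("N", 11L), rep("n", 11L)), collapse = ""),
                       residues)
  }
  residues
}

#' @export
print.masked_seq <- function(x, ...) {
  n <- seq_length(x)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<masked_seq> %s: %d bp, %.1f%% masked\n  %s%s\n",
              x$name, n, masked_fraction(x), head,
              if (n > 60L) "..." else ""))
  invisible(x)
}

#' Length of a sequence in bases
#' @param seq A `masked_seq`.
#' @return Integer number of residues.
#' @export
seq_length <- function(seq) {
  stopifnot(inherits(seq, "masked_seq"))
  nchar(seq$residues)
}

#' @export
as.character.masked_seq <- function(x, ...) x$residues

#' Load a soft-masked FASTA file
#'
#' Reads every record of a FASTA file, preserving residue case exactly
#' (lowercase = soft-masked). IUPAC ambiguity codes other than `ACGTN` are
#' converted to `N`/`n`; residues outside the IUPAC nucleotide alphabet are
#' rejected with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `masked_seq`, in file order.
#' @seealso [write_fasta()]
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    nm <- attr(recs[[i]], "name")
    res <- as.character(recs[[i]])[1L]
    if (is.na(res) || !nzchar(res)) {
      stop("empty FASTA record '", nm, "' in ", path, call. = FALSE)
    }
    out[[i]] <- tryCatch(
      masked_seq(nm, res),
      error = function(e) {
        stop("record '", nm, "': ", conditionMessage(e),
             " (first offending line: ", find_bad_fasta_line(path), ")",
             call. = FALSE)
      })
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# Error path only: locate the first sequence line with a non-IUPAC symbol.
find_bad_fasta_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    if (nzchar(gsub("[ACGTNRYSWKMBDHVUacgtnryswkmbdhvu]", "", ln))) return(i)
  }
  NA_integer_
}

#' Write sequences as FASTA
#'
#' Case-preserving FASTA writer, wrapped at 60 columns.
#'
#' @param seqs A `masked_seq` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "masked_seq")) seqs <- list(seqs)
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) s$residues),
    names = vapply(seqs, `[[`, "", "name"),
    file.out = path, as.string = TRUE, nbchar = 60L)
  invisible(path)
}

#' Extract a sub-sequence (1-based, inclusive)
#'
#' @param seq A `masked_seq`.
#' @param start,end 1-based inclusive coordinates; must satisfy
#'   `1 <= start <= end <= seq_length(seq)`. Out-of-range coordinates are an
#'   error, never clamped.
#' @return A `masked_seq` of length `end - start + 1`; its name records the
#'   source sequence and coordinates as `"<name>:<start>-<end>"`.
#' @export
slice_seq <- function(seq, start, end) {
  stopifnot(inherits(seq, "masked_seq"))
  n <- seq_length(seq)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop(sprintf("slice [%s,%s] out of range for '%s' (length %d)",
                 start, end, seq$name, n), call. = FALSE)
  }
  masked_seq(sprintf("%s:%d-%d", seq$name, start, end),
             substr(seq$residues, start, end))
}

#' Soft-masked base content of a sequence
#'
#' Percentage of lowercase (soft-masked) residues; the pipeline's estimate of
#' a probe's combined repetitive and low-complexity DNA content. `n` counts as
#' masked, `N` as unmasked.
#'
#' @param seq A `masked_seq` or a plain character string.
#' @return Percentage in `[0, 100]`.
#' @export
masked_fraction <- function(seq) {
  res <- if (inherits(seq, "masked_seq")) seq$residues else seq
  n <- nchar(res)
  if (is.na(n) || n == 0L) stop("empty sequence", call. = FALSE)
  100 * lowercase_count(res) / n
}

lowercase_count <- function(residues) {
  nchar(gsub("[^a-z]", "", residues))
}

#' Reverse complement, preserving soft-mask state
#'
#' @param seq A `masked_seq` or character string.
#' @return Same type as the input.
#' @export
revcomp <- function(seq) {
  is_ms <- inherits(seq, "masked_seq")
  res <- if (is_ms) seq$residues else seq
  rc <- chartr("ACGTacgtNn", "TGCAtgcaNn",
               paste(rev(strsplit(res, "", fixed = TRUE)[[1L]]), collapse = ""))
  if (is_ms) masked_seq(paste0(seq$name, "_rc"), rc) else rc
}
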