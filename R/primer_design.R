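# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K), per dinucleotide step read 5'->3'.
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from unified nearest-neighbor thermodynamics
#' (SantaLucia 1998): `Tm = 1000 dH / (dS' + R ln(C/4)) - 273.15` with the
#' entropy salt correction `dS' = dS + 0.368 (N-1) ln[Na+]`, where `C` is the
#' total oligo concentration and `N` the primer length. Defaults (50 mM
#' monovalent salt, 250 nM oligo) are conventional PCR primer conditions.
#'
#' @param seq Primer sequence (ACGT; case ignored).
#' @param na_mM Monovalent cation concentration, mM.
#' @param conc_nM Total oligonucleotide concentration, nM.
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(seq, na_mM = 50, conc_nM = 250) {
  s <- toupper(seq)
  n <- nchar(s)
  stopifnot(n >= 2L)
  if (grepl("[^ACGT]", s)) stop("primer_tm: sequence must be ACGT only",
                                call. = FALSE)
  steps <- substring(s, 1:(n - 1), 2:n)
  dH <- sum(.nn_dH[steps])
  dS <- sum(.nn_dS[steps])
  for (t in c(substr(s, 1, 1), substr(s, n, n))) {
    if (t %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

#' Primer picking constraints
#'
#' @param min_len,max_len Primer length bounds, bases.
#' @param gc_min,gc_max GC content bounds, percent.
#' @param tm_min,tm_max Melting temperature window, degrees Celsius.
#' @param max_tm_diff Maximum |left Tm - right Tm|, degrees Celsius.
#' @param na_mM,conc_nM Thermodynamic conditions for [primer_tm()].
#' @param max_run Maximum run of a single base.
#' @param min_product_frac Minimum product length as a fraction of the probe
#'   length.
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 27L,
                               gc_min = 40, gc_max = 60,
                               tm_min = 57, tm_max = 63, max_tm_diff = 3,
                               na_mM = 50, conc_nM = 250, max_run = 4L,
                               min_product_frac = 0.8) {
  structure(as.list(environment()), class = "primer_constraints")
}

gc_pct <- function(seq) {
  s <- toupper(seq)
  100 * nchar(gsub("[^GC]", "", s)) / nchar(s)
}

# enumerate feasible primers whose 5' starts (left) / 3' starts lie in
# positions `starts` of the probe; returns probe-relative coordinates
enumerate_primers <- function(res, starts, cons) {
  run_re <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                    cons$max_run + 1L, cons$max_run + 1L,
                    cons$max_run + 1L, cons$max_run + 1L)
  L <- nchar(res)
  out <- list()
  for (s in starts) {
    for (len in cons$min_len:cons$max_len) {
      e <- s + len - 1L
      if (e > L) break
      p <- substr(res, s, e)
      pu <- toupper(p)
      if (grepl("[^ACGT]", pu)) next
      if (grepl(run_re, pu)) next
      g <- gc_pct(pu)
      if (g < cons$gc_min || g > cons$gc_max) next
      tm <- primer_tm(pu, cons$na_mM, cons$conc_nM)
      if (tm < cons$tm_min || tm > cons$tm_max) next
      out[[length(out) + 1L]] <- data.frame(start = s, end = e, len = len,
                                            seq = pu, gc = g, tm = tm,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Pick a PCR primer pair to recover a probe from genomic DNA
#'
#' Both primers lie within the probe so that the amplicon is the probe
#' itself: the left primer is a prefix-region substring of the probe, the
#' right primer the reverse complement of a suffix-region substring. Each
#' primer must satisfy the length, GC, melting-temperature and
#' single-base-run constraints, and its 3'-terminal base must not fall on a
#' soft-masked (lowercase) position. The product must cover at least
#' `min_product_frac` of the probe. Among feasible pairs, the pair with the
#' smallest Tm difference is chosen, ties broken by the longest product.
#'
#' @param probe `masked_seq` or character string (case carries the
#'   soft-mask).
#' @param probe_start 1-based genomic coordinate of the probe's first base
#'   (for lifting primer coordinates to the genome).
#' @param constraints A [primer_constraints()].
#' @return A `primer_pair` list (`left_seq`, `right_seq`, `left_start`,
#'   `left_end`, `right_start`, `right_end` genomic 1-based inclusive,
#'   `product_length`, `left_tm`, `right_tm`, `gc_left`, `gc_right`), or
#'   `NULL` when no feasible pair exists.
#' @export
pick_primers <- function(probe, probe_start = 1L,
                         constraints = primer_constraints()) {
  res <- if (inherits(probe, "masked_seq")) probe$residues else probe
  L <- nchar(res)
  if (L < 100L) stop("probe too short for primer design (< 100 bp)",
                     call. = FALSE)
  cons <- constraints
  min_prod <- as.integer(ceiling(cons$min_product_frac * L))
  # left primers start within the prefix that still allows the product
  lefts <- enumerate_primers(res, seq_len(L - min_prod + 1L), cons)
  if (!is.null(lefts)) {
    # 3' end of the left primer must be unmasked
    keep <- !substr_is_lower(res, lefts$end)
    lefts <- lefts[keep, , drop = FALSE]
  }
  if (is.null(lefts) || nrow(lefts) == 0L) return(NULL)
  # right primers: substrings ending in the suffix region; primer is the
  # reverse complement, its 3' end is the substring's first base
  right_sub <- enumerate_primers(res, seq.int(min_prod - cons$max_len + 1L,
                                              L - cons$min_len + 1L), cons)
  if (!is.null(right_sub)) {
    right_sub <- right_sub[right_sub$end >= min_prod &
                             !substr_is_lower(res, right_sub$start), ,
                           drop = FALSE]
  }
  if (is.null(right_sub) || nrow(right_sub) == 0L) return(NULL)

  best <- NULL
  for (i in seq_len(nrow(lefts))) {
    prod <- right_sub$end - lefts$start[i] + 1L
    dtm <- abs(right_sub$tm - lefts$tm[i])
    ok <- prod >= min_prod & dtm <= cons$max_tm_diff
    if (!any(ok)) next
    cand <- data.frame(li = i, ri = which(ok), dtm = dtm[ok],
                       prod = prod[ok])
    if (is.null(best)) best <- cand else best <- rbind(best, cand)
  }
  if (is.null(best)) return(NULL)
  best <- best[order(best$dtm, -best$prod, lefts$start[best$li]), ,
               drop = FALSE]
  lf <- lefts[best$li[1L], ]
  rt <- right_sub[best$ri[1L], ]
  structure(list(
    left_seq = lf$seq,
    right_seq = revcomp(rt$seq),
    left_start = probe_start + lf$start - 1L,
    left_end = probe_start + lf$end - 1L,
    right_start = probe_start + rt$start - 1L,
    right_end = probe_start + rt$end - 1L,
    product_length = rt$end - lf$start + 1L,
    left_tm = lf$tm, right_tm = rt$tm,
    gc_left = lf$gc, gc_right = rt$gc), class = "primer_pair")
}

substr_is_lower <- function(res, pos) {
  ch <- substring(res, pos, pos)
  ch != toupper(ch)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> product %d bp\n", x$product_length))
  cat(sprintf("  left  %s  %d-%d  Tm %.1f  GC %.1f%%\n", x$left_seq,
              x$left_start, x$left_end, x$left_tm, x$gc_left))
  cat(sprintf("  right %s  %d-%d  Tm %.1f  GC %.1f%%\n", x$right_seq,
              x$right_start, x$right_end, x$right_tm, x$gc_right))
  invisible(x)
}

#' Import a primer pair from a boulder-IO record
#'
#' Reads the `KEY=value` records emitted by the standard primer-design tool
#' (records terminated by a lone `=`). Positions are probe-relative and
#' 0-based: `PRIMER_LEFT_0=pos,len` gives the leftmost base of the left
#' primer, `PRIMER_RIGHT_0=pos,len` the rightmost base of the right primer
#' (its 5' end on the plus strand). Probe-relative position 0 maps to
#' `probe_start`.
#'
#' @param path Report file path.
#' @param probe_start 1-based genomic coordinate of the probe's first base.
#' @return A `primer_pair`, or `NULL` when the record reports no primers.
#' @export
import_external_primers <- function(path, probe_start = 1L) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || ln == "=") next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) stop("malformed boulder-IO line: '", ln, "'", call. = FALSE)
    kv[[substr(ln, 1L, eq - 1L)]] <- substr(ln, eq + 1L, nchar(ln))
  }
  nret <- kv[["PRIMER_PAIR_NUM_RETURNED"]]
  if (!is.null(nret) && as.integer(nret) == 0L) return(NULL)
  need <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) stop("boulder-IO record missing key ", key,
                         call. = FALSE)
    v
  }
  poslen <- function(key) {
    v <- strsplit(need(key), ",", fixed = TRUE)[[1L]]
    pl <- suppressWarnings(as.integer(v))
    if (length(pl) != 2L || anyNA(pl)) {
      stop("malformed position in key ", key, call. = FALSE)
    }
    pl
  }
  lp <- poslen("PRIMER_LEFT_0")
  rp <- poslen("PRIMER_RIGHT_0")
  left_start <- probe_start + lp[1L]
  right_end <- probe_start + rp[1L]
  numor <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  structure(list(
    left_seq = toupper(need("PRIMER_LEFT_0_SEQUENCE")),
    right_seq = toupper(need("PRIMER_RIGHT_0_SEQUENCE")),
    left_start = left_start,
    left_end = left_start + lp[2L] - 1L,
    right_start = right_end - rp[2L] + 1L,
    right_end = right_end,
    product_length = right_end - left_start + 1L,
    left_tm = numor("PRIMER_LEFT_0_TM"),
    right_tm = numor("PRIMER_RIGHT_0_TM"),
    gc_left = numor("PRIMER_LEFT_0_GC_PERCENT"),
    gc_right = numor("PRIMER_RIGHT_0_GC_PERCENT")), class = "primer_pair")
}

#' Write primer pairs as TSV
#'
#' @param primers Named list of `primer_pair` (or `NULL` entries for probes
#'   with no feasible pair).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
primers_to_tsv <- function(primers, path) {
  rows <- lapply(names(primers), function(nm) {
    p <- primers[[nm]]
    if (is.null(p)) {
      return(data.frame(probe = nm, left_seq = "no primers",
                        right_seq = "", left_start = NA, right_end = NA,
                        product_length = NA, left_tm = NA, right_tm = NA,
                        gc_left = NA, gc_right = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(probe = nm, left_seq = p$left_seq, right_seq = p$right_seq,
               left_start = p$left_start, right_end = p$right_end,
               product_length = p$product_length,
               left_tm = round(p$left_tm, 1), right_tm = round(p$right_tm, 1),
               gc_left = round(p$gc_left, 1), gc_right = round(p$gc_right, 1),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
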