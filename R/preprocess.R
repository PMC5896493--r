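# Read pre-processing: pair merging, primer trimming with orientation
# normalisation, expected-error filtering, exact-length filtering and
# depth-equalising subsampling.
#
# Every stage returns the kept reads with a `stage_stats` attribute so that
# kept + rejected always reconciles with the input.

# ---- pair merging -----------------------------------------------------------

merge_one_pair <- function(fs, fq, rs, rq, min_overlap, max_mismatch_frac, offset) {
  rcs <- revcomp(rs)
  rcq <- stringi::stri_reverse(rq)
  f <- strsplit(fs, "", fixed = TRUE)[[1]]
  r <- strsplit(rcs, "", fixed = TRUE)[[1]]
  qf <- utf8ToInt(fq) - offset
  qr <- utf8ToInt(rcq) - offset
  lf <- length(f); lr <- length(r)
  omax <- min(lf, lr)
  if (min_overlap > omax) return(NULL)
  best_o <- NA_integer_; best_score <- -Inf; best_matches <- 0L
  for (o in seq(min_overlap, omax)) {
    fi <- (lf - o + 1L):lf
    matches <- sum(f[fi] == r[1:o])
    score <- 2L * matches - o   # matches - mismatches
    if (score >= best_score) {  # ties -> larger overlap
      best_score <- score; best_o <- o; best_matches <- matches
    }
  }
  o <- best_o
  if ((o - best_matches) / o > max_mismatch_frac) return(NULL)
  fi <- (lf - o + 1L):lf
  fo <- f[fi]; ro <- r[1:o]
  qfo <- qf[fi]; qro <- qr[1:o]
  agree <- fo == ro
  cons <- ifelse(qfo >= qro, fo, ro)
  cons[agree] <- fo[agree]
  qcons <- ifelse(agree, pmax(qfo, qro), abs(qfo - qro))
  seq_out <- paste0(
    if (lf > o) paste(f[1:(lf - o)], collapse = "") else "",
    paste(cons, collapse = ""),
    if (lr > o) paste(r[(o + 1L):lr], collapse = "") else ""
  )
  qual_out <- paste0(
    if (lf > o) intToUtf8(qf[1:(lf - o)] + offset) else "",
    intToUtf8(qcons + offset),
    if (lr > o) intToUtf8(qr[(o + 1L):lr] + offset) else ""
  )
  list(seq = seq_out, qual = qual_out)
}

#' Merge paired-end reads by ungapped overlap
#'
#' The reverse read is reverse-complemented and the best ungapped overlap of at
#' least `min_overlap` bases is chosen by maximum matches-minus-mismatches
#' score (ties go to the longer overlap). In the overlap, agreeing bases keep
#' the higher Phred score; disagreeing positions take the higher-Phred base
#' with quality `|Q1 - Q2|`. Pairs whose best overlap exceeds
#' `max_mismatch_frac` mismatches are rejected.
#'
#' @param fwd,rev Row-matched tibbles of forward and reverse reads.
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the overlap.
#' @param phred_offset ASCII offset of the quality strings.
#' @return Tibble of merged reads (ids from `fwd`), with rejection accounted in
#'   [stage_stats()].
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 16, max_mismatch_frac = 0.25,
                        phred_offset = 33) {
  assert_reads(fwd, "fwd"); assert_reads(rev, "rev")
  stopifnot(nrow(fwd) == nrow(rev))
  merged <- vector("list", nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    merged[[i]] <- merge_one_pair(fwd$seq[i], fwd$qual[i], rev$seq[i], rev$qual[i],
                                  min_overlap, max_mismatch_frac, phred_offset)
  }
  keep <- !vapply(merged, is.null, logical(1))
  out <- tibble::tibble(
    id = fwd$id[keep],
    seq = vapply(merged[keep], `[[`, character(1), "seq"),
    qual = vapply(merged[keep], `[[`, character(1), "qual")
  )
  attr(out, "phred_offset") <- attr(fwd, "phred_offset") %||% as.integer(phred_offset)
  with_stage_stats(out, "merge_pairs", nrow(fwd), nrow(out))
}

# ---- primer trimming --------------------------------------------------------

# Vectorised IUPAC-aware mismatch count of `primer` against a fixed-offset
# window of each sequence. `at_end` anchors the window at the 3' end.
iupac_mismatches <- function(seqs, primer, at_end = FALSE) {
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  if (!all(p %in% names(IUPAC_SETS))) abort("primer contains non-IUPAC characters")
  plen <- length(p)
  lens <- nchar(seqs)
  mm <- integer(length(seqs))
  for (j in seq_len(plen)) {
    pos <- if (at_end) lens - plen + j else rep.int(j, length(seqs))
    ch <- substring(seqs, pos, pos)
    allowed <- IUPAC_SETS[[p[j]]]
    if (p[j] == "N") allowed <- c(allowed, "N")
    mm <- mm + !(ch %in% allowed)
  }
  mm[lens < plen] <- plen
  mm
}

#' Trim primers and normalise read orientation
#'
#' Reads carrying the forward primer at the 5' end and the reverse complement
#' of the reverse primer at the 3' end (each within `max_mismatch` IUPAC-aware
#' mismatches, anchored at the read ends) are trimmed to the insert. Reads in
#' reverse orientation are reverse-complemented first (qualities reversed) and
#' then trimmed, so all output reads face forward. Reads matching neither
#' orientation are rejected.
#'
#' @param reads Tibble of merged reads.
#' @param fwd_primer,rev_primer Primer sequences (IUPAC alphabet), both given
#'   in their own 5'->3' orientation.
#' @param max_mismatch Maximum mismatches per primer; default
#'   `ceiling(0.1 * nchar(primer))`.
#' @return Tibble of trimmed, forward-oriented inserts; orientation counts in
#'   `attr(, "orientation")`, rejections in [stage_stats()].
#' @export
trim_and_orient <- function(reads, fwd_primer, rev_primer, max_mismatch = NULL) {
  assert_reads(reads)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  plen_f <- nchar(fwd_primer); plen_r <- nchar(rev_primer)
  mm_f <- if (is.null(max_mismatch)) ceiling(0.1 * plen_f) else max_mismatch
  mm_r <- if (is.null(max_mismatch)) ceiling(0.1 * plen_r) else max_mismatch
  rc_rev <- revcomp(rev_primer)

  n <- nrow(reads)
  if (n == 0L) {
    return(with_stage_stats(reads, "trim_and_orient", 0L, 0L))
  }
  seqs <- reads$seq
  long_enough <- nchar(seqs) > plen_f + plen_r
  fwd_ok <- long_enough &
    iupac_mismatches(seqs, fwd_primer) <= mm_f &
    iupac_mismatches(seqs, rc_rev, at_end = TRUE) <= mm_r

  # remaining reads: try the reverse orientation
  rev_ok <- logical(n)
  todo <- which(!fwd_ok & long_enough)
  if (length(todo)) {
    rc <- revcomp(seqs[todo])
    ok <- iupac_mismatches(rc, fwd_primer) <= mm_f &
      iupac_mismatches(rc, rc_rev, at_end = TRUE) <= mm_r
    rev_ok[todo[ok]] <- TRUE
    seqs[todo[ok]] <- rc[ok]
  }
  keep <- fwd_ok | rev_ok
  qual <- reads$qual
  qual[rev_ok] <- stringi::stri_reverse(qual[rev_ok])
  lens <- nchar(seqs)
  out <- tibble::tibble(
    id = reads$id[keep],
    seq = substring(seqs[keep], plen_f + 1L, lens[keep] - plen_r),
    qual = substring(qual[keep], plen_f + 1L, lens[keep] - plen_r)
  )
  attr(out, "phred_offset") <- attr(reads, "phred_offset")
  attr(out, "orientation") <- c(forward = sum(fwd_ok), reverse = sum(rev_ok))
  with_stage_stats(out, "trim_and_orient", n, nrow(out))
}

# ---- quality / length filters ----------------------------------------------

#' Expected number of sequencing errors per read
#'
#' Sums the per-base error probabilities decoded from the Phred scores,
#' `ee = sum_i 10^(-Q_i / 10)`; an empty read has expected error 0.
#'
#' @param reads Tibble of reads, or a character vector of quality strings.
#' @param phred_offset ASCII offset (taken from the reads attribute if present).
#' @return Numeric vector of expected errors.
#' @export
expected_error <- function(reads, phred_offset = NULL) {
  if (is.data.frame(reads)) {
    off <- phred_offset %||% attr(reads, "phred_offset") %||% 33L
    phred_expected_error(reads$qual, off)
  } else {
    phred_expected_error(reads, phred_offset %||% 33L)
  }
}

#' Filter reads on maximum expected error
#'
#' Keeps reads whose expected error is at most `max_ee` (inclusive boundary).
#'
#' @param reads Tibble of reads.
#' @param max_ee Expected-error ceiling; 0.5 is the usual strict setting.
#' @param phred_offset ASCII offset override.
#' @return Tibble of kept reads with [stage_stats()] attached.
#' @export
filter_ee <- function(reads, max_ee = 0.5, phred_offset = NULL) {
  assert_reads(reads)
  stopifnot(max_ee >= 0)
  # small epsilon so the inclusive boundary survives floating-point summation
  keep <- expected_error(reads, phred_offset) <= max_ee + 1e-9
  out <- reads[keep, , drop = FALSE]
  attr(out, "phred_offset") <- attr(reads, "phred_offset")
  with_stage_stats(out, "filter_ee", nrow(reads), nrow(out))
}

#' Keep only reads of the exact target amplicon length
#'
#' @param reads Tibble of trimmed reads.
#' @param target_len Expected insert length in bp.
#' @return Tibble of kept reads with [stage_stats()] attached.
#' @export
filter_exact_length <- function(reads, target_len) {
  assert_reads(reads)
  stopifnot(target_len > 0)
  keep <- nchar(reads$seq) == target_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "phred_offset") <- attr(reads, "phred_offset")
  with_stage_stats(out, "filter_exact_length", nrow(reads), nrow(out))
}

#' Subsample reads to a fixed depth
#'
#' Uniform sampling without replacement, reproducible under `seed`; the
#' original read order is preserved among the sampled reads. Asking for more
#' reads than are available is an error, because the point of the step is to
#' equalise depth across samples.
#'
#' @param reads Tibble of reads.
#' @param n Target number of reads.
#' @param seed Integer seed.
#' @return Tibble of `n` reads with [stage_stats()] attached.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  assert_reads(reads)
  stopifnot(n >= 1)
  if (n > nrow(reads)) {
    abort(sprintf(paste0(
      "cannot subsample %d reads from %d available; ",
      "lower the target depth so all samples can be equalised"), n, nrow(reads)))
  }
  idx <- withr::with_seed(seed, sort(sample.int(nrow(reads), n)))
  out <- reads[idx, , drop = FALSE]
  attr(out, "phred_offset") <- attr(reads, "phred_offset")
  with_stage_stats(out, "subsample", nrow(reads), n)
}
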