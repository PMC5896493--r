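# Sequence utilities shared across the pipeline stages.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate base -> set of concrete bases it matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the full IUPAC alphabet (case preserved).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGWACWGG"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
    x
  ))
}

is_dna <- function(x, alphabet = c(DNA_BASES, "N")) {
  !grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
}

#' Decode Phred quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @param offset ASCII offset, 33 (default) or 64.
#' @return List of integer vectors, one per read.
#' @export
phred_scores <- function(qual, offset = 33) {
  stopifnot(offset %in% c(33L, 64L))
  lapply(qual, function(q) {
    if (!nzchar(q)) return(integer(0))
    utf8ToInt(q) - offset
  })
}

phred_encode <- function(scores, offset = 33) {
  vapply(scores, function(s) {
    if (!length(s)) return("")
    intToUtf8(s + offset)
  }, character(1))
}

# Sum of per-base error probabilities for each quality string, computed in
# chunks so the intermediate numeric vectors stay small.
phred_expected_error <- function(qual, offset = 33) {
  n <- length(qual)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 20000L))
  for (ii in chunks) {
    lens <- nchar(qual[ii])
    tot <- sum(lens)
    if (tot == 0L) next
    q <- utf8ToInt(paste(qual[ii], collapse = "")) - offset
    if (any(q < 0L)) abort("negative Phred score: wrong ASCII offset?")
    p <- 10^(-q / 10)
    grp <- rep.int(seq_along(ii), lens)
    sums <- rowsum(p, grp)
    out[ii][as.integer(rownames(sums))] <- as.numeric(sums)
  }
  out
}

#' Unit-cost edit distance between sequences
#'
#' Levenshtein distance (substitutions + single-base indels, all cost 1),
#' computed in C via [utils::adist()].
#'
#' @param a,b Character vectors of sequences.
#' @return Integer matrix `length(a)` x `length(b)` of distances.
#' @export
edit_distance <- function(a, b = a) {
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

# Stage accounting attached to every filtering step's result so that read
# conservation (kept + rejected == input) can be audited across the pipeline.
with_stage_stats <- function(x, stage, input, kept) {
  attr(x, "stage_stats") <- tibble::tibble(
    stage = stage, input = as.integer(input),
    kept = as.integer(kept), rejected = as.integer(input - kept)
  )
  x
}

#' Retrieve per-stage read accounting
#'
#' @param x A result returned by a pipeline stage.
#' @return A tibble with columns `stage`, `input`, `kept`, `rejected`.
#' @export
stage_stats <- function(x) attr(x, "stage_stats")

assert_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) || !all(c("id", "seq", "qual") %in% names(reads))) {
    abort(sprintf("`%s` must be a tibble with columns id, seq, qual", arg))
  }
  invisible(reads)
}
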