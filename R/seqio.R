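# Sequence I/O: FASTQ, size-annotated FASTA, dereplication, sample manifests.
#
# Reads are plain tibbles (id, seq, qual) with the Phred offset stored as an
# attribute; dereplicated uniques are long tibbles (seq, sample_id, count) so
# per-sample provenance travels with the sequence rather than in headers.

#' Read a FASTQ file
#'
#' Parses a (optionally gzipped) 4-line-per-record FASTQ file into a tibble.
#' Sequences are uppercased; only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param phred_offset ASCII offset for quality decoding, 33 (default) or 64.
#' @return A tibble with columns `id`, `seq`, `qual` (quality kept as the raw
#'   string; decode with [phred_scores()]), in file order, with the offset in
#'   `attr(, "phred_offset")`.
#' @export
read_fastq <- function(path, phred_offset = 33) {
  stopifnot(file.exists(path), phred_offset %in% c(33L, 64L))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    out <- tibble::tibble(id = character(), seq = character(), qual = character())
    attr(out, "phred_offset") <- as.integer(phred_offset)
    return(out)
  }
  if (n %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record starting at line %d of %s",
                  (n %/% 4L) * 4L + 1L, path))
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- toupper(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ header at line %d: expected '@'", (bad[1] - 1L) * 4L + 1L))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ separator at line %d: expected '+'", (bad[1] - 1L) * 4L + 3L))
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("quality/sequence length mismatch in record at line %d", (bad[1] - 1L) * 4L + 1L))
  }
  bad <- which(!is_dna(seqs))
  if (length(bad)) {
    abort(sprintf("non-ACGTN character in sequence at line %d", (bad[1] - 1L) * 4L + 2L))
  }
  id <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", id)
  out <- tibble::tibble(id = id, seq = seqs, qual = qual)
  attr(out, "phred_offset") <- as.integer(phred_offset)
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_reads(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    rec <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Dereplicate reads into unique sequences
#'
#' Groups reads by exact sequence identity and attributes the counts to one
#' sample, the unit the downstream per-sample abundance prefilter operates on.
#'
#' @param reads Tibble of reads (or any data frame with a `seq` column).
#' @param sample_id Sample the reads belong to.
#' @return Long tibble with columns `seq`, `sample_id`, `count`; the sum of
#'   `count` equals `nrow(reads)`.
#' @export
dereplicate <- function(reads, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!nrow(reads)) {
    return(tibble::tibble(seq = character(), sample_id = character(), count = integer()))
  }
  reads |>
    dplyr::count(.data$seq, name = "count") |>
    dplyr::mutate(sample_id = sample_id, .after = "seq") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
}

# Totals per sequence across samples, in the canonical output order
# (total descending, then sequence lexicographic).
unique_totals <- function(uniques) {
  uniques |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$seq)
}

#' Write unique sequences as size-annotated FASTA
#'
#' Headers carry the usual dereplication dialect `;size=N`; records are sorted
#' by total abundance descending with ties broken lexicographically.
#'
#' @param uniques Long tibble (`seq`, `sample_id`, `count`) or a tibble with
#'   `seq` and `total` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sized <- function(uniques, path) {
  tot <- if ("total" %in% names(uniques)) {
    uniques |> dplyr::arrange(dplyr::desc(.data$total), .data$seq)
  } else {
    unique_totals(uniques)
  }
  con <- file(path, "wt")
  on.exit(close(con))
  if (nrow(tot)) {
    hdr <- sprintf(">u%d;size=%d", seq_len(nrow(tot)), as.integer(tot$total))
    writeLines(paste0(hdr, "\n", tot$seq), con)
  }
  invisible(path)
}

#' Read a size-annotated FASTA file
#'
#' @param path Path to a FASTA file whose headers may carry `;size=N`
#'   annotations (missing annotations count as size 1).
#' @return Tibble with columns `id`, `seq`, `total`.
#' @export
read_fasta_sized <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(id = character(), seq = character(), total = integer()))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  if (!length(hdr_idx) || hdr_idx[1] != 1L) abort("not a FASTA file: missing '>' header")
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  hdr <- sub("^>", "", lines[hdr_idx])
  size <- suppressWarnings(as.integer(sub("^.*;size=(\\d+);?.*$", "\\1", hdr)))
  size[is.na(size)] <- 1L
  id <- sub(";.*$", "", sub("\\s.*$", "", hdr))
  tibble::tibble(id = id, seq = toupper(seqs), total = size)
}

#' Read a sample manifest
#'
#' Tab-delimited text with columns `sample_id`, `replicate_id`, `path` and an
#' optional `path2` (reverse reads). `(sample_id, replicate_id)` pairs must be
#' unique.
#'
#' @param path Path to the manifest file.
#' @return Tibble with one row per sample file set.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "replicate_id", "path")
  if (!all(need %in% names(m))) {
    abort(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  }
  key <- paste(m$sample_id, m$replicate_id, sep = "\r")
  if (anyDuplicated(key)) abort("duplicate (sample_id, replicate_id) pair in manifest")
  tibble::as_tibble(m)
}
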