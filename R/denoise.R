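# Abundance-skew denoising: per-sample prefilter, pooling, greedy centroid
# denoising governed by alpha, and de novo chimera flagging.
#
# This is the heart of the haplotyping approach: sequencing-error variants sit
# at small edit distances from their true parent and at strongly skewed
# abundance ratios, so a candidate u is absorbed into a centroid c whenever
# size_u / size_c <= beta(d) with beta(d) = 1 / 2^(alpha * d + 1).

#' Per-sample abundance prefilter
#'
#' Within each sample, a unique sequence is kept only if its count reaches both
#' the absolute floor (`>= min_abs` copies) and the relative floor
#' (`count / sample_total >= min_rel`); cells failing either condition are
#' zeroed and sequences with no remaining counts are dropped. This mirrors the
#' usual "discard below 10 reads or 0.001% per sample" rule (both boundaries
#' inclusive on the keep side).
#'
#' @param uniques Long tibble (`seq`, `sample_id`, `count`).
#' @param sample_totals Named numeric vector or tibble (`sample_id`, `total`)
#'   of per-sample read counts entering dereplication.
#' @param min_abs Minimum copies per sample (default 10).
#' @param min_rel Minimum relative abundance per sample as a fraction
#'   (default `1e-5`, i.e. 0.001%).
#' @return Filtered long tibble; reads removed are accounted in
#'   [stage_stats()].
#' @export
prefilter <- function(uniques, sample_totals, min_abs = 10, min_rel = 1e-5) {
  stopifnot(min_abs >= 1, min_rel >= 0, min_rel < 1)
  totals <- as_sample_totals(sample_totals)
  unknown <- setdiff(unique(uniques$sample_id), totals$sample_id)
  if (length(unknown)) {
    abort(sprintf("unknown sample id(s) in counts: %s", paste(unknown, collapse = ", ")))
  }
  reads_in <- sum(uniques$count)
  out <- uniques |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::filter(.data$count >= min_abs, .data$count / .data$total >= min_rel) |>
    dplyr::select(-"total")
  with_stage_stats(out, "prefilter", reads_in, sum(out$count))
}

as_sample_totals <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample_id", "total") %in% names(x)))
    tibble::as_tibble(x[c("sample_id", "total")])
  } else {
    tibble::tibble(sample_id = names(x), total = as.numeric(x))
  }
}

#' Pool per-sample uniques across samples
#'
#' Merges identical sequences across samples; per-sample counts are retained
#' in long form and totals are conserved.
#'
#' @param ... Long unique tibbles (or a single list of them).
#' @return Pooled long tibble (`seq`, `sample_id`, `count`).
#' @export
pool_uniques <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  dplyr::bind_rows(parts) |>
    dplyr::group_by(.data$seq, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Abundance-skew threshold beta(d)
#'
#' `beta(d) = 1 / 2^(alpha * d + 1)`: the maximum abundance ratio at which a
#' sequence at edit distance `d` from a centroid is still considered a
#' sequencing-error variant of it. Strictly decreasing in both `d` and
#' `alpha`; a lower alpha therefore merges more variants (stricter denoising).
#'
#' @param d Edit distance(s), integer `>= 1` (identical sequences are merged by
#'   dereplication, never by skew).
#' @param alpha Skew strictness parameter, `> 0`.
#' @return Numeric vector of thresholds.
#' @export
skew_threshold <- function(d, alpha) {
  stopifnot(alpha > 0)
  if (any(d < 1)) abort("skew threshold is only defined for d >= 1")
  1 / 2^(alpha * d + 1)
}

#' Greedy abundance-skew denoising of pooled uniques
#'
#' Uniques are processed by total abundance descending (ties lexicographic by
#' sequence). The first unique founds a centroid; each subsequent unique is
#' absorbed as noise of the qualifying centroid (`size_u / size_c <= beta(d)`,
#' `d` = unit-cost edit distance, `size_c` = the centroid's own dereplicated
#' total) with the smallest `d` — ties broken by larger centroid size, then
#' lexicographic centroid sequence — or founds a new centroid if none
#' qualifies. Absorbed uniques contribute their per-sample counts to the
#' centroid.
#'
#' @param pooled Pooled long tibble (`seq`, `sample_id`, `count`).
#' @param alpha Skew strictness (default 5, the usual final-analysis value).
#' @return An object of class `haplo_denoise`: a list with tibbles
#'   `centroids` (`haplotype_id`, `seq`, `total`, `own_total`, `chimera`),
#'   `counts` (`haplotype_id`, `sample_id`, `count`) and `members`
#'   (`haplotype_id`, `member_seq`, `size`, `dist`), plus the parameters used.
#' @export
denoise <- function(pooled, alpha = 5) {
  stopifnot(alpha > 0)
  if (!nrow(pooled)) abort("denoise: empty input")
  tot <- unique_totals(pooled)   # total desc, seq asc
  n <- nrow(tot)
  seqs <- tot$seq
  sizes <- tot$total
  beta1 <- skew_threshold(1L, alpha)
  cent_idx <- integer(0)         # indices into tot that founded centroids
  assign_to <- integer(n)        # 0 = centroid itself
  dist_to <- integer(n)
  for (i in seq_len(n)) {
    chosen <- 0L
    if (length(cent_idx)) {
      # a centroid can only qualify at some d >= 1 if it qualifies at d = 1
      cand <- cent_idx[sizes[i] / sizes[cent_idx] <= beta1]
      if (length(cand)) {
        d <- as.integer(utils::adist(seqs[i], seqs[cand]))
        ok <- d >= 1L & sizes[i] / sizes[cand] <= skew_threshold(pmax(d, 1L), alpha)
        if (any(ok)) {
          cand <- cand[ok]; d <- d[ok]
          ord <- order(d, -sizes[cand], seqs[cand])
          chosen <- cand[ord[1]]
          dist_to[i] <- d[ord[1]]
        }
      }
    }
    if (chosen == 0L) {
      cent_idx <- c(cent_idx, i)
    } else {
      assign_to[i] <- chosen
    }
  }

  hap_id <- sprintf("hap_%04d", seq_along(cent_idx))
  names(hap_id) <- as.character(cent_idx)
  owner <- ifelse(assign_to == 0L, seq_len(n), assign_to)
  map <- tibble::tibble(seq = seqs, haplotype_id = hap_id[as.character(owner)])
  counts <- pooled |>
    dplyr::inner_join(map, by = "seq") |>
    dplyr::group_by(.data$haplotype_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  centroids <- tibble::tibble(
    haplotype_id = hap_id,
    seq = seqs[cent_idx],
    own_total = sizes[cent_idx]
  ) |>
    dplyr::left_join(
      counts |> dplyr::group_by(.data$haplotype_id) |>
        dplyr::summarise(total = sum(.data$count), .groups = "drop"),
      by = "haplotype_id"
    ) |>
    dplyr::mutate(chimera = FALSE) |>
    dplyr::select("haplotype_id", "seq", "total", "own_total", "chimera")
  absorbed <- which(assign_to > 0L)
  members <- tibble::tibble(
    haplotype_id = hap_id[as.character(assign_to[absorbed])],
    member_seq = seqs[absorbed],
    size = sizes[absorbed],
    dist = dist_to[absorbed]
  )
  structure(
    list(centroids = centroids, counts = counts, members = members,
         params = list(alpha = alpha)),
    class = "haplo_denoise"
  )
}

#' @export
print.haplo_denoise <- function(x, ...) {
  cat(sprintf("<haplo_denoise> %d centroids (%d flagged chimeric), %d absorbed variants, alpha = %g\n",
              nrow(x$centroids), sum(x$centroids$chimera), nrow(x$members), x$params$alpha))
  invisible(x)
}

#' @export
tidy.haplo_denoise <- function(x, ...) x$centroids

#' @export
glance.haplo_denoise <- function(x, ...) {
  tibble::tibble(
    n_centroids = nrow(x$centroids),
    n_chimeric = sum(x$centroids$chimera),
    n_absorbed = nrow(x$members),
    reads_total = sum(x$counts$count),
    alpha = x$params$alpha
  )
}

# longest common prefix / suffix length between two equal-split char vectors
lcp_len <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  neq <- which(a[1:m] != b[1:m])
  if (!length(neq)) m else neq[1] - 1L
}

#' Flag exact two-parent chimeras among denoised centroids
#'
#' A centroid `x` is flagged as chimeric if two distinct, more abundant
#' centroids `a` and `b` (each with at least twice `x`'s total) and a crossover
#' position `k` exist such that `x` equals `a[1..k] + b[k+1..end]` exactly.
#' Only same-length parent pairs are considered. Flagged centroids are
#' excluded from downstream tables; their reads are reported in the result's
#' stage statistics.
#'
#' @param dn A `haplo_denoise` object.
#' @return The same object with the `chimera` flags updated.
#' @export
flag_chimeras <- function(dn) {
  stopifnot(inherits(dn, "haplo_denoise"))
  cents <- dn$centroids
  nC <- nrow(cents)
  if (nC < 3L) return(dn)
  chars <- strsplit(cents$seq, "", fixed = TRUE)
  lens <- nchar(cents$seq)
  rchars <- lapply(chars, rev)
  flag <- cents$chimera
  for (i in seq_len(nC)) {
    parents <- which(cents$total >= 2 * cents$total[i] & lens == lens[i] &
                       seq_len(nC) != i)
    if (length(parents) < 2L) next
    len <- lens[i]
    pre <- vapply(parents, function(p) lcp_len(chars[[i]], chars[[p]]), integer(1))
    suf <- vapply(parents, function(p) lcp_len(rchars[[i]], rchars[[p]]), integer(1))
    # need a != b with k in [1, len-1], k <= pre[a], len - k <= suf[b]
    found <- FALSE
    for (ai in seq_along(parents)) {
      if (pre[ai] < 1L) next
      others <- setdiff(seq_along(parents), ai)
      if (!length(others)) next
      max_suf <- max(suf[others])
      kmax <- min(pre[ai], len - 1L)
      if (kmax >= 1L && len - kmax <= max_suf) { found <- TRUE; break }
    }
    flag[i] <- found
  }
  dn$centroids$chimera <- flag
  dn
}
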