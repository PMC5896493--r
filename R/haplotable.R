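# OTU clustering of denoised haplotypes and the multi-threshold
# haplotype-table filter (minhaplosize / OTUmin / withinOTU / presence).

#' Greedy centroid clustering of haplotypes into OTUs
#'
#' Haplotypes are processed by total abundance descending (ties lexicographic
#' by sequence); each joins the first existing OTU whose centroid identity
#' reaches the threshold, else founds a new OTU. Identity between two
#' sequences is `1 - editdist / max(len_a, len_b)`. Chimera-flagged centroids
#' are excluded.
#'
#' @param x A `haplo_denoise` object, or a tibble with columns
#'   `haplotype_id`, `seq`, `total`.
#' @param identity Identity threshold in `(0, 1]` (default 0.97, the usual
#'   species-proxy radius for COI).
#' @return Tibble (`otu_id`, `haplotype_id`, `seq`, `total`, `is_centroid`).
#' @export
cluster_otus <- function(x, identity = 0.97) {
  stopifnot(identity > 0, identity <= 1)
  haps <- if (inherits(x, "haplo_denoise")) {
    x$centroids |> dplyr::filter(!.data$chimera)
  } else {
    tibble::as_tibble(x)
  }
  stopifnot(all(c("haplotype_id", "seq", "total") %in% names(haps)))
  haps <- haps |> dplyr::arrange(dplyr::desc(.data$total), .data$seq)
  n <- nrow(haps)
  otu_of <- integer(n)
  cent <- integer(0)   # row index of each OTU's centroid, in founding order
  for (i in seq_len(n)) {
    joined <- 0L
    if (length(cent)) {
      d <- as.integer(utils::adist(haps$seq[i], haps$seq[cent]))
      idn <- 1 - d / pmax(nchar(haps$seq[i]), nchar(haps$seq[cent]))
      hit <- which(idn >= identity)
      if (length(hit)) joined <- hit[1]   # first OTU in founding order
    }
    if (joined == 0L) {
      cent <- c(cent, i)
      otu_of[i] <- length(cent)
    } else {
      otu_of[i] <- joined
    }
  }
  haps |>
    dplyr::mutate(
      otu_id = sprintf("otu_%03d", otu_of),
      is_centroid = dplyr::row_number() %in% cent
    ) |>
    dplyr::select("otu_id", "haplotype_id", "seq", "total", "is_centroid") |>
    dplyr::arrange(.data$otu_id, dplyr::desc(.data$total), .data$seq)
}

#' Build the haplotype x sample count table
#'
#' One row per unflagged haplotype, carrying its OTU membership and per-sample
#' counts; OTU counts are column-wise sums over member haplotypes.
#'
#' @param otus OTU membership tibble from [cluster_otus()].
#' @param dn The `haplo_denoise` object the OTUs were built from.
#' @param sample_totals Per-sample read totals entering the table (named
#'   vector or tibble `sample_id`, `total`).
#' @return A `haplo_table` object: list with `counts` (long tibble
#'   `haplotype_id`, `otu_id`, `sample_id`, `count`), `haplotypes`
#'   (`haplotype_id`, `otu_id`, `seq`), `sample_totals`, `params_applied`.
#' @export
build_table <- function(otus, dn, sample_totals) {
  stopifnot(inherits(dn, "haplo_denoise"))
  keep <- dn$centroids |> dplyr::filter(!.data$chimera)
  missing <- setdiff(keep$haplotype_id, otus$haplotype_id)
  if (length(missing)) {
    abort(sprintf("haplotype(s) without OTU assignment: %s", paste(missing, collapse = ", ")))
  }
  membership <- otus |> dplyr::select("haplotype_id", "otu_id", "seq")
  counts <- dn$counts |>
    dplyr::inner_join(membership |> dplyr::select(-"seq"), by = "haplotype_id") |>
    dplyr::filter(.data$count > 0) |>
    dplyr::select("haplotype_id", "otu_id", "sample_id", "count")
  structure(
    list(
      counts = counts,
      haplotypes = membership,
      sample_totals = as_sample_totals(sample_totals),
      params_applied = list()
    ),
    class = "haplo_table"
  )
}

#' @export
print.haplo_table <- function(x, ...) {
  cat(sprintf("<haplo_table> %d haplotypes in %d OTUs x %d samples (%s reads)\n",
              length(unique(x$counts$haplotype_id)),
              length(unique(x$counts$otu_id)),
              nrow(x$sample_totals),
              format(sum(x$counts$count), big.mark = ",")))
  if (length(x$params_applied)) {
    cat("  filters applied:",
        paste(names(x$params_applied), unlist(x$params_applied), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.haplo_table <- function(x, ...) {
  x$counts |> dplyr::left_join(x$haplotypes |> dplyr::select("haplotype_id", "seq"),
                               by = "haplotype_id")
}

#' @export
glance.haplo_table <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = length(unique(x$counts$haplotype_id)),
    n_otus = length(unique(x$counts$otu_id)),
    n_samples = nrow(x$sample_totals),
    reads = sum(x$counts$count)
  )
}

#' Convert a haplotype table to a wide tibble
#'
#' @param x A `haplo_table`.
#' @param ... Unused.
#' @return Wide tibble: one row per haplotype, one column per sample.
#' @export
as_tibble.haplo_table <- function(x, ...) {
  tidy(x) |>
    tidyr::pivot_wider(
      id_cols = c("haplotype_id", "otu_id", "seq"),
      names_from = "sample_id", values_from = "count", values_fill = 0L
    )
}

#' Subset (and optionally rename) the samples of a haplotype table
#'
#' @param table A `haplo_table`.
#' @param sample_ids Samples to keep.
#' @param new_ids Optional replacement names, matched positionally.
#' @return A `haplo_table` restricted to those samples.
#' @export
subset_samples <- function(table, sample_ids, new_ids = NULL) {
  stopifnot(inherits(table, "haplo_table"))
  stopifnot(all(sample_ids %in% table$sample_totals$sample_id))
  ren <- if (is.null(new_ids)) setNames(sample_ids, sample_ids) else setNames(new_ids, sample_ids)
  table$counts <- table$counts |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::mutate(sample_id = unname(ren[.data$sample_id]))
  table$sample_totals <- table$sample_totals |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::mutate(sample_id = unname(ren[.data$sample_id]))
  table
}

# One pass of the fixed-order threshold cascade; returns the filtered counts.
filter_pass <- function(counts, totals, minhaplosize, otumin, within_otu,
                        min_haplo_presence, min_otu_presence) {
  if (!nrow(counts)) return(counts)
  cc <- counts |> dplyr::left_join(totals, by = "sample_id")

  # (1) keep a haplotype only if it reaches minhaplosize% in at least one sample
  keep_h <- cc |>
    dplyr::group_by(.data$haplotype_id) |>
    dplyr::summarise(ok = any(100 * .data$count / .data$total >= minhaplosize),
                     .groups = "drop") |>
    dplyr::filter(.data$ok)
  cc <- cc |> dplyr::semi_join(keep_h, by = "haplotype_id")

  # (2) keep an OTU only if its summed abundance reaches otumin% in >= 1 sample
  keep_o <- cc |>
    dplyr::group_by(.data$otu_id, .data$sample_id, .data$total) |>
    dplyr::summarise(otu_count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(ok = any(100 * .data$otu_count / .data$total >= otumin),
                     .groups = "drop") |>
    dplyr::filter(.data$ok)
  cc <- cc |> dplyr::semi_join(keep_o, by = "otu_id")

  # (3) within each OTU and sample, zero haplotypes below within_otu% of the
  # OTU's (post-step-2) count in that sample; (4) all-zero rows disappear
  cc <- cc |>
    dplyr::group_by(.data$otu_id, .data$sample_id) |>
    dplyr::mutate(otu_count = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(100 * .data$count / .data$otu_count >= within_otu)

  # (5) presence filters on the surviving nonzero cells
  if (min_haplo_presence > 1L) {
    keep_h <- cc |>
      dplyr::group_by(.data$haplotype_id) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$sample_id), .groups = "drop") |>
      dplyr::filter(.data$n >= min_haplo_presence)
    cc <- cc |> dplyr::semi_join(keep_h, by = "haplotype_id")
  }
  if (min_otu_presence > 1L) {
    keep_o <- cc |>
      dplyr::group_by(.data$otu_id) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$sample_id), .groups = "drop") |>
      dplyr::filter(.data$n >= min_otu_presence)
    cc <- cc |> dplyr::semi_join(keep_o, by = "otu_id")
  }
  cc |> dplyr::select("haplotype_id", "otu_id", "sample_id", "count")
}

#' Apply the multi-level abundance thresholds to a haplotype table
#'
#' Thresholds are applied in a fixed order: (1) drop haplotypes that never
#' reach `minhaplosize`% of a sample's reads; (2) drop OTUs that never reach
#' `otumin`% of a sample's reads; (3) within each OTU and sample, zero
#' haplotypes below `within_otu`% of that OTU's reads in that sample; (4) drop
#' rows left with no counts; (5) drop haplotypes/OTUs present in fewer than
#' `min_haplo_presence` / `min_otu_presence` samples. All boundaries are
#' inclusive on the keep side ("less than X" is discarded). The cascade is
#' iterated to a fixed point so the returned table is self-consistent under
#' its own thresholds (it almost always converges after one extra pass);
#' filtering therefore only ever removes or zeroes counts and is idempotent.
#'
#' @param table A `haplo_table`.
#' @param minhaplosize Minimum haplotype abundance, percent of sample reads
#'   (default 0.01).
#' @param otumin Minimum OTU abundance, percent of sample reads (default 0.1).
#' @param within_otu Minimum haplotype share within its OTU and sample,
#'   percent (default 5).
#' @param min_haplo_presence,min_otu_presence Minimum number of samples a
#'   haplotype / OTU must be present in (default 1, i.e. off).
#' @return The filtered `haplo_table` with `params_applied` recorded.
#' @export
filter_table <- function(table, minhaplosize = 0.01, otumin = 0.1,
                         within_otu = 5, min_haplo_presence = 1L,
                         min_otu_presence = 1L) {
  stopifnot(inherits(table, "haplo_table"))
  stopifnot(minhaplosize >= 0, minhaplosize <= 100, otumin >= 0, otumin <= 100,
            within_otu >= 0, within_otu <= 100,
            min_haplo_presence >= 1, min_otu_presence >= 1)
  totals <- table$sample_totals
  if (nrow(table$counts)) {
    active <- unique(table$counts$sample_id)
    if (any(totals$total[totals$sample_id %in% active] <= 0)) {
      abort("sample_totals must be positive for samples with counts")
    }
  }
  cur <- table$counts
  repeat {
    nxt <- filter_pass(cur, totals, minhaplosize, otumin, within_otu,
                       min_haplo_presence, min_otu_presence)
    if (nrow(nxt) == nrow(cur)) break
    cur <- nxt
  }
  table$counts <- cur
  table$haplotypes <- table$haplotypes |>
    dplyr::semi_join(cur, by = "haplotype_id")
  table$params_applied <- list(
    minhaplosize = minhaplosize, otumin = otumin, within_otu = within_otu,
    min_haplo_presence = min_haplo_presence, min_otu_presence = min_otu_presence
  )
  table
}
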