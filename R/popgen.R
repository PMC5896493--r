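# Intraspecific-diversity outputs: haplotypes-per-OTU statistics, minimum
# spanning haplotype networks, per-site frequencies, replicate-consistency
# R-squared, and classification against a known truth set.

#' Haplotypes-per-OTU summary
#'
#' Counts haplotypes with any nonzero count per OTU and returns the mean and
#' sample standard deviation over OTUs.
#'
#' @param table A filtered `haplo_table`.
#' @return List with `mean`, `sd`, `per_otu` (tibble `otu_id`,
#'   `n_haplotypes`) and `degenerate` (TRUE when only one OTU is present, in
#'   which case `sd` is reported as 0).
#' @export
haplotypes_per_otu <- function(table) {
  stopifnot(inherits(table, "haplo_table"))
  if (!nrow(table$counts)) abort("haplotypes_per_otu: empty table")
  per_otu <- table$counts |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(n_haplotypes = dplyr::n_distinct(.data$haplotype_id),
                     .groups = "drop")
  degenerate <- nrow(per_otu) < 2L
  list(
    mean = mean(per_otu$n_haplotypes),
    sd = if (degenerate) 0 else stats::sd(per_otu$n_haplotypes),
    per_otu = per_otu,
    degenerate = degenerate
  )
}

# deterministic Kruskal: edges sorted by (distance, -max endpoint abundance,
# lexicographic id pair); union-find over node indices
kruskal_mst <- function(ids, seqs, totals) {
  n <- length(ids)
  if (n < 2L) {
    return(tibble::tibble(from = character(), to = character(), d = integer()))
  }
  dmat <- edit_distance(seqs)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  e <- tibble::tibble(
    i = pairs[, 1], j = pairs[, 2],
    d = dmat[pairs],
    amax = pmax(totals[pairs[, 1]], totals[pairs[, 2]]),
    a = pmin(ids[pairs[, 1]], ids[pairs[, 2]]),
    b = pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  ) |>
    dplyr::arrange(.data$d, dplyr::desc(.data$amax), .data$a, .data$b)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(nrow(e))
  taken <- 0L
  for (k in seq_len(nrow(e))) {
    ri <- find(e$i[k]); rj <- find(e$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  e[keep, c("a", "b", "d")] |> dplyr::rename(from = "a", to = "b")
}

#' Minimum spanning haplotype network for one OTU
#'
#' Reduces the complete pairwise edit-distance graph over the OTU's
#' haplotypes to a minimum spanning tree (each edge step is one base-pair
#' difference of weight). Ties are broken deterministically: among
#' equal-weight edges, those touching the most abundant haplotype win, then
#' the lexicographically smaller id pair. Nodes carry per-site relative
#' frequencies; haplotypes whose sequence is absent from the optional
#' reference set are marked novel.
#'
#' @param table A `haplo_table`.
#' @param otu_id The OTU to build the network for.
#' @param reference Optional truth set: tibble with columns `id`, `seq`.
#' @return A `haplo_network` object: list with `otu_id`, `nodes` (tibble
#'   `haplotype_id`, `seq`, `total`, `novel`), `edges` (`from`, `to`, `d`) and
#'   `frequencies` (per-site relative frequencies from [site_frequencies()]).
#' @export
build_network <- function(table, otu_id, reference = NULL) {
  stopifnot(inherits(table, "haplo_table"))
  rows <- table$counts |> dplyr::filter(.data$otu_id == !!otu_id)
  if (!nrow(rows)) abort(sprintf("OTU '%s' not present in table", otu_id))
  nodes <- rows |>
    dplyr::group_by(.data$haplotype_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(table$haplotypes |> dplyr::select("haplotype_id", "seq"),
                     by = "haplotype_id") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$haplotype_id)
  nodes$novel <- if (is.null(reference)) NA else !(nodes$seq %in% reference$seq)
  edges <- kruskal_mst(nodes$haplotype_id, nodes$seq, nodes$total)
  structure(
    list(otu_id = otu_id, nodes = nodes, edges = edges,
         frequencies = site_frequencies(table, otu_id)),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> OTU %s: %d haplotypes, %d edges (total weight %d)\n",
              x$otu_id, nrow(x$nodes), nrow(x$edges), sum(x$edges$d)))
  invisible(x)
}

#' @export
tidy.haplo_network <- function(x, ...) x$edges

#' @export
glance.haplo_network <- function(x, ...) {
  tibble::tibble(
    otu_id = x$otu_id,
    n_haplotypes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$d),
    n_novel = if (all(is.na(x$nodes$novel))) NA_integer_ else sum(x$nodes$novel)
  )
}

#' Per-site haplotype frequencies within an OTU
#'
#' @param table A `haplo_table`.
#' @param otu_id OTU of interest.
#' @return Tibble (`sample_id`, `haplotype_id`, `frequency`); frequencies sum
#'   to 1 within each occupied site, empty sites are omitted.
#' @export
site_frequencies <- function(table, otu_id) {
  stopifnot(inherits(table, "haplo_table"))
  rows <- table$counts |> dplyr::filter(.data$otu_id == !!otu_id)
  if (!nrow(rows)) abort(sprintf("OTU '%s' not present in table", otu_id))
  rows |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "haplotype_id", "frequency") |>
    dplyr::arrange(.data$sample_id, .data$haplotype_id)
}

#' Replicate-consistency R-squared per OTU
#'
#' For each OTU, the per-(haplotype, site) abundances of two replicate tables
#' are paired (union of haplotypes; absent counts are 0) and replicate B is
#' regressed on replicate A by ordinary least squares; the adjusted R-squared
#' is reported per OTU together with the mean and SD across OTUs. OTUs with
#' fewer than `min_pairs` informative pairs (nonzero in at least one
#' replicate) or with zero variance in either vector are excluded and listed.
#'
#' @param table_a,table_b Replicate `haplo_table`s sharing the haplotype/OTU
#'   namespace and sample ids (e.g. produced by [subset_samples()] on one
#'   pooled run).
#' @param min_pairs Minimum informative pairs per OTU (default 3).
#' @param raw_counts Use raw counts instead of relative abundances.
#' @return A `replicate_r2` object: list with `per_otu` (tibble `otu_id`,
#'   `r2`, `n_pairs`), `excluded`, `mean`, `sd`.
#' @export
replicate_r2 <- function(table_a, table_b, min_pairs = 3L, raw_counts = FALSE) {
  stopifnot(inherits(table_a, "haplo_table"), inherits(table_b, "haplo_table"))
  rel <- function(tab, which) {
    x <- tab$counts |> dplyr::left_join(tab$sample_totals, by = "sample_id")
    val <- if (raw_counts) x$count else x$count / x$total
    tibble::tibble(otu_id = x$otu_id, haplotype_id = x$haplotype_id,
                   sample_id = x$sample_id, !!which := val)
  }
  ab <- dplyr::full_join(
    rel(table_a, "a"), rel(table_b, "b"),
    by = c("otu_id", "haplotype_id", "sample_id")
  ) |>
    dplyr::mutate(a = dplyr::coalesce(.data$a, 0), b = dplyr::coalesce(.data$b, 0))
  fits <- ab |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < min_pairs || stats::sd(g$a) == 0 || stats::sd(g$b) == 0) {
        return(tibble::tibble(otu_id = key$otu_id, r2 = NA_real_, n_pairs = n))
      }
      fit <- stats::lm(b ~ a, data = g)
      rss <- sum(stats::residuals(fit)^2)
      tss <- sum((g$b - mean(g$b))^2)
      # adjusted R^2 computed directly; a perfect fit is exactly 1
      r2 <- if (rss <= 1e-24 * tss) 1 else {
        if (n < 3L) NA_real_ else 1 - (rss / tss) * (n - 1) / (n - 2)
      }
      tibble::tibble(otu_id = key$otu_id, r2 = r2, n_pairs = n)
    }) |>
    dplyr::bind_rows()
  ok <- fits |> dplyr::filter(!is.na(.data$r2))
  structure(
    list(
      per_otu = ok,
      excluded = fits |> dplyr::filter(is.na(.data$r2)),
      mean = if (nrow(ok)) mean(ok$r2) else NA_real_,
      sd = if (nrow(ok) > 1) stats::sd(ok$r2) else 0
    ),
    class = "replicate_r2"
  )
}

#' @export
print.replicate_r2 <- function(x, ...) {
  cat(sprintf("<replicate_r2> %d OTUs: mean adjusted R^2 = %.3f (SD = %.3f); %d excluded\n",
              nrow(x$per_otu), x$mean, x$sd, nrow(x$excluded)))
  invisible(x)
}

#' @export
tidy.replicate_r2 <- function(x, ...) x$per_otu

#' @export
glance.replicate_r2 <- function(x, ...) {
  tibble::tibble(mean_r2 = x$mean, sd_r2 = x$sd,
                 n_otus = nrow(x$per_otu), n_excluded = nrow(x$excluded))
}

#' Classify recovered haplotypes against a known truth set
#'
#' Haplotypes at or above the relative-abundance floor in at least one sample
#' are partitioned into expected (exact sequence match to the truth set) and
#' unexpected; truth sequences not recovered are listed as missed. Relative
#' abundance is computed per sample against that sample's read total, and the
#' samples a haplotype passed the floor in are reported (replicate
#' concordance).
#'
#' @param dn A `haplo_denoise` object (or a `haplo_table`).
#' @param truth Tibble with columns `id`, `seq` (unique sequences).
#' @param floor Relative-abundance floor as a fraction (default 0).
#' @param sample_totals Per-sample totals; taken from the table when `dn` is a
#'   `haplo_table`.
#' @return List with tibbles `expected`, `unexpected`, `missed` and the floor
#'   used. `expected`/`unexpected` carry `haplotype_id`, `seq`, `total` and
#'   `samples` (comma-separated samples where the floor was passed).
#' @export
classify_against_truth <- function(dn, truth, floor = 0, sample_totals = NULL) {
  stopifnot(floor >= 0)
  if (anyDuplicated(truth$seq)) abort("truth sequences must be unique")
  if (inherits(dn, "haplo_table")) {
    counts <- dn$counts |>
      dplyr::left_join(dn$haplotypes |> dplyr::select("haplotype_id", "seq"),
                       by = "haplotype_id")
    totals <- dn$sample_totals
  } else if (inherits(dn, "haplo_denoise")) {
    counts <- dn$counts |>
      dplyr::left_join(dn$centroids |> dplyr::select("haplotype_id", "seq", "chimera"),
                       by = "haplotype_id") |>
      dplyr::filter(!.data$chimera)
    totals <- if (is.null(sample_totals)) {
      dn$counts |> dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(total = sum(.data$count), .groups = "drop")
    } else {
      as_sample_totals(sample_totals)
    }
  } else {
    abort("`dn` must be a haplo_denoise or haplo_table object")
  }
  passed <- counts |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::filter(.data$count / .data$total >= floor, .data$count > 0) |>
    dplyr::group_by(.data$haplotype_id, .data$seq) |>
    dplyr::summarise(total = sum(.data$count),
                     samples = paste(sort(unique(.data$sample_id)), collapse = ","),
                     .groups = "drop")
  expected <- passed |> dplyr::filter(.data$seq %in% truth$seq)
  unexpected <- passed |> dplyr::filter(!(.data$seq %in% truth$seq))
  missed <- truth |> dplyr::filter(!(.data$seq %in% expected$seq))
  list(expected = expected, unexpected = unexpected,
       missed = tibble::as_tibble(missed), floor = floor)
}
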