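# Independent oracles used by the test suite. These deliberately share no
# code with the package internals: the denoiser oracle materialises the full
# distance matrix and applies the greedy rules step by step, and the MST
# oracle enumerates every spanning tree.

# Brute-force greedy abundance-skew denoiser over a (seq, total) table.
# Returns the centroid sequences and, for each input sequence, the centroid
# it was assigned to.
oracle_denoise <- function(seqs, totals, alpha) {
  ord <- order(-totals, seqs)
  seqs <- seqs[ord]
  totals <- totals[ord]
  n <- length(seqs)
  dmat <- as.matrix(utils::adist(seqs))
  beta <- function(d) 1 / 2^(alpha * d + 1)
  centroid <- integer(0)
  owner <- integer(n)
  for (i in seq_len(n)) {
    best <- 0L
    if (length(centroid)) {
      qualifies <- vapply(centroid, function(c) {
        d <- dmat[i, c]
        d >= 1 && totals[i] / totals[c] <= beta(d)
      }, logical(1))
      q <- centroid[qualifies]
      if (length(q)) {
        dq <- dmat[i, q]
        ordq <- order(dq, -totals[q], seqs[q])
        best <- q[ordq[1]]
      }
    }
    if (best == 0L) centroid <- c(centroid, i)
    owner[i] <- if (best == 0L) i else best
  }
  list(centroid_seqs = sort(seqs[centroid]),
       assignment = tibble::tibble(seq = seqs, owner_seq = seqs[owner]))
}

# Minimum spanning tree weight by enumeration over all edge subsets of size
# n - 1 that connect the graph (feasible for n <= 6).
oracle_mst_weight <- function(dmat) {
  n <- nrow(dmat)
  if (n < 2) return(0)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  ne <- nrow(pairs)
  combs <- utils::combn(ne, n - 1)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    sel <- pairs[combs[, k], , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (rep in seq_len(n)) {
      for (e in seq_len(nrow(sel))) {
        a <- comp[sel[e, 1]]; b <- comp[sel[e, 2]]
        if (a != b) comp[comp == b] <- a
      }
    }
    if (length(unique(comp)) == 1L) {
      w <- sum(dmat[sel])
      if (w < best) best <- w
    }
  }
  best
}

# Random unique-sequence tables with the size/distance structure the denoiser
# sees in practice: a few abundant roots plus error variants at small edit
# distances and strongly skewed sizes, plus some unrelated sequences.
random_unique_pool <- function(n_max = 30, seq_len = 24, n_roots = 3) {
  bases <- c("A", "C", "G", "T")
  roots <- replicate(n_roots, paste(sample(bases, seq_len, replace = TRUE),
                                    collapse = ""))
  seqs <- roots
  totals <- sample(200:2000, n_roots)
  n_extra <- sample.int(n_max - n_roots, 1)
  for (k in seq_len(n_extra)) {
    parent <- sample(seqs, 1)
    s <- strsplit(parent, "", fixed = TRUE)[[1]]
    nmut <- sample(1:3, 1)
    for (p in sample(length(s), nmut)) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs <- c(seqs, paste(s, collapse = ""))
    totals <- c(totals, sample(1:50, 1))
  }
  keep <- !duplicated(seqs)
  tibble::tibble(seq = seqs[keep], sample_id = "s1", count = totals[keep])
}

# Small random haplotype tables for the filter property tests.
random_haplo_table <- function(n_otus = 3, max_haps = 4, n_samples = 3) {
  rows <- list()
  hap_i <- 0L
  for (o in seq_len(n_otus)) {
    for (h in seq_len(sample.int(max_haps, 1))) {
      hap_i <- hap_i + 1L
      counts <- rpois(n_samples, lambda = sample(c(2, 20, 200, 2000), 1))
      for (s in seq_len(n_samples)) {
        if (counts[s] > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            haplotype_id = sprintf("hap_%03d", hap_i),
            otu_id = sprintf("otu_%02d", o),
            sample_id = sprintf("s%d", s),
            count = counts[s]
          )
        }
      }
    }
  }
  counts <- dplyr::bind_rows(rows)
  totals <- counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(count) + sample(0:5000, 1), .groups = "drop")
  haps <- counts |> dplyr::distinct(haplotype_id, otu_id) |>
    dplyr::mutate(seq = replicate(dplyr::n(), paste(sample(c("A", "C", "G", "T"),
                                                           20, replace = TRUE),
                                                    collapse = "")))
  structure(list(counts = counts, haplotypes = haps, sample_totals = totals,
                 params_applied = list()),
            class = "haplo_table")
}

# Convenience: a tiny denoise result built directly from explicit centroids.
manual_denoise <- function(centroids, counts) {
  structure(list(
    centroids = centroids,
    counts = counts,
    members = tibble::tibble(haplotype_id = character(), member_seq = character(),
                             size = numeric(), dist = integer()),
    params = list(alpha = 5)
  ), class = "haplo_denoise")
}
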