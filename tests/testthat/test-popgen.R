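# Minimal table constructor for downstream-statistics tests.
mktab <- function(counts, seqs = NULL, totals = NULL) {
  haps <- counts |> dplyr::distinct(haplotype_id, otu_id)
  haps$seq <- seqs %||% replicate(nrow(haps),
    paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE), collapse = ""))
  st <- totals %||% (counts |> dplyr::group_by(sample_id) |>
                       dplyr::summarise(total = sum(count), .groups = "drop"))
  structure(list(counts = counts, haplotypes = haps,
                 sample_totals = st, params_applied = list()),
            class = "haplo_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("haplotypes per OTU gives mean and sample SD, flagging the degenerate case", {
  counts <- tibble::tibble(
    haplotype_id = sprintf("h%d", 1:6),
    otu_id = c("o1", "o2", "o2", "o2", "o3", "o3"),
    sample_id = "s1",
    count = rep(10L, 6)
  )
  res <- haplotypes_per_otu(mktab(counts))
  expect_equal(res$mean, 2)      # counts {1, 3, 2}
  expect_equal(res$sd, 1)
  expect_false(res$degenerate)

  solo <- haplotypes_per_otu(mktab(counts[1, ]))
  expect_equal(solo$sd, 0)
  expect_true(solo$degenerate)
  expect_error(haplotypes_per_otu(mktab(counts[0, ])), "empty")
})

test_that("network MST matches hand-checked cases and brute force on the star", {
  # two haplotypes one difference apart -> single edge of weight 1
  counts2 <- tibble::tibble(haplotype_id = c("h1", "h2"), otu_id = "o1",
                            sample_id = "s1", count = c(30L, 10L))
  net2 <- build_network(mktab(counts2, seqs = c("AAAA", "AAAC")), "o1")
  expect_equal(net2$edges$d, 1L)

  # star: ancestor + 3 derived, each d=1 from ancestor, d=2 pairwise
  counts4 <- tibble::tibble(haplotype_id = c("anc", "d1", "d2", "d3"),
                            otu_id = "o1", sample_id = "s1",
                            count = c(100L, 10L, 10L, 10L))
  seqs <- c("AAAAAA", "CAAAAA", "AACAAA", "AAAAAC")
  net4 <- build_network(mktab(counts4, seqs = seqs), "o1")
  expect_equal(nrow(net4$edges), 3L)
  expect_equal(sum(net4$edges$d), 3L)
  expect_equal(oracle_mst_weight(as.matrix(utils::adist(seqs))), 3)
  expect_true(all(net4$edges$from == "anc" | net4$edges$to == "anc"))

  # single haplotype -> no edges
  net1 <- build_network(mktab(counts4[1, ], seqs = seqs[1]), "o1")
  expect_equal(nrow(net1$edges), 0L)
})

test_that("network MST weight equals brute force and igraph on random instances", {
  withr::with_seed(55, {
    for (k in 1:30) {
      n <- sample(3:6, 1)
      seqs <- character(0)
      while (length(unique(seqs)) < n) {
        seqs <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                                 replace = TRUE), collapse = "")))
      }
      counts <- tibble::tibble(haplotype_id = sprintf("h%02d", seq_len(n)),
                               otu_id = "o1", sample_id = "s1",
                               count = sample(10:100, n))
      net <- build_network(mktab(counts, seqs = seqs), "o1")
      dmat <- as.matrix(utils::adist(seqs))
      expect_equal(sum(net$edges$d), oracle_mst_weight(dmat))
      g <- igraph::graph_from_adjacency_matrix(dmat, weighted = TRUE,
                                               mode = "undirected")
      expect_equal(sum(net$edges$d),
                   sum(igraph::E(igraph::mst(g))$weight))
      # spanning-tree shape: connected with n-1 edges
      expect_equal(nrow(net$edges), n - 1L)
    }
  })
})

test_that("novel haplotypes are those absent from the reference set", {
  counts <- tibble::tibble(haplotype_id = c("h1", "h2"), otu_id = "o1",
                           sample_id = "s1", count = c(30L, 10L))
  ref <- tibble::tibble(id = "known", seq = "AAAA")
  net <- build_network(mktab(counts, seqs = c("AAAA", "AAAC")), "o1",
                       reference = ref)
  expect_equal(net$nodes$novel[match(c("h1", "h2"), net$nodes$haplotype_id)],
               c(FALSE, TRUE))
})

test_that("site frequencies sum to one per occupied site and match ratios", {
  counts <- tibble::tibble(
    haplotype_id = c("h1", "h2", "h1"),
    otu_id = "o1",
    sample_id = c("s1", "s1", "s2"),
    count = c(10L, 30L, 7L)
  )
  f <- site_frequencies(mktab(counts), "o1")
  expect_equal(f$frequency[f$sample_id == "s1"], c(0.25, 0.75))
  expect_equal(f$frequency[f$sample_id == "s2"], 1)
  sums <- f |> dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("replicate R^2 is exactly 1 for identical and scaled tables", {
  counts <- tibble::tibble(
    haplotype_id = rep(c("h1", "h2", "h3"), each = 3),
    otu_id = "o1",
    sample_id = rep(c("s1", "s2", "s3"), 3),
    count = c(50L, 60L, 70L, 10L, 14L, 8L, 4L, 6L, 3L)
  )
  ta <- mktab(counts, totals = tibble::tibble(sample_id = c("s1", "s2", "s3"),
                                              total = c(100, 100, 100)))
  r_same <- replicate_r2(ta, ta)
  expect_equal(r_same$per_otu$r2, 1)
  expect_equal(r_same$mean, 1)

  tb <- ta
  tb$counts$count <- tb$counts$count * 2L
  tb$sample_totals$total <- tb$sample_totals$total   # same denominator: pure scaling
  r_scaled <- replicate_r2(ta, tb)
  expect_equal(r_scaled$per_otu$r2, 1)
})

test_that("replicate R^2 matches a hand-computed OLS fit on four points", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- c(0.12, 0.18, 0.33, 0.41)
  counts_a <- tibble::tibble(haplotype_id = "h1", otu_id = "o1",
                             sample_id = sprintf("s%d", 1:4),
                             count = as.integer(a * 1000))
  counts_b <- counts_a; counts_b$count <- as.integer(b * 1000)
  tot <- tibble::tibble(sample_id = sprintf("s%d", 1:4), total = rep(1000, 4))
  ta <- mktab(counts_a, totals = tot); tb <- mktab(counts_b, totals = tot)
  tb$haplotypes <- ta$haplotypes
  res <- replicate_r2(ta, tb, min_pairs = 3)
  # closed-form adjusted R^2 for simple OLS on 4 points
  fit_ss <- function(x, y) {
    bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ahat <- mean(y) - bhat * mean(x)
    resid <- y - ahat - bhat * x
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    1 - (1 - r2) * (4 - 1) / (4 - 2)
  }
  expect_equal(res$per_otu$r2, fit_ss(a, b), tolerance = 1e-10)
})

test_that("zero-variance OTUs are excluded from replicate R^2 and reported", {
  counts <- tibble::tibble(
    haplotype_id = c("h1", "h1", "h2", "h2"),
    otu_id = c("o1", "o1", "o2", "o2"),
    sample_id = c("s1", "s2", "s1", "s2"),
    count = c(10L, 20L, 30L, 30L)
  )
  tot <- tibble::tibble(sample_id = c("s1", "s2"), total = c(100, 100))
  ta <- mktab(counts, totals = tot)
  res <- replicate_r2(ta, ta, min_pairs = 2)
  expect_true("o2" %in% res$excluded$otu_id)   # constant vector
  expect_false("o2" %in% res$per_otu$otu_id)
})

test_that("classification against a truth set partitions by exact sequence match", {
  cents <- tibble::tibble(
    haplotype_id = c("hap_0001", "hap_0002", "hap_0003"),
    seq = c("AAAA", "AAAC", "GGGG"),
    total = c(1000L, 100L, 5L),
    own_total = c(1000L, 100L, 5L),
    chimera = FALSE
  )
  counts <- tibble::tibble(haplotype_id = rep(cents$haplotype_id, 2),
                           sample_id = rep(c("repA", "repB"), each = 3),
                           count = c(500L, 50L, 5L, 500L, 50L, 0L))
  dn <- manual_denoise(cents, counts)
  truth <- tibble::tibble(id = c("t1", "t2"), seq = c("AAAA", "TTTT"))
  res <- classify_against_truth(dn, truth, floor = 0)
  expect_equal(res$expected$seq, "AAAA")
  expect_setequal(res$unexpected$seq, c("AAAC", "GGGG"))
  expect_equal(res$missed$id, "t2")   # truth seq absent from output
  # replicate concordance: hap_0003 only passes in repA
  expect_equal(res$unexpected$samples[res$unexpected$seq == "GGGG"], "repA")

  # monotone non-increasing in the floor
  floors <- c(0, 1e-4, 1e-2, 0.2)
  hits <- vapply(floors, function(f) {
    nrow(classify_against_truth(dn, truth, floor = f)$expected)
  }, numeric(1))
  expect_true(all(diff(hits) <= 0))
})
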