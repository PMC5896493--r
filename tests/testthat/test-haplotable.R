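test_that("OTU clustering follows the greedy identity rules including the chain case", {
  # two 100-bp sequences, 10 differences: 0.90 identity -> 2 OTUs at 0.97
  base <- strrep("A", 100)
  mut <- function(s, pos) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]; ch[pos] <- "C"
    paste(ch, collapse = "")
  }
  far <- mut(base, 1:10)
  h2 <- tibble::tibble(haplotype_id = c("h1", "h2"), seq = c(base, far),
                       total = c(100L, 50L))
  expect_equal(length(unique(cluster_otus(h2)$otu_id)), 2L)

  # 2 differences: 0.98 identity -> 1 OTU
  near <- mut(base, 1:2)
  h1 <- tibble::tibble(haplotype_id = c("h1", "h2"), seq = c(base, near),
                       total = c(100L, 50L))
  expect_equal(length(unique(cluster_otus(h1)$otu_id)), 1L)

  # chain a-b 3%, b-c 3%, a-c 6%: b joins a's OTU, c founds its own
  a <- base; b <- mut(base, 1:3); c_ <- mut(base, 1:6)
  chain <- tibble::tibble(haplotype_id = c("a", "b", "c"),
                          seq = c(a, b, c_), total = c(300L, 200L, 100L))
  res <- cluster_otus(chain)
  expect_equal(res$otu_id[match(c("a", "b", "c"), res$haplotype_id)],
               c("otu_001", "otu_001", "otu_002"))

  # limit checks
  expect_equal(length(unique(cluster_otus(chain, identity = 1)$otu_id)), 3L)
  expect_equal(length(unique(cluster_otus(chain, identity = 1e-9)$otu_id)), 1L)
})

test_that("build_table sums OTU counts over member haplotypes", {
  cents <- tibble::tibble(haplotype_id = c("hap_0001", "hap_0002"),
                          seq = c(strrep("A", 50), paste0(strrep("A", 49), "C")),
                          total = c(90L, 10L), own_total = c(90L, 10L),
                          chimera = FALSE)
  counts <- tibble::tibble(haplotype_id = cents$haplotype_id, sample_id = "s1",
                           count = c(90L, 10L))
  dn <- manual_denoise(cents, counts)
  otus <- cluster_otus(dn)
  tab <- build_table(otus, dn, c(s1 = 100))
  otu_sum <- tab$counts |> dplyr::group_by(otu_id, sample_id) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_equal(otu_sum$n, 100L)
  expect_equal(nrow(as_tibble(tab)), 2L)
})

test_that("the within-OTU 5% rule zeroes minor haplotypes against the OTU total", {
  # OTU with counts {90, 6, 4}: 4% row zeroed, 6% kept
  counts <- tibble::tibble(
    haplotype_id = c("h1", "h2", "h3"),
    otu_id = "otu_001",
    sample_id = "s1",
    count = c(90L, 6L, 4L)
  )
  tab <- structure(list(
    counts = counts,
    haplotypes = counts |> dplyr::distinct(haplotype_id, otu_id) |>
      dplyr::mutate(seq = c("AAAA", "AAAC", "AAAG")),
    sample_totals = tibble::tibble(sample_id = "s1", total = 100),
    params_applied = list()
  ), class = "haplo_table")
  out <- filter_table(tab, minhaplosize = 0.01, otumin = 0.1, within_otu = 5)
  expect_setequal(out$counts$haplotype_id, c("h1", "h2"))
  expect_equal(out$counts$count, c(90L, 6L))
})

test_that("minhaplosize retains the inclusive 0.01% boundary", {
  counts <- tibble::tibble(
    haplotype_id = c("big", "atfloor", "below"),
    otu_id = "otu_001",
    sample_id = "s1",
    count = c(989900L, 100L, 50L)   # of 1e6: 98.99%, 0.01%, 0.005%
  )
  tab <- structure(list(
    counts = counts,
    haplotypes = counts |> dplyr::distinct(haplotype_id, otu_id) |>
      dplyr::mutate(seq = c("AAAA", "AAAC", "AAAG")),
    sample_totals = tibble::tibble(sample_id = "s1", total = 1e6),
    params_applied = list()
  ), class = "haplo_table")
  out <- filter_table(tab, minhaplosize = 0.01, otumin = 0.1, within_otu = 0)
  expect_true("atfloor" %in% out$counts$haplotype_id)
  expect_false("below" %in% out$counts$haplotype_id)
})

test_that("presence filtering drops haplotypes seen in too few samples", {
  counts <- tibble::tibble(
    haplotype_id = c("h1", "h1", "h2"),
    otu_id = "otu_001",
    sample_id = c("s1", "s2", "s1"),
    count = c(500L, 500L, 400L)
  )
  tab <- structure(list(
    counts = counts,
    haplotypes = counts |> dplyr::distinct(haplotype_id, otu_id) |>
      dplyr::mutate(seq = c("AAAA", "AAAC")),
    sample_totals = tibble::tibble(sample_id = c("s1", "s2"), total = c(1000, 1000)),
    params_applied = list()
  ), class = "haplo_table")
  out <- filter_table(tab, within_otu = 0, min_haplo_presence = 2)
  expect_setequal(unique(out$counts$haplotype_id), "h1")
})

test_that("filter_table is idempotent and monotone over random tables", {
  withr::with_seed(303, {
    for (k in 1:40) {
      tab <- random_haplo_table()
      p <- list(minhaplosize = sample(c(0.01, 0.5, 2), 1),
                otumin = sample(c(0.1, 1), 1),
                within_otu = sample(c(0, 5, 10), 1))
      f1 <- filter_table(tab, p$minhaplosize, p$otumin, p$within_otu)
      f2 <- filter_table(f1, p$minhaplosize, p$otumin, p$within_otu)
      expect_equal(f2$counts, f1$counts)

      # raising any threshold never adds a haplotype or increases a count
      stricter <- filter_table(tab, p$minhaplosize * 2, p$otumin * 2,
                               min(p$within_otu + 5, 100))
      expect_true(all(stricter$counts$haplotype_id %in% f1$counts$haplotype_id))
      joined <- dplyr::inner_join(
        stricter$counts, f1$counts,
        by = c("haplotype_id", "otu_id", "sample_id"))
      expect_true(all(joined$count.x <= joined$count.y))
    }
  })
})
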