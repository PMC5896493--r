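mkreads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  tibble::tibble(id = paste0("r", seq_along(seqs)), seq = seqs, qual = quals)
}

test_that("pair merging finds the best overlap and applies the posterior quality rule", {
  # identical 7-base overlap of two 8-mers yields the 9-mer at Q40 throughout
  fwd <- mkreads("ACGTACGT")
  rev <- mkreads(revcomp("CGTACGTA"))
  merged <- merge_pairs(fwd, rev, min_overlap = 4)
  expect_equal(merged$seq, "ACGTACGTA")
  expect_equal(phred_scores(merged$qual)[[1]], rep(40L, 9))

  # no overlap >= min_overlap -> reject, counted in stage stats
  none <- merge_pairs(mkreads("AAAAAAAA"), mkreads("CCCCCCCC"), min_overlap = 6)
  expect_equal(nrow(none), 0L)
  expect_equal(stage_stats(none)$rejected, 1L)

  # one disagreeing base: fwd Q40 vs rev Q10 -> fwd base kept with quality 30
  fwd <- mkreads("ACGTACGT")                      # all Q40
  rev_seq <- revcomp("CGTACGTA")
  rev_qual <- strrep("+", 8)                      # '+' = Phred 10
  merged <- merge_pairs(fwd, mkreads(rev_seq, rev_qual), min_overlap = 4)
  expect_equal(merged$seq, "ACGTACGTA")
  q <- phred_scores(merged$qual)[[1]]
  expect_equal(q[1:8], rep(40L, 8))   # agreement keeps max Q
  expect_equal(q[9], 10L)             # overhang from the reverse read

  rev2 <- mkreads(revcomp("CGTACGGA"), rev_qual)  # disagrees at overlap pos 7
  merged2 <- merge_pairs(fwd, rev2, min_overlap = 4, max_mismatch_frac = 0.3)
  q2 <- phred_scores(merged2$qual)[[1]]
  expect_equal(substr(merged2$seq, 8, 8), "T")    # higher-Q fwd base wins
  expect_equal(q2[8], 30L)                        # |40 - 10|
})

test_that("pair merging is symmetric under role exchange with reverse complement", {
  withr::with_seed(5, {
    for (k in 1:10) {
      insert <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
      f <- substr(insert, 1, 28)
      r <- revcomp(substr(insert, 13, 40))
      a <- merge_pairs(mkreads(f), mkreads(r), min_overlap = 10)
      b <- merge_pairs(mkreads(r), mkreads(f), min_overlap = 10)
      expect_equal(a$seq, insert)
      expect_equal(b$seq, revcomp(insert))
    }
  })
})

test_that("primer trimming is IUPAC-aware and orientation-invariant", {
  fwd_p <- "GGWACWGG"
  rev_p <- "TCCGGAAT"   # appears as revcomp at the 3' end
  insert <- "ACGTACGTACGTACGTACGT"
  read <- paste0("GGAACAGG", insert, revcomp(rev_p))   # W matched by A
  tr <- trim_and_orient(mkreads(read), fwd_p, rev_p)
  expect_equal(tr$seq, insert)

  # reverse-complemented read yields the identical insert
  rc <- trim_and_orient(mkreads(revcomp(read)), fwd_p, rev_p)
  expect_equal(rc$seq, insert)
  expect_equal(attr(rc, "orientation")[["reverse"]], 1L)

  # too many mismatches to both orientations -> reject
  bad <- paste0("TTTTTTTT", insert, revcomp(rev_p))
  rej <- trim_and_orient(mkreads(bad), fwd_p, rev_p, max_mismatch = 2)
  expect_equal(nrow(rej), 0L)
  expect_equal(stage_stats(rej)$rejected, 1L)
})

test_that("orientation invariance holds for random passing reads (with qualities)", {
  fwd_p <- "GGWACWGG"; rev_p <- "TGRTTYTT"
  withr::with_seed(21, {
    for (k in 1:20) {
      insert <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
      qual <- paste(sample(strsplit("IJKLMNOP", "")[[1]], 46, replace = TRUE),
                    collapse = "")
      read <- paste0("GGAACAGG", insert, revcomp("TGATTCTT"))
      fwd_res <- trim_and_orient(mkreads(read, qual), fwd_p, rev_p)
      rev_res <- trim_and_orient(
        tibble::tibble(id = "r1", seq = revcomp(read),
                       qual = stringi::stri_reverse(qual)),
        fwd_p, rev_p)
      expect_equal(rev_res$seq, fwd_res$seq)
      expect_equal(rev_res$qual, fwd_res$qual)
    }
  })
})

test_that("expected error is the sum of per-base error probabilities", {
  # 50 bases at Q20 -> ee = 0.5 exactly
  r <- mkreads(strrep("A", 50), strrep("5", 50))   # '5' = Phred 20
  expect_equal(expected_error(r), 0.5)
  # empty read -> 0
  expect_equal(expected_error(tibble::tibble(id = "e", seq = "", qual = "")), 0)
  # mixed qualities [10, 20, 30] -> 0.111
  r3 <- mkreads("ACG", intToUtf8(c(10, 20, 30) + 33))
  expect_equal(expected_error(r3), 0.111)
})

test_that("ee filtering keeps the inclusive boundary and is idempotent and monotone", {
  r <- mkreads(c(strrep("A", 50), strrep("C", 50), strrep("G", 10)),
               c(strrep("5", 50), strrep("+", 50), strrep("I", 10)))
  # ee: 0.5 (boundary, kept), 5.0 (discarded), tiny (kept)
  kept <- filter_ee(r, 0.5)
  expect_setequal(kept$id, c("r1", "r3"))
  expect_equal(stage_stats(kept)$kept + stage_stats(kept)$rejected, 3L)

  withr::with_seed(9, {
    for (k in 1:10) {
      n <- sample(5:50, 1)
      quals <- vapply(seq_len(n), function(i) {
        paste(intToUtf8(sample(35:73, 30, replace = TRUE), multiple = FALSE), collapse = "")
      }, character(1))
      rr <- mkreads(rep(strrep("A", 30), n), quals)
      e <- runif(1, 0.05, 1)
      once <- filter_ee(rr, e)
      expect_equal(filter_ee(once, e)$id, once$id)          # idempotent
      expect_true(all(filter_ee(rr, e / 2)$id %in% once$id)) # monotone
    }
  })
})

test_that("exact-length filter keeps only the target length", {
  r <- mkreads(c(strrep("A", 178), strrep("C", 178), strrep("G", 177), strrep("T", 179)))
  kept <- filter_exact_length(r, 178)
  expect_equal(nrow(kept), 2L)
  expect_equal(nrow(filter_exact_length(kept, 178)), 2L)    # identity when all match
  expect_equal(nrow(filter_exact_length(r[0, ], 178)), 0L)
})

test_that("subsampling is deterministic, order-preserving and without replacement", {
  r <- mkreads(rep(strrep("A", 5), 1000))
  r$id <- sprintf("r%04d", 1:1000)
  s1 <- subsample_reads(r, 100, seed = 3)
  s2 <- subsample_reads(r, 100, seed = 3)
  expect_identical(s1$id, s2$id)
  expect_equal(anyDuplicated(s1$id), 0L)
  expect_false(is.unsorted(match(s1$id, r$id)))
  expect_identical(subsample_reads(r, 1000, seed = 1)$id, r$id)
  expect_error(subsample_reads(r, 1001, seed = 1), "lower the target depth")
})
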