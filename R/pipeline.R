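# End-to-end pipeline: preprocess -> per-sample prefilter -> pool -> denoise
# -> chimera flag -> OTU clustering -> haplotype table -> threshold filter,
# with per-stage read accounting throughout.

#' Preprocess the reads of one sample
#'
#' Runs (optional) pair merging, primer trimming/orientation, expected-error
#' filtering, exact-length filtering and (optional) subsampling, collecting
#' the per-stage read accounting.
#'
#' @param reads Tibble of reads (merged/single-end), or a list
#'   `list(fwd = , rev = )` of paired read tibbles.
#' @param fwd_primer,rev_primer Primer pair (IUPAC).
#' @param target_len Exact insert length to keep.
#' @param max_ee Expected-error ceiling (default 0.5).
#' @param subsample_n Optional target depth; NULL skips subsampling.
#' @param seed Seed for subsampling.
#' @param min_overlap,max_mismatch_frac Pair-merging parameters.
#' @return Tibble of clean reads; `attr(, "stages")` holds the per-stage
#'   accounting.
#' @export
preprocess_sample <- function(reads, fwd_primer, rev_primer, target_len,
                              max_ee = 0.5, subsample_n = NULL, seed = 1L,
                              min_overlap = 16, max_mismatch_frac = 0.25) {
  stages <- list()
  if (is.list(reads) && !is.data.frame(reads)) {
    stopifnot(all(c("fwd", "rev") %in% names(reads)))
    reads <- merge_pairs(reads$fwd, reads$rev, min_overlap, max_mismatch_frac)
    stages <- c(stages, list(stage_stats(reads)))
  }
  reads <- trim_and_orient(reads, fwd_primer, rev_primer)
  stages <- c(stages, list(stage_stats(reads)))
  reads <- filter_ee(reads, max_ee)
  stages <- c(stages, list(stage_stats(reads)))
  reads <- filter_exact_length(reads, target_len)
  stages <- c(stages, list(stage_stats(reads)))
  if (!is.null(subsample_n)) {
    reads <- subsample_reads(reads, subsample_n, seed)
    stages <- c(stages, list(stage_stats(reads)))
  }
  attr(reads, "stages") <- dplyr::bind_rows(stages)
  reads
}

#' Run the full haplotyping pipeline
#'
#' Takes demultiplexed per-sample reads through preprocessing, the per-sample
#' abundance prefilter, pooling, abundance-skew denoising, chimera flagging,
#' OTU clustering, table construction and the multi-level threshold filter.
#'
#' @param samples Named list of read tibbles (one per sample; an element may
#'   be `list(fwd=, rev=)` for unmerged pairs), or a manifest tibble/path with
#'   columns `sample_id`, `replicate_id`, `path` (and optional `path2`) whose
#'   FASTQ files will be read. Manifest samples are keyed
#'   `<sample_id>_<replicate_id>` when replicate ids are informative.
#' @param fwd_primer,rev_primer Primer pair.
#' @param target_len Exact amplicon length after primer removal.
#' @param max_ee Expected-error ceiling (default 0.5).
#' @param subsample_n Optional per-sample depth to equalise to.
#' @param min_abs,min_rel Per-sample prefilter floors (default 10 copies and
#'   0.001%).
#' @param alpha Denoising strictness (default 5).
#' @param chimera_check Flag exact two-parent chimeras (default TRUE).
#' @param otu_identity OTU clustering identity (default 0.97).
#' @param apply_filters Apply the table-level thresholds (default TRUE).
#' @param minhaplosize,otumin,within_otu,min_haplo_presence,min_otu_presence
#'   Table filter thresholds, see [filter_table()].
#' @param seed Integer seed (subsampling).
#' @param outdir Optional run directory; tables, centroid FASTA and stage
#'   statistics are written there.
#' @return A `haplo_run` object: list with `stage_stats`, `sample_totals`,
#'   `denoise`, `otus`, `table_raw` (unfiltered), `table` (filtered) and
#'   `summary` (one-row tibble of headline metrics: OTU count, haplotype
#'   count, mean haplotypes per OTU).
#' @export
run_pipeline <- function(samples, fwd_primer, rev_primer, target_len,
                         max_ee = 0.5, subsample_n = NULL,
                         min_abs = 10, min_rel = 1e-5, alpha = 5,
                         chimera_check = TRUE, otu_identity = 0.97,
                         apply_filters = TRUE,
                         minhaplosize = 0.01, otumin = 0.1, within_otu = 5,
                         min_haplo_presence = 1L, min_otu_presence = 1L,
                         seed = 1L, outdir = NULL) {
  if (is.character(samples) && length(samples) == 1L) {
    samples <- read_manifest(samples)
  }
  if (is.data.frame(samples)) {
    m <- samples
    key <- if (length(unique(m$replicate_id)) > 1L || anyDuplicated(m$sample_id)) {
      paste(m$sample_id, m$replicate_id, sep = "_")
    } else m$sample_id
    has_path2 <- "path2" %in% names(m)
    samples <- lapply(seq_len(nrow(m)), function(i) {
      if (has_path2 && !is.na(m$path2[i]) && nzchar(m$path2[i])) {
        list(fwd = read_fastq(m$path[i]), rev = read_fastq(m$path2[i]))
      } else {
        read_fastq(m$path[i])
      }
    })
    names(samples) <- key
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    abort("`samples` must be a named list of read tibbles")
  }

  uniques <- list()
  totals <- numeric(0)
  all_stats <- list()
  for (sid in names(samples)) {
    clean <- preprocess_sample(samples[[sid]], fwd_primer, rev_primer, target_len,
                               max_ee = max_ee, subsample_n = subsample_n,
                               seed = seed + which(names(samples) == sid))
    st <- attr(clean, "stages")
    st$sample_id <- sid
    all_stats[[sid]] <- st
    totals[sid] <- nrow(clean)
    uniques[[sid]] <- dereplicate(clean, sid)
  }
  stage_tbl <- dplyr::bind_rows(all_stats) |> dplyr::relocate("sample_id")
  sample_totals <- tibble::tibble(sample_id = names(totals), total = unname(totals))

  filtered <- lapply(uniques, prefilter, sample_totals = sample_totals,
                     min_abs = min_abs, min_rel = min_rel)
  pooled <- pool_uniques(filtered)
  if (!nrow(pooled)) abort("no reads survived preprocessing and prefiltering")
  dn <- denoise(pooled, alpha = alpha)
  if (chimera_check) dn <- flag_chimeras(dn)
  otus <- cluster_otus(dn, identity = otu_identity)
  table_raw <- build_table(otus, dn, sample_totals)
  tab <- if (apply_filters) {
    filter_table(table_raw, minhaplosize = minhaplosize, otumin = otumin,
                 within_otu = within_otu,
                 min_haplo_presence = min_haplo_presence,
                 min_otu_presence = min_otu_presence)
  } else {
    table_raw
  }
  hpo <- if (nrow(tab$counts)) haplotypes_per_otu(tab) else
    list(mean = NA_real_, sd = NA_real_, per_otu = tibble::tibble(), degenerate = TRUE)
  summary <- tibble::tibble(
    n_samples = nrow(sample_totals),
    reads_clean = sum(sample_totals$total),
    reads_denoised = sum(dn$counts$count),
    n_centroids = nrow(dn$centroids),
    n_chimeric = sum(dn$centroids$chimera),
    n_otus = length(unique(tab$counts$otu_id)),
    n_haplotypes = length(unique(tab$counts$haplotype_id)),
    mean_haplotypes_per_otu = hpo$mean,
    sd_haplotypes_per_otu = hpo$sd
  )
  run <- structure(
    list(stage_stats = stage_tbl, sample_totals = sample_totals,
         denoise = dn, otus = otus, table_raw = table_raw, table = tab,
         summary = summary,
         params = list(max_ee = max_ee, subsample_n = subsample_n,
                       min_abs = min_abs, min_rel = min_rel, alpha = alpha,
                       chimera_check = chimera_check, otu_identity = otu_identity,
                       apply_filters = apply_filters, minhaplosize = minhaplosize,
                       otumin = otumin, within_otu = within_otu,
                       min_haplo_presence = min_haplo_presence,
                       min_otu_presence = min_otu_presence, seed = seed)),
    class = "haplo_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.haplo_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<haplo_run> %d samples, %s clean reads\n",
    "  denoised: %d centroids (%d chimeric) carrying %s reads\n",
    "  final table: %d haplotypes in %d OTUs (mean %.2f, SD %.2f haplotypes/OTU)\n"),
    s$n_samples, format(s$reads_clean, big.mark = ","),
    s$n_centroids, s$n_chimeric, format(s$reads_denoised, big.mark = ","),
    s$n_haplotypes, s$n_otus, s$mean_haplotypes_per_otu, s$sd_haplotypes_per_otu))
  invisible(x)
}

#' @export
glance.haplo_run <- function(x, ...) x$summary

#' @export
tidy.haplo_run <- function(x, ...) tidy(x$table)

# Write the run's tables and statistics into a directory.
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$stage_stats, file.path(outdir, "stage_stats.tsv"))
  readr::write_tsv(run$sample_totals, file.path(outdir, "sample_totals.tsv"))
  cents <- run$denoise$centroids
  writeLines(
    paste0(">", cents$haplotype_id, ";size=", cents$total,
           ifelse(cents$chimera, ";chimera", ""), "\n", cents$seq),
    file.path(outdir, "centroids.fasta")
  )
  readr::write_tsv(run$denoise$members, file.path(outdir, "members.tsv"))
  readr::write_tsv(run$otus, file.path(outdir, "otus.tsv"))
  readr::write_tsv(as_tibble(run$table_raw), file.path(outdir, "haplotype_table_raw.tsv"))
  readr::write_tsv(as_tibble(run$table), file.path(outdir, "haplotype_table.tsv"))
  readr::write_tsv(run$summary, file.path(outdir, "summary.tsv"))
  invisible(outdir)
}
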