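# Mock-community read simulator with full ground truth.
#
# Emulates two validation designs: a single-species mock (31 specimens
# carrying 15 known haplotypes whose biomass spans three orders of magnitude,
# sequenced in two replicates) and multi-species communities of divergent
# OTUs, each carrying closely related haplotypes with site-structured
# frequencies. Reads carry their template of origin so recovery can be scored
# exactly.

# Standard degenerate COI primers used as simulation defaults.
DEFAULT_FWD_PRIMER <- "GGDACWGGWTGAACWGTWTAYCCHCC"
DEFAULT_REV_PRIMER <- "TCDGGRTGNCCRAARAAYCA"

# Replace degenerate IUPAC positions with concrete bases (uses the current
# RNG state): amplified molecules carry whatever the template offered at the
# degenerate primer positions.
concretize_iupac <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    deg <- which(!(ch %in% DNA_BASES))
    for (p in deg) ch[p] <- sample(IUPAC_SETS[[ch[p]]], 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Sequencing error model for the read simulator
#'
#' @param sub_rate Per-base substitution probability (default 0.002).
#' @param indel_rate Per-base single-base indel probability (default 2e-4).
#' @param chimera_frac Fraction of reads formed by splicing two templates at a
#'   uniform crossover (default 0.01).
#' @param q_mean Mean Phred score at the 5' end (default 35).
#' @param q_sd Per-base Phred standard deviation (default 3).
#' @param q_end_loss Mean Phred drop from 5' to 3' end (default 5).
#' @return An `error_model` list.
#' @export
error_model <- function(sub_rate = 0.002, indel_rate = 2e-4, chimera_frac = 0.01,
                        q_mean = 35, q_sd = 3, q_end_loss = 5) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            chimera_frac >= 0, chimera_frac <= 1)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 chimera_frac = chimera_frac, q_mean = q_mean, q_sd = q_sd,
                 q_end_loss = q_end_loss),
            class = "error_model")
}

#' Generate a set of related haplotype sequences
#'
#' Draws a random ancestor of `amplicon_len` bases; each further haplotype
#' substitutes its own disjoint set of 2 to `divergence` ancestor positions
#' (1 when `divergence` is 1). All haplotypes are pairwise distinct, pairwise
#' distances lie in `[1, 2 * divergence]`, and — because mutated position sets
#' do not overlap — any two haplotypes differ by at least two substitutions,
#' so abundance-skew denoising can in principle separate all of them.
#'
#' @param n_haplotypes Number of haplotypes (the first is the ancestor).
#' @param amplicon_len Amplicon length in bp (default 178, a short COI
#'   fragment).
#' @param divergence Maximum substitutions per haplotype relative to the
#'   ancestor (default 4).
#' @param seed Integer seed.
#' @return Tibble (`haplotype_id`, `seq`).
#' @export
make_haplotypes <- function(n_haplotypes = 15, amplicon_len = 178,
                            divergence = 4, seed = 1L) {
  stopifnot(n_haplotypes >= 1, amplicon_len > 0, divergence >= 1)
  withr::with_seed(seed, {
    ancestor <- paste(sample(DNA_BASES, amplicon_len, replace = TRUE), collapse = "")
    tibble::tibble(
      haplotype_id = sprintf("H%02d", seq_len(n_haplotypes)),
      seq = mutate_from_ancestor(ancestor, n_haplotypes, divergence)
    )
  })
}

# Derive n haplotypes from `ancestor` (included as the first); each variant
# substitutes its own disjoint block of 2..divergence positions. Uses the
# current RNG state.
mutate_from_ancestor <- function(ancestor, n, divergence) {
  if (n == 1L) return(ancestor)
  len <- nchar(ancestor)
  lo <- min(2L, divergence)
  n_subs <- sample(lo:divergence, n - 1L, replace = TRUE)
  if (sum(n_subs) > len) {
    abort("cannot place distinct haplotypes within the divergence budget: amplicon too short")
  }
  pool <- sample.int(len)
  anc <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  taken <- 0L
  seqs <- character(n)
  seqs[1] <- ancestor
  for (h in seq_len(n - 1L)) {
    pos <- pool[(taken + 1L):(taken + n_subs[h])]
    taken <- taken + n_subs[h]
    s <- anc
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, anc[p]), 1L)
    seqs[h + 1L] <- paste(s, collapse = "")
  }
  seqs
}

#' Assign specimen biomasses spanning a given number of decades
#'
#' Biomasses are log-uniform over `[1, 10^decades]` and rescaled to sum to 1;
#' a specimen's expected read share is proportional to its biomass.
#'
#' @param n_specimens Number of specimens (default 31).
#' @param decades Orders of magnitude spanned (default 3); 0 gives equal
#'   shares.
#' @param seed Integer seed.
#' @return Tibble (`specimen_id`, `biomass`, `share`); shares sum to 1.
#' @export
assign_biomass <- function(n_specimens = 31, decades = 3, seed = 1L) {
  stopifnot(n_specimens >= 1, decades >= 0)
  withr::with_seed(seed, {
    biomass <- 10^stats::runif(n_specimens, 0, decades)
    tibble::tibble(
      specimen_id = sprintf("S%02d", seq_len(n_specimens)),
      biomass = biomass,
      share = biomass / sum(biomass)
    )
  })
}

# Position-dependent quality strings: mean declines linearly by q_end_loss
# from 5' to 3'; scores clipped to [2, 41]. One call handles all reads.
random_quals <- function(lens, model, offset = 33L) {
  n <- length(lens)
  if (!n) return(character(0))
  out <- character(n)
  chunks <- split(seq_len(n), ceiling(cumsum(as.numeric(lens)) / 4e6))
  for (ii in chunks) {
    l <- lens[ii]
    pos <- sequence(l)
    lrep <- rep.int(l, l)
    mu <- model$q_mean - model$q_end_loss * (pos - 1) / pmax(lrep - 1, 1)
    q <- pmin(41L, pmax(2L, as.integer(round(stats::rnorm(length(pos), mu, model$q_sd)))))
    big <- intToUtf8(q + offset)
    stops <- cumsum(l)
    starts <- stops - l + 1L
    out[ii] <- substring(big, starts, stops)
  }
  out
}

#' Simulate amplicon reads from a set of templates
#'
#' Reads are drawn multinomially by template share. A `chimera_frac` fraction
#' of reads is spliced from the read's own template and a second,
#' share-weighted template at a uniform crossover. Per-base Phred qualities
#' follow the model's profile; substitution counts per read are binomial at
#' `sub_rate` with positions weighted by each base's Phred-implied error
#' probability, so errors concentrate where the emitted qualities say they
#' should. Indels are placed uniformly at `indel_rate`. Fully deterministic
#' under `seed`.
#'
#' @param templates Tibble (`template_id`, `seq`, `share`); shares need not be
#'   normalised.
#' @param n_reads Number of reads to draw.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for read ids.
#' @return Read tibble (`id`, `seq`, `qual`) with provenance columns
#'   `template_id` and `chimera`.
#' @export
sequence_reads <- function(templates, n_reads, model = error_model(), seed = 1L,
                           id_prefix = "read") {
  stopifnot(n_reads >= 1, nrow(templates) >= 1)
  shares <- templates$share / sum(templates$share)
  nt <- nrow(templates)
  withr::with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n_reads, shares))
    tpl <- sample(rep.int(seq_len(nt), counts))
    seqs <- templates$seq[tpl]
    n <- length(tpl)

    chim <- logical(n)
    if (model$chimera_frac > 0 && nt >= 2L) {
      chim <- stats::runif(n) < model$chimera_frac
      ci <- which(chim)
      for (i in ci) {
        others <- setdiff(seq_len(nt), tpl[i])
        partner <- if (length(others) == 1L) others else {
          sample(others, 1L, prob = shares[others])
        }
        lmin <- min(nchar(seqs[i]), nchar(templates$seq[partner]))
        k <- sample.int(lmin - 1L, 1L)
        seqs[i] <- paste0(substr(seqs[i], 1L, k),
                          substr(templates$seq[partner], k + 1L,
                                 nchar(templates$seq[partner])))
      }
    }

    lens <- nchar(seqs)
    quals <- random_quals(lens, model)

    n_sub <- stats::rbinom(n, lens, model$sub_rate)
    for (i in which(n_sub > 0L)) {
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      w <- 10^(-(utf8ToInt(quals[i]) - 33L) / 10)
      pos <- sample.int(lens[i], n_sub[i], prob = w)
      for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
      seqs[i] <- paste(s, collapse = "")
    }

    if (model$indel_rate > 0) {
      n_ind <- stats::rbinom(n, lens, model$indel_rate)
      for (i in which(n_ind > 0L)) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        q <- strsplit(quals[i], "", fixed = TRUE)[[1]]
        for (k in seq_len(n_ind[i])) {
          len <- length(s)
          p <- sample.int(len, 1L)
          if (stats::runif(1) < 0.5 && len > 1L) {
            s <- s[-p]; q <- q[-p]
          } else {
            s <- append(s, sample(DNA_BASES, 1L), after = p)
            q <- append(q, q[p], after = p)
          }
        }
        seqs[i] <- paste(s, collapse = "")
        quals[i] <- paste(q, collapse = "")
      }
    }

    out <- tibble::tibble(
      id = sprintf("%s_%07d", id_prefix, seq_len(n)),
      seq = seqs, qual = quals,
      template_id = templates$template_id[tpl],
      chimera = chim
    )
    attr(out, "phred_offset") <- 33L
    out
  })
}

#' Simulate the single-species mock-community experiment
#'
#' Emulates a mock of `n_specimens` individuals carrying `n_haplotypes`
#' distinct haplotypes of a short COI amplicon, with biomass spanning
#' `biomass_decades` orders of magnitude and read share proportional to
#' biomass, sequenced in independent replicates. Specimens are assigned to
#' haplotypes round-robin so every haplotype is carried by at least one
#' specimen. Templates carry the primer pair so the reads exercise trimming.
#'
#' @param n_specimens,n_haplotypes,amplicon_len,biomass_decades Mock design
#'   (defaults 31, 15, 178 bp, 3 decades).
#' @param divergence Maximum substitutions per haplotype vs the ancestor.
#' @param n_reads Reads per replicate (default 1e6).
#' @param replicates Number of sequencing replicates (default 2).
#' @param model An [error_model()].
#' @param fwd_primer,rev_primer Primers attached to each template.
#' @param seed Integer seed controlling everything.
#' @param dir Optional directory; when given, FASTQ files, a manifest and
#'   truth tables are written there.
#' @return List with `reads` (named list of read tibbles, one per replicate
#'   sample `repA`, `repB`, ...), `truth` (list: `haplotypes`, `specimens`,
#'   `hap_shares`, `draws` = realised reads per haplotype and replicate) and
#'   `params`.
#' @export
simulate_mock <- function(n_specimens = 31, n_haplotypes = 15,
                          amplicon_len = 178, biomass_decades = 3,
                          divergence = 4, n_reads = 1e6, replicates = 2,
                          model = error_model(),
                          fwd_primer = DEFAULT_FWD_PRIMER,
                          rev_primer = DEFAULT_REV_PRIMER,
                          seed = 1L, dir = NULL) {
  stopifnot(n_haplotypes <= n_specimens)
  haps <- make_haplotypes(n_haplotypes, amplicon_len, divergence, seed = seed)
  biomass <- assign_biomass(n_specimens, biomass_decades, seed = seed + 101L)
  specimens <- biomass |>
    dplyr::mutate(haplotype_id = haps$haplotype_id[(dplyr::row_number() - 1L) %% n_haplotypes + 1L])
  hap_shares <- specimens |>
    dplyr::group_by(.data$haplotype_id) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop")
  templates <- withr::with_seed(seed + 77L, haps |>
    dplyr::left_join(hap_shares, by = "haplotype_id") |>
    dplyr::transmute(template_id = .data$haplotype_id,
                     seq = paste0(concretize_iupac(fwd_primer), .data$seq,
                                  concretize_iupac(revcomp(rev_primer))),
                     share = .data$share))
  rep_ids <- paste0("rep", LETTERS[seq_len(replicates)])
  reads <- lapply(seq_len(replicates), function(r) {
    sequence_reads(templates, n_reads, model, seed = seed + 1000L * r,
                   id_prefix = rep_ids[r])
  })
  names(reads) <- rep_ids
  draws <- dplyr::bind_rows(lapply(rep_ids, function(rid) {
    reads[[rid]] |>
      dplyr::count(.data$template_id, name = "n_reads") |>
      dplyr::rename(haplotype_id = "template_id") |>
      dplyr::mutate(replicate = rid, .before = 1)
  }))
  out <- list(
    reads = reads,
    truth = list(haplotypes = haps, specimens = specimens,
                 hap_shares = hap_shares, draws = draws),
    params = list(n_specimens = n_specimens, n_haplotypes = n_haplotypes,
                  amplicon_len = amplicon_len, biomass_decades = biomass_decades,
                  divergence = divergence, n_reads = n_reads,
                  replicates = replicates, model = model,
                  fwd_primer = fwd_primer, rev_primer = rev_primer, seed = seed)
  )
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

#' Simulate a multi-species community with site-structured haplotypes
#'
#' Builds `n_otus` mutually divergent OTU centroids, gives each a small set of
#' closely related haplotypes, draws per-site haplotype frequencies from a
#' Dirichlet around each OTU's baseline, and sequences every site in
#' replicate. With `cline = TRUE` the first haplotype of the first OTU
#' follows a strictly increasing frequency gradient across the site index (a
#' latitudinal-cline analogue).
#'
#' @param n_otus Number of species-level OTUs (default 4).
#' @param haplos_per_otu Haplotypes per OTU (scalar or vector, default 3).
#' @param n_sites Number of sampling sites (default 6).
#' @param amplicon_len Amplicon length (default 178).
#' @param intra_divergence Max substitutions of a haplotype vs its OTU
#'   centroid (default 2, keeping haplotypes within ~2% of each other).
#' @param interspecific_divergence Minimum pairwise divergence between OTU
#'   centroids as a fraction (default 0.2).
#' @param cline Impose the frequency gradient (default FALSE).
#' @param depth Reads per site and replicate (default 12000).
#' @param replicates Replicates per site (default 2).
#' @param model An [error_model()].
#' @param concentration Dirichlet concentration for per-site frequency
#'   variation around the OTU baseline (default 20; smaller = more
#'   site-to-site structure).
#' @param fwd_primer,rev_primer Primers attached to templates.
#' @param seed Integer seed.
#' @param dir Optional output directory (FASTQs, manifest, truth tables).
#' @return List with `reads` (named by sample id `site01_A`, ...), `manifest`
#'   (tibble `sample_id`, `replicate_id`, `site`), `truth` (list:
#'   `haplotypes`, `site_frequencies`, `otu_weights`) and `params`.
#' @export
make_community <- function(n_otus = 4, haplos_per_otu = 3, n_sites = 6,
                           amplicon_len = 178, intra_divergence = 2,
                           interspecific_divergence = 0.2, cline = FALSE,
                           depth = 12000, replicates = 2,
                           model = error_model(), concentration = 20,
                           fwd_primer = DEFAULT_FWD_PRIMER,
                           rev_primer = DEFAULT_REV_PRIMER,
                           seed = 1L, dir = NULL) {
  stopifnot(n_otus >= 1, n_sites >= 1,
            interspecific_divergence > intra_divergence / amplicon_len)
  nh <- rep_len(haplos_per_otu, n_otus)
  haps <- withr::with_seed(seed, {
    cents <- replicate(n_otus, paste(sample(DNA_BASES, amplicon_len, replace = TRUE),
                                     collapse = ""))
    if (n_otus > 1L) {
      dv <- utils::adist(cents) / amplicon_len
      if (any(dv[upper.tri(dv)] < interspecific_divergence)) {
        abort("drawn OTU centroids are less divergent than requested; change the seed")
      }
    }
    dplyr::bind_rows(lapply(seq_len(n_otus), function(o) {
      tibble::tibble(
        otu_id = sprintf("sp%02d", o),
        haplotype_id = sprintf("sp%02d_H%02d", o, seq_len(nh[o])),
        seq = mutate_from_ancestor(cents[o], nh[o], intra_divergence)
      )
    }))
  })
  if (anyDuplicated(haps$seq)) abort("duplicate haplotype sequences across OTUs; change the seed")

  site_freq <- withr::with_seed(seed + 5000L, {
    # per-OTU baseline haplotype frequencies, then per-site Dirichlet jitter
    baselines <- lapply(seq_len(n_otus), function(o) {
      g <- rgamma(nh[o], shape = 2); g / sum(g)
    })
    otu_w <- matrix(rgamma(n_sites * n_otus, shape = 5), n_sites, n_otus)
    otu_w <- otu_w / rowSums(otu_w)
    site_freq <- dplyr::bind_rows(lapply(seq_len(n_sites), function(s) {
      dplyr::bind_rows(lapply(seq_len(n_otus), function(o) {
        f <- rgamma(nh[o], shape = concentration * baselines[[o]] * nh[o])
        f <- f / sum(f)
        if (cline && o == 1L) {
          focal <- if (n_sites > 1L) 0.1 + 0.8 * (s - 1) / (n_sites - 1) else 0.5
          if (nh[o] > 1L) {
            rest <- f[-1] / sum(f[-1]) * (1 - focal)
            f <- c(focal, rest)
          } else {
            f <- 1
          }
        }
        tibble::tibble(site = s, otu_id = sprintf("sp%02d", o),
                       haplotype_id = haps$haplotype_id[haps$otu_id == sprintf("sp%02d", o)],
                       otu_weight = otu_w[s, o], frequency = f)
      }))
    }))
  })

  templates_all <- withr::with_seed(seed + 77L, haps |>
    dplyr::mutate(template_seq = paste0(concretize_iupac(fwd_primer), .data$seq,
                                        concretize_iupac(revcomp(rev_primer)))))
  rep_ids <- LETTERS[seq_len(replicates)]
  reads <- list()
  manifest <- tibble::tibble(sample_id = character(), replicate_id = character(),
                             site = integer())
  for (s in seq_len(n_sites)) {
    sf <- site_freq |> dplyr::filter(.data$site == s)
    tpl <- templates_all |>
      dplyr::left_join(sf |> dplyr::select("haplotype_id", "otu_weight", "frequency"),
                       by = "haplotype_id") |>
      dplyr::transmute(template_id = .data$haplotype_id, seq = .data$template_seq,
                       share = .data$otu_weight * .data$frequency)
    for (r in seq_len(replicates)) {
      sid <- sprintf("site%02d_%s", s, rep_ids[r])
      reads[[sid]] <- sequence_reads(tpl, depth, model,
                                     seed = seed + 131L * s + 17L * r,
                                     id_prefix = sid)
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        sample_id = sid, replicate_id = rep_ids[r], site = s))
    }
  }
  out <- list(
    reads = reads, manifest = manifest,
    truth = list(haplotypes = haps,
                 site_frequencies = site_freq,
                 centroid_divergence_min = if (n_otus > 1L) {
                   dv <- utils::adist(haps$seq[!duplicated(haps$otu_id)]) / amplicon_len
                   min(dv[upper.tri(dv)])
                 } else NA_real_),
    params = list(n_otus = n_otus, haplos_per_otu = nh, n_sites = n_sites,
                  amplicon_len = amplicon_len, intra_divergence = intra_divergence,
                  interspecific_divergence = interspecific_divergence,
                  cline = cline, depth = depth, replicates = replicates,
                  model = model, concentration = concentration,
                  fwd_primer = fwd_primer, rev_primer = rev_primer, seed = seed)
  )
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

# Write a simulation (mock or community) to disk: FASTQ per sample, a
# manifest, and plain-text truth tables.
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- names(sim$reads)
  paths <- file.path(dir, paste0(samples, ".fastq"))
  for (i in seq_along(samples)) {
    write_fastq(sim$reads[[samples[i]]], paths[i])
  }
  manifest <- sim$manifest %||% tibble::tibble(
    sample_id = samples,
    replicate_id = sub("^rep", "", samples)
  )
  manifest$path <- paths
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  truth_haps <- sim$truth$haplotypes
  writeLines(
    paste0(">", truth_haps$haplotype_id, "\n", truth_haps$seq),
    file.path(dir, "truth_haplotypes.fasta")
  )
  for (nm in setdiff(names(sim$truth), "haplotypes")) {
    if (is.data.frame(sim$truth[[nm]])) {
      readr::write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
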