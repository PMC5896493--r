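---
title: "Haplotyping metabarcoding data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotyping metabarcoding data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotidy)
```

## The problem

DNA metabarcoding of bulk invertebrate samples amplifies a short fragment of
the mitochondrial COI gene from every individual in the sample at once. The
standard analysis collapses reads into ~97%-identity OTUs and stops at the
species level. But the reads also contain intraspecific variation: distinct
COI haplotypes carried by different individuals of the same species. That
signal is buried under PCR and sequencing errors, which generate sequence
variants at exactly the 1–3 bp distances where real haplotypes live.
`haplotidy` separates the two using the one property that distinguishes
them: error variants are rare *relative to the sequence they derive from*,
while true haplotypes are as abundant as the individuals that carry them.

## The model

### Expected-error read filtering

Each base's Phred score \(Q_i\) decodes to an error probability
\(p_i = 10^{-Q_i/10}\), and the read's expected number of errors is
\(ee = \sum_i p_i\). Reads with \(ee\) above a ceiling (default 0.5, i.e.
fewer than half an error expected per read) are discarded. The boundary is
inclusive — a read at exactly the ceiling is kept — and the comparison
carries a \(10^{-9}\) epsilon so that mathematically exact boundary cases
(say, 50 bases at Q20) are not lost to floating-point summation. Reads are
then restricted to the exact amplicon length of the primer set, which
removes most indel-bearing reads, and can be subsampled (without
replacement, seeded) to equalise depth across samples.

### Per-sample abundance prefilter

After dereplication, a sequence is kept within a sample only if it reaches
**both** an absolute floor (≥ 10 copies) and a relative floor (≥ 0.001% of
the sample's reads). Reading "discard below 10 reads or 0.001%" as
keep-requires-both is deliberate: the absolute floor controls sparse noise
at low depth, the relative floor controls it at high depth, and either alone
is vacuous in the opposite regime.

### Abundance-skew denoising

All samples are pooled (pooling raises the counts of genuine haplotypes
shared across samples, improving their odds against the skew test) and the
unique sequences are processed greedily in order of decreasing total
abundance, ties broken lexicographically. The first sequence founds a
centroid. Each subsequent sequence \(u\) is compared with the accepted
centroids; it is absorbed into centroid \(c\) as an error variant when

\[
\frac{\text{size}_u}{\text{size}_c} \le \beta(d) = \frac{1}{2^{\alpha d + 1}},
\]

where \(d \ge 1\) is the unit-cost edit distance (substitutions and
single-base indels) and \(\alpha\) controls strictness. If several centroids
qualify, the one at the smallest \(d\) wins, then the larger centroid, then
the lexicographically smaller sequence; if none qualifies, \(u\) founds a new
centroid. Absorbed sequences contribute their per-sample counts to their
centroid, which is how the haplotype × sample table acquires its counts
(no separate read-mapping pass is needed; an identity-threshold re-mapping
of all quality-filtered reads could be layered on top, but membership-based
counting is exact with respect to the denoising decisions actually taken).

Three deliberate choices fix the parts the skew criterion leaves open:

* **Static centroid sizes.** The denominator \(\text{size}_c\) is the
  centroid's own dereplicated total, not inflated by previously absorbed
  members. This makes the outcome independent of absorption bookkeeping and
  keeps the brute-force oracle (and the post-hoc audit that every member
  satisfies its skew bound) simple.
* **Single pass, no reassignment.** Later centroids never steal earlier
  assignments; the greedy order is the algorithm.
* **Deterministic tie-breaks** everywhere, so that the test suite can demand
  exact equality with an independent matrix-based re-implementation.

Lower \(\alpha\) raises \(\beta(d)\), so more candidates pass the skew test
and are merged away: low \(\alpha\) = stricter denoising, fewer centroids,
but real low-abundance haplotypes are lost; high \(\alpha\) = permissive,
more centroids, more error variants surviving. The default \(\alpha = 5\)
is the usual final-analysis setting; the relaxed validation run uses
\(\alpha = 10\) on purpose, because it asks a different question (are the
true sequences *present* among the centroids at all?).

### Chimera flagging

A centroid is flagged as chimeric when it is exactly a single-crossover
splice of two distinct, same-length centroids that are each at least twice
as abundant. This is a conservative, exact-match model of de novo chimera
detection — it will miss chimeras whose parents were themselves denoised
away, and it is switchable off — but it is deterministic and auditable, and
at the abundance ratios where chimeras matter the exact test is the one
that fires. Flagged centroids are excluded from tables; their reads stay in
the stage accounting.

### OTU clustering and the threshold cascade

Haplotypes are clustered greedily at 97% identity
(\(1 - d/\max(\mathrm{len})\)), most abundant first, each joining the first
OTU whose centroid is close enough. The haplotype table is then filtered in
a fixed order:

1. drop haplotypes that never reach `minhaplosize` (default 0.01%) of any
   sample's reads;
2. drop OTUs that never reach `otumin` (default 0.1%) of any sample's reads;
3. within each OTU and sample, zero haplotypes below `within_otu` (default
   5%) of that OTU's reads in that sample;
4. drop rows with no counts left;
5. optionally require presence in a minimum number of samples (defaults 1 =
   off, appropriate for small site sets).

All boundaries are inclusive on the keep side ("less than X" is what gets
discarded). One subtlety: a single pass of this cascade is not quite
idempotent — step 3 can zero the very cell that justified a row's survival
of step 1, so a second application could still remove rows. The cascade is
therefore iterated to a fixed point (counts only ever decrease, so this
terminates, almost always after one extra pass). The exported table is thus
self-consistent under its own thresholds, re-filtering is a no-op, and
raising any threshold can only remove haplotypes or zero counts.

The 5% within-OTU rule is the workhorse: haplotypes below it cannot be
separated reliably from PCR/sequencing artifacts, so the method knowingly
sacrifices rare haplotypes (and with them, the haplotypes of small-biomass
specimens) for specificity. The worked mock example in the README shows the
effect directly: 15/15 true haplotypes among the centroids, 10/15 left in
the filtered table.

### Downstream statistics

* **Haplotypes per OTU**: mean and sample SD of per-OTU haplotype counts; a
  single-OTU table reports SD 0 with a degeneracy flag.
* **Haplotype networks**: per OTU, the complete pairwise edit-distance graph
  reduced to a minimum spanning tree (Kruskal), with ties broken first
  toward edges touching the most abundant haplotype, then by lexicographic
  id pair. A single MST was chosen over a multi-tree minimum-spanning
  network: at COI amplicon scale ties are rare, trees are what the
  visualisations need, and determinism makes the brute-force optimality
  oracle testable.
* **Replicate consistency**: per OTU, the per-(haplotype, site) relative
  abundances of two replicates are paired (union of haplotypes, absent = 0)
  and replicate B is regressed on A by OLS; adjusted R² is computed directly
  from the residual and total sums of squares (a perfect fit is exactly 1),
  and OTUs with fewer than 3 informative pairs or zero variance are
  excluded and reported. Relative abundances (not raw counts) are the
  default because replicates rarely share depth; `raw_counts = TRUE`
  switches.
* **Truth-set classification**: haplotypes at or above a relative-abundance
  floor (per sample, against that sample's total) are split into expected
  (exact sequence match) and unexpected, with missed truth sequences and
  per-sample concordance reported.

## The simulator

`simulate_mock()` emulates a single-species mock community: 31 specimens
carrying 15 distinct 178-bp haplotypes (defaults), specimen biomass
log-uniform across three orders of magnitude with read share proportional
to biomass, two independently seeded replicates. `make_community()` emulates
a multi-species monitoring design: mutually divergent OTU centroids, each
with a few close haplotypes, per-site frequencies drawn from a Dirichlet
around each OTU's baseline, optionally with one haplotype on a strict
monotone frequency gradient across sites (a latitudinal-cline analogue).

Design choices worth knowing:

* **Haplotype construction.** Each haplotype mutates its own disjoint set of
  2–4 ancestor positions. Pairwise distances are therefore ≥ 2, which is
  what makes the noiseless-limit guarantee attainable: under proportional
  biomass shares the abundance ratio between any two true haplotypes stays
  far above \(\beta(2)\) at the default \(\alpha\), so no true haplotype can
  absorb another. Real mocks are harsher — true haplotypes at \(d = 1\) from
  a much more abundant one are genuinely indistinguishable from errors by
  skew alone, and that failure mode is exactly why recovery in real mock
  experiments is partial. The simulator makes it a controllable choice
  (`divergence = 1` re-creates it) rather than a permanent property.
* **Error model.** Substitutions at 0.002/base (binomial per read, positions
  weighted by each base's Phred-implied error probability, so errors land
  where the qualities say they should), indels at 2×10⁻⁴/base, chimeras at
  1% of reads spliced from two share-weighted templates at a uniform
  crossover, Phred means 35 at the 5' end declining by 5 toward the 3' end
  (SD 3). These rates make error haplotypes clearly visible at mock depth
  yet controllable; all are exposed.
* **What is not modelled**: PCR efficiency bias between templates, tag
  switching, numts/heteroplasmy, platform-specific error motifs. Passing
  recovery tests on simulated data therefore demonstrates the algorithmic
  contract (errors that follow the skew model are removed; abundant truth
  survives), not robustness to every artifact class in real libraries.
* **Determinism.** Every stochastic step runs under a seed derived from the
  single user seed; identical calls produce byte-identical FASTQ files.

## Problem sizes and numerical choices

The validation suite runs the mock design at 200,000 reads per replicate
(the design's 1M-read depth adds nothing to the recovery question at 15
haplotypes over three biomass decades; the rarest haplotype already carries
thousands of reads at 200k), the noiseless-limit check at 60,000 reads, and
the replicate-consistency check at 4 OTUs × 6 sites × 12,000 reads × 2
replicates. The denoiser skips centroid comparisons that cannot qualify at
any distance (`size_u/size_c > β(1)`), which is exact — β is strictly
decreasing in d — and reduces the dominant cost to edit distances against a
handful of large centroids. Edit distances are computed with `utils::adist`
(C implementation); `d = 0` can never arise inside denoising because
dereplication has already merged identical sequences, and `skew_threshold`
refuses `d < 1` outright.

## Known limitations

* Abundance-skew denoising cannot rescue a true haplotype whose abundance
  ratio to a 1-bp neighbour falls below \(\beta(1)\); with biomass spanning
  three decades this *will* happen in real data, and the affected haplotypes
  are lost silently.
* The within-OTU 5% rule removes genuinely rare haplotypes; per-site
  haplotype richness is therefore a floor, not an estimate.
* The chimera model only detects exact single-crossover splices of surviving
  centroids.
* Greedy 97% clustering can split a species whose haplotypes straddle the
  identity radius (visible in the mock example: 15 single-species haplotypes
  land in 6 OTUs when maximal intra-mock divergence exceeds 3%); OTU-level
  counts are conservative in that direction.
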