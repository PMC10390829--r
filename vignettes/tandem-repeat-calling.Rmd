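---
title: "Calling tandem-repeat alleles from spanning reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tandem-repeat alleles from spanning reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemcall)
```

## The model

`tandemcall` treats tandem-repeat genotyping as an *evidence counting*
problem rather than an inference problem. The unit of evidence is a
**spanning read**: an alignment whose reference span contains the whole
repeat tract plus a few flanking bases. Each spanning read contributes
exactly one candidate allele sequence — the bases aligned inside the tract —
and alleles are the haplotype sequences supported by enough independent
reads. Nothing is ever inferred about an allele that no read spans in full;
a read carrying only part of a tract is skipped and tallied in the locus QC.

This design rests on three assumptions:

* the alignment is trustworthy at the *span* level (the aligner placed the
  read at the right locus, even if gap placement inside the repeat is
  arbitrary);
* sequencing errors are rare enough that the true allele is the
  *exact-sequence mode* of the spanning reads;
* true alleles fit inside single reads. Alleles longer than the read length
  minus twice the flank are structurally invisible (they drop out), which is
  a property we test rather than hide.

Haplotype classification is **exact string identity** of the extracted
tract. Two same-length alleles that differ by an internal SNP are distinct
haplotypes; no error-tolerant clustering is attempted. A fuzzier grouping
would trade precision (the strong suit of evidence-based calling) for
sensitivity on noisy reads, and would need a stutter-and-error model that
the counting design deliberately avoids.

## Boundary projection

The repeat tract `[start, end)` (0-based half-open, BED convention,
covering the tract only — no flanks) is projected into each read by a
single left-to-right walk over the CIGAR:

* match/mismatch ops map positions linearly;
* an **insertion** is assigned by its reference anchor: strictly inside the
  tract → part of the allele (this is how expansions longer than the
  reference appear); anchored exactly at `start` or `end` → part of the
  flank, excluded. Without this rule an expansion at the tract edge would be
  attributed ambiguously;
* a **deletion** covering a boundary snaps that boundary to the nearest
  aligned base inside the tract, so contractions shorten the extracted
  allele instead of invalidating the read;
* a boundary that falls in a soft clip or outside the aligned span is a
  spanning failure: the read is skipped, never an error.

The walk is checked, over thousands of random CIGARs, against an
independent per-base alignment-column oracle in the test suite. Degenerate
outcomes are defined, not special-cased: a tract entirely deleted in a read
projects to an empty string, which then simply fails motif validation and
is tallied as invalid.

## Filters and their order

| parameter | default | unit | role |
|---|---|---|---|
| `flank` | 5 | bp | span requirement on each side of the tract |
| `min_mapq` | 1 | – | drops unplaced/multi-placed alignments |
| `min_coverage` | 2 | reads | minimum support per called allele (use ~10 for deep amplicon data) |
| `min_proportion` | 0.10 | fraction | minimum share of classified reads at the locus |
| `stutter_ratio` | 0.25 | fraction | stutter count-ratio threshold (per-locus override in the BED) |
| `donors` | 1 | – | contributor count *d*; cap = ploidy × *d* |

Filters apply in a fixed order — coverage, proportion, stutter, cap — and
each haplotype records the *first* filter it failed, so the unfiltered
report explains every exclusion unambiguously. The order matters only for
that attribution: the called set would be identical under any order because
the first two filters are per-haplotype thresholds and the last two only
remove haplotypes that later stages would also reject.

Choices made where reasonable alternatives existed:

* **Proportion denominator** is the classified (motif-valid, spanning)
  reads at the locus, not all fetched reads, so junk alignments cannot
  dilute a real allele below threshold.
* **Stutter is one-sided**: a candidate exactly one motif unit *shorter*
  than a kept haplotype, below `stutter_ratio` times its count. Contraction
  slippage dominates PCR stutter; a two-sided rule would risk deleting real
  short alleles in unbalanced heterozygotes. Candidates are evaluated in
  descending count order so a haplotype already classified as stutter
  cannot shelter a further stutter. In mixture mode (`donors > 1`) the
  filter is disabled entirely — a minor contributor's allele is
  indistinguishable from stutter by count ratio alone. Setting the ratio to
  0 disables it for PCR-free libraries.
* **Proportion applies in mixture mode** at the same default; with the
  10% default this bounds detectable contributors at roughly 1:9, which the
  user can relax explicitly.
* **Cap tie-breaks** are deterministic: higher count, then shorter allele,
  then lexicographic sequence. Identical inputs give byte-identical output.
* Reads are consumed in reference orientation as stored in the BAM; motif
  validation is forward-only, which is consistent because the BED motif is
  also given in reference orientation.

The length-based designation divides the offset-corrected allele length by
the motif length: integer part = complete repeats, remainder = the
fractional label (allele `3.1` = 3 repeats + 1 bp). The internal offset is
the number of bases inside the interval that the forensic nomenclature
excludes from counting. The conversion is exactly invertible given the
locus definition, and the package asserts that invertibility on every
called allele.

## The simulator and what it emulates

The built-in generator exists so that every stage — projection, filters,
mixtures, stutter, depth titration — is testable from a cold start with no
downloads. Its fixed study conditions are:

* **Panel**: 20 loci, one per ~1.5 kb synthetic contig, tract centred;
  motifs mostly 4 bp with some 3 bp and 5 bp units; 6–12 reference repeats
  (24–48 bp tracts, all spannable by 150 bp reads with the 5 bp flanks);
  some loci carry 2–6 bp internal offsets; all diploid.
* **Genotypes**: per donor haplotype, repeat edits of −2…+3 units inserted
  one motif into the tract (strictly inside, so boundary conventions are
  exercised), plus an optional SNP inside the repeat region (probability
  0.25). Donor weights sum to 1.
* **Reads**: `pe150`/`pe250` paired-end with Gaussian fragment lengths
  (450 ± 50, 700 ± 70 bp) and independent substitution errors at 0.001 —
  representative of modern short-read chemistry after QC; `long_ccs` reads
  of ~1 kb (scaled to the contigs) with mixed substitution/indel errors at
  1:1 totalling 0.05, i.e. 95% base accuracy consensus long reads.
  `mean_depth` is the *total sample* depth over locus positions; a diploid
  donor's haplotypes each receive half. Realized mid-locus depth is held
  within ~10% of the request (tested at 50x).
* **Alignment**: read positions and CIGARs are constructed from the known
  simulation coordinates ("truth alignment"), composing each haplotype's
  known indel events with any injected error indels. This isolates the
  caller from aligner idiosyncrasies; a FASTQ export exists for optional
  end-to-end runs through a real aligner.
* Everything is seeded and byte-reproducible.

What it deliberately does **not** emulate: aligner-specific gap placement
and soft-clipping habits, PCR stutter chemistry (a one-motif-loss stutter
*read injector* is provided as a fixture utility instead), coverage bias,
base-quality structure, and real flanking-sequence homology. Passing the
simulation suite therefore demonstrates the algorithm's correctness under
idealised alignment, not robustness to a hostile aligner; on real data the
dominant additional failure mode is mis-mapping, which the `min_mapq` gate
only partially addresses.

## Sensitivity, and the statistics of low depth

`sensitivity_experiment()` runs the depth-titration design: fresh diploid
genotypes per replicate, reads per (mode, depth), default-configuration
calling, scored as **allele recall** (correctly called alleles / expected
alleles) and **locus dropout** (loci whose called set differs from truth).
The test suite runs 100 replicates of the 20-locus panel at the
informative depths rather than the full 3 × 13 grid; the full grid is
available from `tandemcall-simulate`.

Two statistical facts shape the results and are worth stating plainly,
because they bound what *any* exact-match spanning-read caller can do:

* **Spanning coverage is thinned Poisson.** A diploid allele at total depth
  *D* is covered by about *D*/2 reads, of which only those starting in a
  window of `read_length − tract − 2·flank` positions span the tract. At
  25x PE150 a 30–50 bp tract receives ~8–9 spanning reads per allele, and
  with `min_coverage = 2` the Poisson tail puts per-allele dropout at
  ~0.1–0.5%: measured mean recall is ≈ 99.5–99.8%. At 10x PE250 (~4 reads
  per allele) recall is ≈ 90%.
* **Exact matching taxes long reads at high error.** At 95% accuracy the
  probability that a read crosses a 24–48 bp tract without a single error
  is only 0.95^L ≈ 0.09–0.29, so at 5x total depth the expected number of
  *error-free* spanning reads per allele is well below 1 and measured
  recall is ~9%. High-accuracy long reads do excel — noise-free long reads
  recover every allele at modest depth, and they are the only reads that
  can call tracts longer than short reads (tested as a structural
  property) — but at 5% error the exact-haplotype model needs depth,
  roughly 2/(0.95^L) error-free-read expectation per allele, to call
  reliably.

Precision behaves differently: error haplotypes are overwhelmingly
singletons, so the coverage and cap filters remove them and measured
precision is 100% at 30x and above across all replicates. Recall is
depth-limited; precision is filter-protected.

## Known limitations

* No inference of alleles longer than the read length (by design; use
  assembly- or graph-based tools for megasatellite expansions beyond the
  read length).
* No realignment and no probabilistic stutter model; heavily stuttered
  amplicon data may need the per-locus `stutter_ratio` raised, or
  `min_coverage` of ~10 as is conventional for deep targeted data.
* Exact-identity classification makes recall at low depth sensitive to the
  per-base error rate (quantified above).
* The locus interval must be the repeat tract itself; panels whose BED
  intervals include flanking bases should shrink them (the internal offset
  mechanism is for non-repeat bases *inside* the tract, not for flanks).
* `--threads` is accepted for interface compatibility; calling is currently
  sequential, and results are independent of locus order by construction.
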