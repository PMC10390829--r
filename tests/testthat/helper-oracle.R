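# Independent per-base alignment-column oracle for interval projection.
# Expands the CIGAR into one row per query base, recording for aligned bases
# their reference position and for inserted bases the reference anchor (the
# position of the next aligned base). The projected query interval is the
# union of aligned bases with ref in [lo, hi) and inserted bases whose
# anchor lies strictly inside (lo, hi).
oracle_project <- function(cigar, pos, lo, hi) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qtype <- character(0) # "A" aligned, "I" inserted, "S" clipped
  qref <- integer(0)
  rpos <- pos
  for (j in seq_along(ops)) {
    op <- ops[j]
    len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      qtype <- c(qtype, rep("A", len))
      qref <- c(qref, rpos + seq_len(len) - 1L)
      rpos <- rpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op == "I") {
      qtype <- c(qtype, rep("I", len))
      qref <- c(qref, rep(rpos, len)) # anchor = next aligned ref position
    } else if (op == "S") {
      qtype <- c(qtype, rep("S", len))
      qref <- c(qref, rep(NA_integer_, len))
    }
  }
  ref_span <- range(qref[qtype == "A"])
  if (lo < pos || hi > rpos) {
    return(c(NA_integer_, NA_integer_))
  }
  take <- (qtype == "A" & qref >= lo & qref < hi) |
    (qtype == "I" & qref > lo & qref < hi)
  if (!any(take)) {
    # interval fully deleted in this read: empty segment at the snap point
    after <- which(qtype == "A" & qref >= lo)
    q <- if (length(after)) min(after) - 1L else length(qtype)
    return(c(q, q))
  }
  c(min(which(take)) - 1L, max(which(take)))
}

# Random valid CIGAR for property tests: optional soft clips, M runs
# interleaved with I/D/N, always starting and ending the aligned region
# with M, never two gap ops adjacent.
random_cigar <- function(min_m = 5L, max_m = 60L, n_segments = NULL) {
  if (is.null(n_segments)) n_segments <- sample(1:5, 1)
  ops <- character(0)
  lens <- integer(0)
  if (runif(1) < 0.3) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:20, 1))
  }
  for (k in seq_len(n_segments)) {
    ops <- c(ops, "M")
    lens <- c(lens, sample(min_m:max_m, 1))
    if (k < n_segments) {
      ops <- c(ops, sample(c("I", "D", "N"), 1, prob = c(0.45, 0.45, 0.1)))
      lens <- c(lens, sample(1:12, 1))
    }
  }
  if (runif(1) < 0.3) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:20, 1))
  }
  paste0(lens, ops, collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One-row read tibble compatible with fetch_spanning_reads()/project_interval()
make_read <- function(cigar, pos, chrom = "ctg01", qname = "r1",
                      flag = 0L, mapq = 60L, seq = NULL) {
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  if (is.null(seq)) seq <- random_seq(qlen)
  tibble::tibble(
    qname = qname, flag = flag, chrom = chrom, pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = cigar, seq = seq
  )
}

# Single-row locus helper
make_locus <- function(chrom = "ctg01", start, end, name = "LOC",
                       motif = "ACGT", internal_offset = 0L,
                       stutter_ratio = NA_real_, ploidy = 2L) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, motif = motif, motif_length = nchar(motif),
    internal_offset = as.integer(internal_offset),
    stutter_ratio = stutter_ratio, ploidy = as.integer(ploidy)
  )
}

# Brute-force span predicate over an in-memory read table: the oracle that
# the indexed fetch must reproduce.
brute_force_spanning <- function(reads, locus, flank = 5L, min_mapq = 1L) {
  bad <- bitwAnd(reads$flag, 0x4L + 0x100L + 0x200L + 0x400L + 0x800L) != 0L
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  keep <- !bad & reads$chrom == locus$chrom &
    reads$pos <= locus$start - flank &
    reads$pos + w >= locus$end + flank &
    reads$mapq >= min_mapq
  reads[keep, ]
}

empty_read_table <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), chrom = character(),
    pos = integer(), mapq = integer(), cigar = character(), seq = character()
  )
}

# Small seeded end-to-end fixture shared by several test files
demo_world <- function(seed = 11L, n_loci = 6L, n_donors = 1L,
                       mode = "pe250", depth = 60, error_rate = 0) {
  panel <- simulate_panel(n_loci = n_loci, seed = seed)
  geno <- simulate_genotypes(panel$loci, n_donors = n_donors, seed = seed + 1L)
  genomes <- build_truth_genomes(panel$reference, panel$loci, geno)
  reads <- simulate_reads(genomes, mode, depth, error_rate = error_rate,
                          seed = seed + 2L)
  list(panel = panel, geno = geno, genomes = genomes, reads = reads)
}
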