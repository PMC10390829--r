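#' Fetch reads fully spanning a target locus
#'
#' Retrieves, through the BAM index, the primary, non-duplicate,
#' non-supplementary, QC-pass reads whose aligned reference span contains
#' `[locus$start - flank, locus$end + flank)` and whose mapping quality is at
#' least `min_mapq`. Only such spanning reads carry complete evidence for a
#' repeat allele; a read covering the tract partially is never used.
#'
#' Also accepts an in-memory read tibble in place of a BAM path, in which
#' case the same span and mapping-quality predicates are applied directly
#' (flag-based exclusion uses the `flag` column).
#'
#' @param alignment Path to a coordinate-sorted BAM with a `.bai` index, or a
#'   read tibble (columns `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`,
#'   `seq`; `pos` 0-based).
#' @param locus Single-row target tibble.
#' @param flank Required flanking bases covered on each side of the tract.
#' @param min_mapq Minimum mapping quality.
#' @return A read tibble (0-based `pos`), one row per spanning read.
#' @export
fetch_spanning_reads <- function(alignment, locus, flank = 5L, min_mapq = 1L) {
  UseMethod("fetch_spanning_reads")
}

#' @export
fetch_spanning_reads.character <- function(alignment, locus, flank = 5L, min_mapq = 1L) {
  stopifnot(nrow(locus) == 1L, flank >= 0)
  if (!file.exists(alignment)) {
    stop("alignment file not found: ", alignment, call. = FALSE)
  }
  bai <- paste0(alignment, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", alignment))) {
    stop(
      "no index (.bai) found for ", alignment,
      "; run sort_and_index() first", call. = FALSE
    )
  }
  bf <- Rsamtools::BamFile(alignment)
  header_seqs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!(locus$chrom %in% header_seqs)) {
    warning("sequence '", locus$chrom, "' absent from alignment header; locus ",
            locus$name, " yields no reads", call. = FALSE)
    return(empty_reads())
  }
  lo <- locus$start - flank
  hi <- locus$end + flank
  which <- GenomicRanges::GRanges(
    locus$chrom, IRanges::IRanges(start = max(lo, 0L) + 1L, end = hi)
  )
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
      isNotPassingQualityControls = FALSE
    )
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  if (length(res$pos) == 0L) {
    return(empty_reads())
  }
  reads <- tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq)
  )
  span_filter(reads, locus, flank, min_mapq)
}

#' @export
fetch_spanning_reads.data.frame <- function(alignment, locus, flank = 5L, min_mapq = 1L) {
  stopifnot(nrow(locus) == 1L, flank >= 0)
  # exclude unmapped (0x4), secondary (0x100), QC-fail (0x200),
  # duplicate (0x400), supplementary (0x800)
  bad <- bitwAnd(alignment$flag, 0x4L + 0x100L + 0x200L + 0x400L + 0x800L) != 0L
  span_filter(alignment[!bad, , drop = FALSE], locus, flank, min_mapq)
}

span_filter <- function(reads, locus, flank, min_mapq) {
  if (nrow(reads) == 0L) {
    return(empty_reads())
  }
  lo <- locus$start - flank
  hi <- locus$end + flank
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  keep <- reads$chrom == locus$chrom &
    reads$pos <= lo & reads$pos + ref_w >= hi &
    reads$mapq >= min_mapq
  as_tibble(reads[keep, c("qname", "flag", "chrom", "pos", "mapq", "cigar", "seq")])
}

empty_reads <- function() {
  tibble(
    qname = character(), flag = integer(), chrom = character(),
    pos = integer(), mapq = integer(), cigar = character(), seq = character()
  )
}

#' Sort and index an alignment file
#'
#' Preprocessing utility: coordinate-sorts a BAM (or converts and sorts a
#' SAM) and writes a companion `.bai` index. Idempotent on already-sorted
#' input.
#'
#' @param in_path Input SAM/BAM path.
#' @param out_path Output BAM path (default: input with `.sorted.bam`).
#' @return The sorted BAM path, invisibly.
#' @export
sort_and_index <- function(in_path, out_path = NULL) {
  if (!file.exists(in_path)) {
    stop("alignment file not found: ", in_path, call. = FALSE)
  }
  if (grepl("\\.sam$", in_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(in_path, sub("\\.sam$", "", in_path, ignore.case = TRUE),
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- in_path
  }
  if (is.null(out_path)) {
    out_path <- sub("\\.bam$", ".sorted.bam", bam, ignore.case = TRUE)
  }
  dest <- sub("\\.bam$", "", out_path, ignore.case = TRUE)
  sorted <- Rsamtools::sortBam(bam, dest)
  Rsamtools::indexBam(sorted)
  invisible(sorted)
}

#' Reduce an alignment to the reads overlapping target loci
#'
#' Writes a BAM containing exactly one copy of every read that overlaps any
#' target locus (plus flank); loci that share reads do not duplicate
#' records. Calling on the reduced file gives identical results to calling
#' on the original, because every spanning read is retained.
#'
#' @param alignment Indexed BAM path.
#' @param loci Target tibble.
#' @param flank Flank in bp retained around each locus.
#' @param out_path Output BAM path.
#' @return The output BAM path (sorted and indexed), invisibly.
#' @export
reduce_to_targets <- function(alignment, loci, flank = 5L, out_path) {
  stopifnot(file.exists(alignment), nrow(loci) >= 0)
  gr <- GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(start = pmax(loci$start - flank, 0L) + 1L,
                     end = loci$end + flank)
  )
  gr <- GenomicRanges::reduce(gr) # merge overlaps so no read is emitted twice
  header_seqs <- names(Rsamtools::scanBamHeader(Rsamtools::BamFile(alignment))$targets)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% header_seqs]
  if (length(gr) == 0L) {
    # nothing on any known contig: emit a header-only BAM
    dest <- Rsamtools::filterBam(
      Rsamtools::BamFile(alignment), destination = out_path,
      filter = S4Vectors::FilterRules(list(none = function(x) {
        rep(FALSE, nrow(x))
      })),
      param = Rsamtools::ScanBamParam(what = "qname"),
      indexDestination = TRUE
    )
    return(invisible(dest))
  }
  param <- Rsamtools::ScanBamParam(which = gr, what = character())
  dest <- Rsamtools::filterBam(
    Rsamtools::BamFile(alignment), destination = out_path, param = param,
    indexDestination = TRUE
  )
  invisible(dest)
}
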