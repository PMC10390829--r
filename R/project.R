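#' Project a reference interval onto read coordinates
#'
#' Walks each read's CIGAR once, left to right, to find the 0-based half-open
#' query (read) coordinates of the segment aligned to the reference interval
#' `[ref_start, ref_end)`. This is the boundary-determination step of the
#' caller: the repeat tract defined in the target BED is located inside every
#' spanning read before extraction.
#'
#' Conventions, applied deterministically:
#' * insertions whose reference anchor lies strictly inside the interval are
#'   included in the projected segment; insertions anchored exactly at
#'   `ref_start` or `ref_end` belong to the flanks and are excluded;
#' * a deletion (or reference skip) covering a boundary shifts that boundary
#'   to the nearest aligned base inside the interval;
#' * if either boundary falls outside the aligned reference span (including
#'   into a soft clip), the read does not span the interval and both query
#'   coordinates are returned as `NA`.
#'
#' @param reads A tibble of aligned reads with columns `pos` (0-based leftmost
#'   aligned reference position), `cigar` and `seq`, as returned by
#'   [fetch_spanning_reads()].
#' @param ref_start,ref_end 0-based half-open reference interval to project.
#' @return `reads` with integer columns `query_start` and `query_end` added
#'   (both `NA` on spanning failure).
#' @export
project_interval <- function(reads, ref_start, ref_end) {
  stopifnot(is.data.frame(reads), ref_end > ref_start)
  n <- nrow(reads)
  qs <- rep(NA_integer_, n)
  qe <- rep(NA_integer_, n)
  if (n == 0L) {
    return(mutate(reads, query_start = qs, query_end = qe))
  }

  check_cigar_lengths(reads$cigar, reads$seq, reads$qname)

  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  spans <- reads$pos <= ref_start & reads$pos + ref_w >= ref_end

  # fast path: pure-match alignments need only offset arithmetic
  pure <- spans & grepl("^[0-9]+M$", reads$cigar)
  qs[pure] <- as.integer(ref_start - reads$pos[pure])
  qe[pure] <- as.integer(ref_end - reads$pos[pure])

  todo <- which(spans & !pure)
  if (length(todo) > 0L) {
    ops_l <- GenomicAlignments::explodeCigarOps(reads$cigar[todo])
    len_l <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[todo])
    for (k in seq_along(todo)) {
      i <- todo[k]
      res <- walk_cigar(ops_l[[k]], len_l[[k]], reads$pos[i], ref_start, ref_end)
      qs[i] <- res[1]
      qe[i] <- res[2]
    }
  }
  mutate(reads, query_start = qs, query_end = qe)
}

# Single-pass CIGAR walk; returns c(query_start, query_end), 0-based half-open.
walk_cigar <- function(ops, lens, pos, lo, hi) {
  qpos <- 0L
  rpos <- pos
  qstart <- NA_integer_
  qend <- NA_integer_
  last <- hi - 1L
  for (j in seq_along(ops)) {
    op <- ops[j]
    len <- lens[j]
    if (op == "M" || op == "=" || op == "X") {
      if (is.na(qstart) && lo >= rpos && lo < rpos + len) {
        qstart <- qpos + (lo - rpos)
      }
      if (is.na(qend) && last >= rpos && last < rpos + len) {
        qend <- qpos + (last - rpos) + 1L
      }
      qpos <- qpos + len
      rpos <- rpos + len
    } else if (op == "D" || op == "N") {
      if (is.na(qstart) && lo >= rpos && lo < rpos + len) {
        qstart <- qpos # snap right, to the first aligned base inside
      }
      if (is.na(qend) && last >= rpos && last < rpos + len) {
        qend <- qpos # snap left: segment ends before the deleted run
      }
      rpos <- rpos + len
    } else if (op == "I" || op == "S") {
      # insertions between qstart and qend are included by construction;
      # an insertion anchored at lo precedes qstart, one anchored at hi
      # follows qend, so both are excluded without special cases
      qpos <- qpos + len
    }
    # H and P consume neither query nor reference
  }
  if (is.na(qstart) || is.na(qend)) {
    return(c(NA_integer_, NA_integer_))
  }
  c(as.integer(qstart), as.integer(max(qstart, qend)))
}

check_cigar_lengths <- function(cigar, seq, qname) {
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar) # soft clips count
  bad <- which(qw != nchar(seq))
  if (length(bad) > 0L) {
    stop(
      "CIGAR query length disagrees with sequence length for read(s): ",
      paste(head(qname[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Extract the repeat tract sequence from spanning reads
#'
#' Projects the locus interval into each read with [project_interval()] and
#' trims away all bases outside the projected boundaries. Reads in which the
#' tract is not fully contained (boundary in a clip or outside the aligned
#' span) are skipped, never an error: they receive an `NA` tract and the
#' reason is tallied by [call_locus()].
#'
#' @param reads Read tibble (see [fetch_spanning_reads()]).
#' @param locus A single-row target tibble (one locus).
#' @return `reads` with columns `tr_seq` (extracted tract, `NA` when skipped)
#'   and `skip_reason` (`NA` or `"incomplete_span"`).
#' @export
extract_tr_sequence <- function(reads, locus) {
  stopifnot(is.data.frame(locus), nrow(locus) == 1L)
  out <- project_interval(reads, locus$start, locus$end)
  out$tr_seq <- ifelse(
    is.na(out$query_start), NA_character_,
    substr(out$seq, out$query_start + 1L, out$query_end)
  )
  out$skip_reason <- ifelse(is.na(out$tr_seq), "incomplete_span", NA_character_)
  out
}
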