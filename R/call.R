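#' Caller configuration
#'
#' Bundles the run-level thresholds of the allele caller. Defaults follow
#' common practice for ~30x whole-genome data: a haplotype needs at least 2
#' supporting reads and at least 10% of the classified reads at its locus,
#' PCR stutter is filtered at a 0.25 count ratio for single-source samples,
#' and reads must span the locus plus a 5 bp flank on each side.
#'
#' @param min_coverage Minimum supporting reads for a called allele.
#' @param min_proportion Minimum fraction of classified reads at the locus.
#' @param donors Number of DNA contributors `d`; at most `ploidy * donors`
#'   alleles are called per locus. `donors > 1` switches on mixture mode,
#'   in which the stutter filter is disabled.
#' @param default_stutter_ratio Stutter count-ratio threshold used when a
#'   locus does not define its own; 0 disables stutter filtering.
#' @param flank Flanking bases on each side of the locus that a read's
#'   aligned span must cover to count as spanning.
#' @param min_mapq Minimum mapping quality for a read to be used.
#' @return A list of class `tr_config`.
#' @export
caller_config <- function(min_coverage = 2L, min_proportion = 0.10, donors = 1L,
                          default_stutter_ratio = 0.25, flank = 5L, min_mapq = 1L) {
  stopifnot(
    min_coverage >= 1, min_proportion >= 0, min_proportion <= 1,
    donors >= 1, default_stutter_ratio >= 0, default_stutter_ratio <= 1,
    flank >= 0, min_mapq >= 0
  )
  structure(
    list(
      min_coverage = as.integer(min_coverage),
      min_proportion = as.numeric(min_proportion),
      donors = as.integer(donors),
      default_stutter_ratio = as.numeric(default_stutter_ratio),
      flank = as.integer(flank),
      min_mapq = as.integer(min_mapq),
      mixture_mode = donors > 1
    ),
    class = "tr_config"
  )
}

#' @export
print.tr_config <- function(x, ...) {
  cat("<tr_config>\n")
  for (nm in setdiff(names(x), "mixture_mode")) {
    cat(sprintf("  %-21s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-21s %s\n", "mixture_mode", x$mixture_mode))
  invisible(x)
}

#' Does an extracted sequence contain the repeat motif?
#'
#' Allele validation: an extracted tract is only admitted to haplotype
#' classification if the locus motif occurs in it as an exact substring
#' (case-insensitive, reference orientation).
#'
#' @param sequence Character vector of extracted tract sequences.
#' @param motif Repeat motif (scalar).
#' @return Logical vector.
#' @examples
#' validate_motif("ATCGATCGggATCGA", "ATCG")
#' @export
validate_motif <- function(sequence, motif) {
  stopifnot(is.character(sequence), nchar(motif) >= 1)
  !is.na(sequence) & nchar(sequence) > 0 &
    stringr::str_detect(toupper(sequence), stringr::fixed(toupper(motif)))
}

#' Tally identical extracted sequences into haplotypes
#'
#' Groups motif-validated tract sequences by exact string identity; each
#' distinct sequence becomes one haplotype observation whose coverage is its
#' occurrence count and whose proportion is taken over all classified reads
#' at the locus.
#'
#' @param sequences Character vector of validated tract sequences.
#' @param locus_name Locus identifier attached to the output.
#' @return A tibble with columns `locus`, `sequence`, `read_count`,
#'   `proportion`, sorted by decreasing count then sequence; zero rows when
#'   `sequences` is empty (a no-call locus).
#' @export
classify_haplotypes <- function(sequences, locus_name) {
  sequences <- sequences[!is.na(sequences)]
  if (length(sequences) == 0L) {
    return(tibble(
      locus = character(), sequence = character(),
      read_count = integer(), proportion = double()
    ))
  }
  tab <- table(toupper(sequences))
  out <- tibble(
    locus = locus_name,
    sequence = names(tab),
    read_count = as.integer(tab)
  )
  out$proportion <- out$read_count / sum(out$read_count)
  arrange(out, desc(.data$read_count), .data$sequence)
}

#' Maximum number of callable alleles at a locus
#'
#' The allele cap is the product of the locus ploidy `m` and the number of
#' DNA donors `d`: a diploid autosomal locus in a single-source sample can
#' carry at most 2 alleles, a two-donor mixture at most 4.
#'
#' @param ploidy Locus ploidy `m` (1 for X/Y loci in males, 2 for autosomes).
#' @param donors Number of contributors `d`.
#' @return `ploidy * donors` as an integer.
#' @examples
#' max_alleles(2, 1)
#' max_alleles(2, 2)
#' @export
max_alleles <- function(ploidy, donors) {
  if (any(ploidy < 1) || any(donors < 1)) {
    stop("ploidy and donors must be positive integers", call. = FALSE)
  }
  as.integer(ploidy) * as.integer(donors)
}

#' Filter PCR stutter haplotypes
#'
#' In single-source samples, a haplotype exactly one motif unit shorter than
#' a kept haplotype and supported by fewer than `stutter_ratio` times the
#' parent's reads is flagged as PCR stutter. Candidates are evaluated in
#' decreasing count order, so a haplotype already flagged as stutter cannot
#' shelter another as its parent. In mixture mode nothing is filtered: a
#' minor contributor's true allele is indistinguishable from stutter by
#' count ratio alone.
#'
#' @param observations Haplotype tibble from [classify_haplotypes()] (sorted
#'   by decreasing count).
#' @param motif_length Motif length in bp.
#' @param stutter_ratio Count-ratio threshold in `[0, 1]`; 0 disables.
#' @param mixture_mode If `TRUE`, return everything unfiltered.
#' @return `observations` with a logical column `is_stutter`.
#' @export
stutter_filter <- function(observations, motif_length, stutter_ratio,
                           mixture_mode = FALSE) {
  n <- nrow(observations)
  out <- mutate(observations, is_stutter = FALSE)
  if (n == 0L || mixture_mode || stutter_ratio <= 0) {
    return(out)
  }
  ord <- order(-observations$read_count, observations$sequence)
  len <- nchar(observations$sequence)
  cnt <- observations$read_count
  stut <- logical(n)
  for (i in ord) {
    parents <- !stut & (len - len[i] == motif_length)
    parents[i] <- FALSE
    if (any(parents & cnt[i] < stutter_ratio * cnt)) {
      stut[i] <- TRUE
    }
  }
  out$is_stutter <- stut
  out
}

#' Apply the calling filters to classified haplotypes
#'
#' Filters are applied in a fixed order -- minimum coverage, minimum
#' proportion, stutter, allele-count cap -- and every haplotype keeps the
#' status of the first filter it failed (`filtered_coverage`,
#' `filtered_proportion`, `filtered_stutter`, `filtered_cap`) or `called`.
#' The cap keeps the `max_alleles(ploidy, donors)` highest-count survivors,
#' breaking ties by shorter sequence then lexicographic order.
#'
#' @param observations Haplotype tibble from [classify_haplotypes()].
#' @param locus Single-row target tibble.
#' @param config A [caller_config()].
#' @return An allele-call tibble: every observation with columns `locus`,
#'   `sequence`, `allele_label`, `allele_length`, `read_count`, `proportion`
#'   and `status`, sorted called-first by decreasing count.
#' @export
apply_filters <- function(observations, locus, config = caller_config()) {
  stopifnot(nrow(locus) == 1L, inherits(config, "tr_config"))
  obs <- arrange(observations, desc(.data$read_count), nchar(.data$sequence), .data$sequence)
  n <- nrow(obs)
  status <- rep("called", n)

  status[obs$read_count < config$min_coverage] <- "filtered_coverage"
  fail_prop <- status == "called" & obs$proportion < config$min_proportion
  status[fail_prop] <- "filtered_proportion"

  ratio <- if (!is.na(locus$stutter_ratio)) locus$stutter_ratio else config$default_stutter_ratio
  alive <- status == "called"
  if (any(alive)) {
    st <- stutter_filter(obs[alive, , drop = FALSE], locus$motif_length,
                         ratio, config$mixture_mode)
    status[which(alive)[st$is_stutter]] <- "filtered_stutter"
  }

  cap <- max_alleles(locus$ploidy, config$donors)
  alive <- which(status == "called")
  if (length(alive) > cap) {
    status[alive[-seq_len(cap)]] <- "filtered_cap"
  }

  obs$allele_length <- nchar(obs$sequence)
  obs$allele_label <- if (n > 0L) {
    to_length_allele(obs$allele_length, locus$internal_offset, locus$motif_length)
  } else {
    character()
  }
  obs$status <- status
  select(
    obs, "locus", "sequence", "allele_label", "allele_length",
    "read_count", "proportion", "status"
  )
}

#' Convert an allele length to its length-based designation
#'
#' Forensic length-based nomenclature: after excluding the locus-internal
#' offset bases, the allele is expressed as the number of complete repeat
#' units (integer part) and any leftover bases (fractional part), joined as
#' `"I.F"`; the fractional part is omitted when zero.
#'
#' \deqn{I = \lfloor (L - o) / r \rfloor, \quad F = (L - o) \bmod r}
#'
#' where `L` is the allele length in bp, `o` the internal offset and `r` the
#' repeat (motif) length. A 15 bp allele with a 2 bp internal offset and a
#' 4 bp motif is designated `"3.1"`.
#'
#' @param allele_length Allele length(s) in bp.
#' @param internal_offset Bases excluded from repeat counting.
#' @param motif_length Repeat unit length in bp.
#' @return Character vector of designations.
#' @examples
#' to_length_allele(15, 2, 4) # "3.1"
#' to_length_allele(16, 0, 4) # "4"
#' @export
to_length_allele <- function(allele_length, internal_offset, motif_length) {
  stopifnot(all(motif_length >= 1))
  if (any(allele_length <= internal_offset)) {
    stop("allele_length must exceed internal_offset", call. = FALSE)
  }
  adj <- allele_length - internal_offset
  i <- adj %/% motif_length
  f <- adj %% motif_length
  ifelse(f == 0, sprintf("%d", i), sprintf("%d.%d", i, f))
}

#' Parse a length-based designation back to bp
#'
#' Inverse of [to_length_allele()]: reconstructs the allele length from an
#' `"I.F"` label given the locus motif length and internal offset.
#'
#' @param allele_label Character vector of `"I"` / `"I.F"` designations.
#' @param internal_offset,motif_length As in [to_length_allele()].
#' @return Integer allele lengths in bp.
#' @export
from_length_allele <- function(allele_label, internal_offset, motif_length) {
  parts <- stringr::str_split_fixed(allele_label, stringr::fixed("."), 2)
  i <- as.integer(parts[, 1])
  f <- ifelse(parts[, 2] == "", 0L, as.integer(parts[, 2]))
  as.integer(i * motif_length + f + internal_offset)
}

#' Call tandem-repeat alleles at one locus
#'
#' Runs the full per-locus pipeline: retrieve spanning reads, project the
#' tract boundaries through each CIGAR and trim, validate the motif, tally
#' identical tracts into haplotypes, apply the coverage/proportion/stutter/
#' cap filters and attach length-based designations. Deterministic: the same
#' alignment, locus and configuration give identical output.
#'
#' @param alignment Either a path to a coordinate-sorted, indexed BAM file or
#'   an in-memory read tibble (columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`) such as [simulate_reads()] produces.
#' @param locus Single-row target tibble.
#' @param config A [caller_config()].
#' @return A list of class `tr_locus_result` with elements `calls` (the
#'   allele-call tibble from [apply_filters()]) and `qc` (a one-row tibble:
#'   `locus`, `fetched`, `skipped_incomplete`, `motif_invalid`, `classified`,
#'   `called`).
#' @export
call_locus <- function(alignment, locus, config = caller_config()) {
  stopifnot(nrow(locus) == 1L)
  reads <- fetch_spanning_reads(alignment, locus, flank = config$flank,
                                min_mapq = config$min_mapq)
  fetched <- nrow(reads)
  if (fetched == 0L) {
    calls <- apply_filters(classify_haplotypes(character(), locus$name), locus, config)
    qc <- tibble(
      locus = locus$name, fetched = 0L, skipped_incomplete = 0L,
      motif_invalid = 0L, classified = 0L, called = 0L
    )
    return(structure(list(calls = calls, qc = qc), class = "tr_locus_result"))
  }
  ext <- extract_tr_sequence(reads, locus)
  skipped <- sum(!is.na(ext$skip_reason))
  tract <- ext$tr_seq[is.na(ext$skip_reason)]
  valid <- validate_motif(tract, locus$motif)
  invalid <- sum(!valid)
  obs <- classify_haplotypes(tract[valid], locus$name)
  calls <- apply_filters(obs, locus, config)
  qc <- tibble(
    locus = locus$name,
    fetched = fetched,
    skipped_incomplete = skipped,
    motif_invalid = invalid,
    classified = as.integer(sum(valid)),
    called = sum(calls$status == "called")
  )
  structure(list(calls = calls, qc = qc), class = "tr_locus_result")
}

#' Call tandem-repeat alleles over a target panel
#'
#' Applies [call_locus()] to every locus of a target panel, in panel order,
#' and collects the allele calls and per-locus QC tallies.
#'
#' @param alignment BAM path or read tibble (see [call_locus()]).
#' @param loci Target tibble from [read_targets()] or [simulate_panel()].
#' @param config A [caller_config()].
#' @return An object of class `tr_calls`: a list with `calls` (all haplotype
#'   rows with statuses), `qc` (one row per locus), `loci` and `config`.
#'   `tidy()` returns the call rows, `glance()` a one-row run summary, and
#'   `autoplot()` a per-locus allele plot.
#' @export
call_targets <- function(alignment, loci, config = caller_config()) {
  stopifnot(is.data.frame(loci))
  results <- purrr::map(seq_len(nrow(loci)), function(i) {
    call_locus(alignment, loci[i, , drop = FALSE], config)
  })
  structure(
    list(
      calls = bind_rows(purrr::map(results, "calls")),
      qc = bind_rows(purrr::map(results, "qc")),
      loci = loci,
      config = config
    ),
    class = "tr_calls"
  )
}

#' Extract only the called alleles from a result
#'
#' @param x A `tr_calls` object.
#' @return Tibble of rows with `status == "called"`.
#' @export
called_alleles <- function(x) {
  stopifnot(inherits(x, "tr_calls"))
  filter(x$calls, .data$status == "called")
}
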