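#' Simulate a synthetic target panel
#'
#' Builds a small reference (one contig per locus) with an embedded tandem
#' repeat at each contig's centre, plus the matching target table. The
#' default panel emulates a forensic-style STR panel: 20 loci, mostly 4 bp
#' motifs with a few 3 bp and 5 bp motifs, 6-12 reference repeat units
#' (24-48 bp tracts, all spannable by 150 bp reads with flanks) and a subset
#' of loci carrying a small internal offset of non-repeat bases.
#'
#' @param n_loci Number of loci (one per contig).
#' @param seed RNG seed; the same seed reproduces the panel exactly.
#' @param contig_length Length of each synthetic contig in bp.
#' @param repeat_range Integer range the reference repeat count is drawn from.
#' @return A list with `reference` (named character vector of contig
#'   sequences) and `loci` (target tibble as from [read_targets()]).
#' @export
simulate_panel <- function(n_loci = 20L, seed = 1L, contig_length = 1500L,
                           repeat_range = 6:12) {
  withr::with_seed(seed, {
    motif_lens <- rep(c(4L, 4L, 4L, 3L, 4L, 5L, 4L), length.out = n_loci)
    offsets <- rep(c(0L, 0L, 2L, 0L, 4L, 0L, 6L), length.out = n_loci)
    ref <- character(n_loci)
    rows <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      motif <- random_motif(motif_lens[i])
      k <- sample(repeat_range, 1L)
      tract <- paste0(random_dna(offsets[i]), strrep(motif, k))
      tw <- nchar(tract)
      start <- as.integer((contig_length - tw) %/% 2)
      left <- random_dna(start)
      right <- random_dna(contig_length - start - tw)
      ref[i] <- paste0(left, tract, right)
      rows[[i]] <- tibble(
        chrom = sprintf("ctg%02d", i),
        start = start, end = start + tw,
        name = sprintf("LOC%02d", i),
        motif = motif, motif_length = motif_lens[i],
        internal_offset = offsets[i],
        stutter_ratio = NA_real_, ploidy = 2L
      )
    }
    names(ref) <- sprintf("ctg%02d", seq_len(n_loci))
    list(reference = ref, loci = bind_rows(rows))
  })
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# motif with at least two distinct bases (no homopolymer units)
random_motif <- function(len) {
  repeat {
    m <- random_dna(len)
    if (length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
  }
}

#' Draw a random genotype specification for a panel
#'
#' For every donor, haplotype and locus, draws a repeat-count edit (number of
#' motif units gained or lost relative to the reference) and, with
#' probability `snp_prob`, a single substitution inside the repeat region.
#' Donor mixture weights default to equal and always sum to 1.
#'
#' @param loci Target tibble.
#' @param n_donors Number of contributors.
#' @param seed RNG seed.
#' @param delta_choices Candidate repeat-count edits.
#' @param snp_prob Per-haplotype probability of one SNP inside the tract.
#' @param weights Optional donor mixture weights (recycled/normalised).
#' @return A tibble with one row per (locus, donor, haplotype): columns
#'   `name`, `donor`, `hap`, `delta`, `snp_off` (0-based offset of the SNP
#'   within the edited repeat region, `NA` when none), `snp_base`, `weight`.
#' @export
simulate_genotypes <- function(loci, n_donors = 1L, seed = 1L,
                               delta_choices = -2:3, snp_prob = 0.25,
                               weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / n_donors, n_donors)
  stopifnot(length(weights) == n_donors)
  weights <- weights / sum(weights)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      name = loci$name, donor = seq_len(n_donors), hap = 1:2
    )
    grid <- left_join(
      grid,
      select(loci, "name", "motif_length", "internal_offset", "start", "end"),
      by = "name"
    )
    k_ref <- (grid$end - grid$start - grid$internal_offset) %/% grid$motif_length
    n <- nrow(grid)
    delta <- sample(delta_choices, n, replace = TRUE)
    delta <- pmax(delta, -(k_ref - 3L)) # keep at least 3 repeat units
    has_snp <- runif(n) < snp_prob
    rep_len <- (k_ref + delta) * grid$motif_length
    snp_off <- ifelse(has_snp, floor(runif(n) * rep_len), NA_real_)
    snp_base <- ifelse(has_snp, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                       NA_character_)
    tibble(
      name = grid$name, donor = grid$donor, hap = grid$hap,
      delta = as.integer(delta),
      snp_off = as.integer(snp_off), snp_base = snp_base,
      weight = weights[grid$donor]
    )
  })
}

#' Build donor haplotype genomes with known repeat edits
#'
#' Applies a genotype specification to the reference: repeat expansions are
#' inserted one motif unit into the repeat region (so the novel bases sit
#' strictly inside the tract), contractions delete whole motif units at the
#' same anchor, and SNPs substitute single bases inside the repeat region.
#' Outside the loci every haplotype is identical to the reference. The
#' returned truth set records, for every (locus, donor, haplotype), the exact
#' allele sequence and its length-based designation, computed with
#' [to_length_allele()].
#'
#' @param reference Named character vector of contig sequences
#'   (from [simulate_panel()]).
#' @param loci Target tibble; at most one locus per contig.
#' @param genotypes Genotype tibble from [simulate_genotypes()].
#' @return A list of class `tr_genomes`: `haplotypes` (list with `hap_id`,
#'   `donor`, `hap`, `weight`, `seqs` named character vector, `events` tibble
#'   of indel events in reference and haplotype coordinates), `truth`
#'   (tibble: `locus`, `donor`, `hap`, `allele_seq`, `allele_length`,
#'   `allele_label`, `weight`), plus `reference` and `loci`.
#' @export
build_truth_genomes <- function(reference, loci, genotypes) {
  stopifnot(all(loci$chrom %in% names(reference)))
  if (anyDuplicated(loci$chrom)) {
    stop("build_truth_genomes() expects at most one locus per contig", call. = FALSE)
  }
  haps <- vector("list", 0L)
  truth <- vector("list", 0L)
  for (d in sort(unique(genotypes$donor))) {
    for (h in 1:2) {
      spec <- filter(genotypes, .data$donor == d, .data$hap == h)
      seqs <- reference
      events <- vector("list", 0L)
      for (j in seq_len(nrow(spec))) {
        s <- spec[j, ]
        loc <- loci[loci$name == s$name, ]
        ref_seq <- reference[[loc$chrom]]
        mlen <- loc$motif_length
        # anchor one motif unit into the repeat region: strictly inside tract
        anchor <- loc$start + loc$internal_offset + mlen
        if (s$delta > 0L) {
          ins <- strrep(loc$motif, s$delta)
          new_seq <- paste0(
            substr(ref_seq, 1L, anchor),
            ins,
            substr(ref_seq, anchor + 1L, nchar(ref_seq))
          )
          events[[length(events) + 1L]] <- tibble(
            chrom = loc$chrom, type = "ins",
            ref_pos = anchor, hap_pos = anchor,
            len = s$delta * mlen
          )
        } else if (s$delta < 0L) {
          dlen <- -s$delta * mlen
          if (anchor + dlen > loc$end) stop("contraction exceeds tract", call. = FALSE)
          new_seq <- paste0(
            substr(ref_seq, 1L, anchor),
            substr(ref_seq, anchor + dlen + 1L, nchar(ref_seq))
          )
          events[[length(events) + 1L]] <- tibble(
            chrom = loc$chrom, type = "del",
            ref_pos = anchor, hap_pos = anchor,
            len = dlen
          )
        } else {
          new_seq <- ref_seq
        }
        tract_len <- (loc$end - loc$start) + s$delta * mlen
        if (!is.na(s$snp_off)) {
          p <- loc$start + loc$internal_offset + s$snp_off # 0-based in haplotype
          base <- substr(new_seq, p + 1L, p + 1L)
          alt <- s$snp_base
          if (alt == base) alt <- setdiff(c("A", "C", "G", "T"), base)[1L]
          substr(new_seq, p + 1L, p + 1L) <- alt
        }
        seqs[[loc$chrom]] <- new_seq
        allele_seq <- substr(new_seq, loc$start + 1L, loc$start + tract_len)
        truth[[length(truth) + 1L]] <- tibble(
          locus = loc$name, donor = d, hap = h,
          allele_seq = allele_seq,
          allele_length = nchar(allele_seq),
          allele_label = to_length_allele(nchar(allele_seq), loc$internal_offset, mlen),
          weight = s$weight[1]
        )
      }
      haps[[length(haps) + 1L]] <- list(
        hap_id = sprintf("d%d.h%d", d, h), donor = d, hap = h,
        weight = spec$weight[1],
        seqs = seqs,
        events = if (length(events)) bind_rows(events) else
          tibble(chrom = character(), type = character(),
                 ref_pos = integer(), hap_pos = integer(), len = integer())
      )
    }
  }
  structure(
    list(
      haplotypes = haps,
      truth = bind_rows(truth),
      reference = reference,
      loci = loci
    ),
    class = "tr_genomes"
  )
}

# Mapped-block table for one haplotype contig: hap [hs,he) aligns to ref
# starting at rs. Gaps between blocks in hap space are insertions, gaps in
# ref space are deletions.
hap_blocks <- function(events, hap_len) {
  ev <- events[order(events$hap_pos), , drop = FALSE]
  blocks <- list()
  cur_h <- 0L
  cur_r <- 0L
  for (j in seq_len(nrow(ev))) {
    e <- ev[j, ]
    w <- e$hap_pos - cur_h
    if (w > 0L) {
      blocks[[length(blocks) + 1L]] <- c(hs = cur_h, he = cur_h + w, rs = cur_r)
    }
    cur_h <- cur_h + w
    cur_r <- cur_r + w
    if (e$type == "ins") {
      cur_h <- cur_h + e$len
    } else {
      cur_r <- cur_r + e$len
    }
  }
  if (hap_len > cur_h) {
    blocks[[length(blocks) + 1L]] <- c(hs = cur_h, he = hap_len, rs = cur_r)
  }
  do.call(rbind, blocks)
}

# Alignment of haplotype interval [s, e) against the reference: returns
# list(pos = 0-based leftmost ref position, cigar = string). Haplotype bases
# outside any mapped block at the read edges become soft clips.
align_hap_read <- function(s, e, blocks) {
  ops <- character()
  lens <- integer()
  pos <- NA_integer_
  prev_he <- NA_integer_ # haplotype end of last emitted match segment
  prev_re <- NA_integer_ # reference end of last emitted match segment
  for (b in seq_len(nrow(blocks))) {
    hs <- blocks[b, "hs"]; he <- blocks[b, "he"]; rs <- blocks[b, "rs"]
    ss <- max(s, hs); ee <- min(e, he)
    if (ee <= ss) next
    if (is.na(pos)) {
      if (ss > s) { # read starts inside an insertion: clip the lead-in
        ops <- c(ops, "S"); lens <- c(lens, as.integer(ss - s))
      }
      pos <- as.integer(rs + (ss - hs))
    } else {
      hap_gap <- ss - prev_he # unmapped hap bases between blocks: insertion
      if (hap_gap > 0L) {
        ops <- c(ops, "I"); lens <- c(lens, as.integer(hap_gap))
      }
      ref_gap <- (rs + (ss - hs)) - prev_re # missing ref bases: deletion
      if (ref_gap > 0L) {
        ops <- c(ops, "D"); lens <- c(lens, as.integer(ref_gap))
      }
    }
    ops <- c(ops, "M"); lens <- c(lens, as.integer(ee - ss))
    prev_he <- ee
    prev_re <- rs + (ee - hs)
  }
  if (is.na(pos)) stop("read maps entirely inside an insertion", call. = FALSE)
  if (prev_he < e) { # trailing bases inside an insertion
    ops <- c(ops, "S"); lens <- c(lens, as.integer(e - prev_he))
  }
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}

mode_params <- function(mode) {
  switch(mode,
    pe150 = list(paired = TRUE, read_len = 150L, frag_mean = 450, frag_sd = 50,
                 error = 0.001, indels = FALSE),
    pe250 = list(paired = TRUE, read_len = 250L, frag_mean = 700, frag_sd = 70,
                 error = 0.001, indels = FALSE),
    long_ccs = list(paired = FALSE, read_len = 1000L, len_sd = 100,
                    error = 0.05, indels = TRUE),
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

#' Simulate sequencing reads from donor haplotype genomes
#'
#' Draws reads uniformly over every haplotype so that the realized total
#' depth over interior positions matches `mean_depth`; a diploid donor's two
#' haplotypes split the donor's share (donor weight) equally. Three modes are
#' supported: `pe150` and `pe250` (paired-end short reads, Gaussian fragment
#' lengths, independent substitution errors) and `long_ccs` (single long
#' reads, ~1 kb on these contigs, with mixed substitution/indel errors at a
#' 1:1 ratio, default total rate 0.05 emulating 95% base accuracy
#' consensus reads).
#'
#' Alignments are constructed directly from the known simulation coordinates
#' ("truth alignment"): each read's reference position and CIGAR are derived
#' from the haplotype's known indel events, decoupling caller tests from any
#' external aligner. The same seed gives byte-identical output.
#'
#' @param genomes A `tr_genomes` object from [build_truth_genomes()].
#' @param mode `"pe150"`, `"pe250"` or `"long_ccs"`.
#' @param mean_depth Target total depth (x-fold) over locus positions.
#' @param error_rate Per-base error rate; defaults to 0.001 for paired-end
#'   modes and 0.05 for `long_ccs`.
#' @param seed RNG seed.
#' @return A read tibble (`qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`,
#'   `seq`, plus `hap_id`), coordinate-sorted, usable directly by
#'   [call_targets()] or written with [write_reads_bam()].
#' @export
simulate_reads <- function(genomes, mode = c("pe150", "pe250", "long_ccs"),
                           mean_depth, error_rate = NULL, seed = 1L) {
  stopifnot(inherits(genomes, "tr_genomes"), mean_depth > 0)
  mode <- match.arg(mode)
  mp <- mode_params(mode)
  if (is.null(error_rate)) error_rate <- mp$error
  stopifnot(error_rate >= 0, error_rate < 0.5)

  withr::with_seed(seed, {
    out <- vector("list", 0L)
    counter <- 0L
    for (hp in genomes$haplotypes) {
      depth_hap <- mean_depth * hp$weight / 2
      for (chrom in names(hp$seqs)) {
        hseq <- hp$seqs[[chrom]]
        hlen <- nchar(hseq)
        ev <- filter(hp$events, .data$chrom == .env$chrom)
        blocks <- hap_blocks(ev, hlen)
        if (mp$paired) {
          rl <- mp$read_len
          n_frag <- rpois(1L, depth_hap * max(hlen - mp$frag_mean + 1, 1) / (2 * rl))
          if (n_frag == 0L) next
          fl <- pmin(pmax(round(rnorm(n_frag, mp$frag_mean, mp$frag_sd)), 2L * rl), hlen)
          fs <- floor(runif(n_frag) * (hlen - fl + 1))
          ivs <- rbind(
            cbind(s = fs, e = fs + rl, mate = 1L, id = seq_len(n_frag)),
            cbind(s = fs + fl - rl, e = fs + fl, mate = 2L, id = seq_len(n_frag))
          )
        } else {
          rl0 <- min(mp$read_len, hlen)
          # reads this long cover the (centred) locus from almost any start;
          # size the draw so midpoint coverage, not per-base average, hits
          # the target depth
          mid <- hlen %/% 2L
          n_starts <- max(hlen - rl0 + 1L, 1L)
          w_mid <- min(mid, hlen - rl0) - max(0L, mid - rl0 + 1L) + 1L
          n <- rpois(1L, depth_hap * n_starts / max(w_mid, 1L))
          if (n == 0L) next
          rl <- pmin(pmax(round(rnorm(n, rl0, mp$len_sd)), 300L), hlen)
          fs <- floor(runif(n) * (hlen - rl + 1))
          ivs <- cbind(s = fs, e = fs + rl, mate = 0L, id = seq_len(n))
        }
        s <- as.integer(ivs[, "s"]); e <- as.integer(ivs[, "e"])
        nr <- length(s)
        pos <- integer(nr)
        cig <- character(nr)
        # fast path: read wholly inside one mapped block -> pure match
        pure <- rep(FALSE, nr)
        for (b in seq_len(nrow(blocks))) {
          inb <- s >= blocks[b, "hs"] & e <= blocks[b, "he"]
          pos[inb] <- blocks[b, "rs"] + (s[inb] - blocks[b, "hs"])
          pure <- pure | inb
        }
        cig[pure] <- paste0(e[pure] - s[pure], "M")
        for (r in which(!pure)) {
          aln <- align_hap_read(s[r], e[r], blocks)
          pos[r] <- aln$pos
          cig[r] <- aln$cigar
        }
        seqs <- substr(rep(hseq, nr), s + 1L, e)
        if (error_rate > 0) {
          sub_rate <- if (mp$indels) error_rate / 2 else error_rate
          n_sub <- stats::rbinom(nr, nchar(seqs), sub_rate)
          for (r in which(n_sub > 0L)) {
            bases <- strsplit(seqs[r], "")[[1]]
            at <- sample.int(length(bases), n_sub[r])
            for (p in at) {
              bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
            }
            seqs[r] <- paste(bases, collapse = "")
          }
          if (mp$indels) {
            n_ind <- stats::rbinom(nr, nchar(seqs), error_rate / 2)
            for (r in which(n_ind > 0L)) {
              patched <- patch_indels(seqs[r], cig[r], pos[r], n_ind[r])
              seqs[r] <- patched$seq
              cig[r] <- patched$cigar
              pos[r] <- patched$pos
            }
          }
        }
        mate <- ivs[, "mate"]
        qname <- ifelse(
          mate == 0L,
          sprintf("sim_%s_%s_%06d", hp$hap_id, chrom, counter + seq_len(nr)),
          sprintf("sim_%s_%s_f%06d", hp$hap_id, chrom, ivs[, "id"])
        )
        counter <- counter + nr
        out[[length(out) + 1L]] <- tibble(
          qname = qname,
          flag = ifelse(mate == 0L, 0L, ifelse(mate == 1L, 99L, 147L)),
          chrom = chrom, pos = pos, mapq = 60L, cigar = cig, seq = seqs,
          hap_id = hp$hap_id
        )
      }
    }
    reads <- bind_rows(out)
    if (nrow(reads) == 0L) {
      warning("requested depth yielded no reads", call. = FALSE)
      return(mutate(empty_reads(), hap_id = character()))
    }
    arrange(reads, .data$chrom, .data$pos, .data$qname, .data$flag)
  })
}

# Inject n 1-bp indel errors (insertion/deletion 1:1) into a read alignment.
patch_indels <- function(seq, cigar, pos, n) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  q_ops <- rep(ops[ops != "D"], lens[ops != "D"]) # per-query-base op
  dafter <- integer(length(q_ops)) # deleted ref bases after query base i
  qi <- 0L
  for (j in seq_along(ops)) {
    if (ops[j] == "D") {
      if (qi >= 1L) dafter[qi] <- dafter[qi] + lens[j]
    } else {
      qi <- qi + lens[j]
    }
  }
  bases <- strsplit(seq, "")[[1]]
  dbefore <- 0L # ref bases deleted before the first aligned base
  for (k in seq_len(n)) {
    if (length(bases) <= 2L) break
    if (runif(1) < 0.5) { # insertion error: extra base in the read
      p <- sample.int(length(bases) - 1L, 1L) # after base p, inside the read
      bases <- append(bases, sample(c("A", "C", "G", "T"), 1L), after = p)
      q_ops <- append(q_ops, "I", after = p)
      dafter <- append(dafter, 0L, after = p)
    } else { # deletion error: read base lost
      p <- sample.int(length(bases), 1L)
      was_m <- q_ops[p] == "M"
      d <- dafter[p]
      bases <- bases[-p]
      q_ops <- q_ops[-p]
      dafter <- dafter[-p]
      extra <- (if (was_m) 1L else 0L) + d
      if (p > 1L) {
        dafter[p - 1L] <- dafter[p - 1L] + extra
      } else {
        dbefore <- dbefore + extra
      }
    }
  }
  # leading/trailing insertions become soft clips; leading deletions shift pos
  n_q <- length(q_ops)
  lead <- 0L
  while (lead < n_q && q_ops[lead + 1L] != "M") lead <- lead + 1L
  if (lead > 0L) q_ops[seq_len(lead)] <- "S"
  tail_i <- 0L
  while (tail_i < n_q - lead && q_ops[n_q - tail_i] != "M") tail_i <- tail_i + 1L
  if (tail_i > 0L) q_ops[(n_q - tail_i + 1L):n_q] <- "S"
  if (tail_i > 0L) dafter[(n_q - tail_i):n_q] <- 0L # no trailing deletions
  out_ops <- character()
  out_lens <- integer()
  push <- function(op, len) {
    m <- length(out_ops)
    if (m > 0L && out_ops[m] == op) {
      out_lens[m] <<- out_lens[m] + len
    } else {
      out_ops <<- c(out_ops, op)
      out_lens <<- c(out_lens, len)
    }
  }
  for (i in seq_len(n_q)) {
    push(q_ops[i], 1L)
    if (dafter[i] > 0L && i > lead && i <= n_q - tail_i) push("D", dafter[i])
  }
  list(
    seq = paste(bases, collapse = ""),
    cigar = paste0(out_lens, out_ops, collapse = ""),
    pos = pos + dbefore
  )
}

#' Write simulated reads as a sorted, indexed BAM
#'
#' Serialises a read tibble to SAM, converts to BAM, coordinate-sorts and
#' indexes it, yielding input identical in structure to an aligner's output.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param ref_lengths Named integer vector of contig lengths (e.g.
#'   `nchar(panel$reference)`).
#' @param path Output BAM path (must end in `.bam`).
#' @return The BAM path, invisibly (index written alongside).
#' @export
write_reads_bam <- function(reads, ref_lengths, path) {
  stopifnot(grepl("\\.bam$", path), !is.null(names(ref_lengths)))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  if (nrow(reads) > 0L) {
    paired <- bitwAnd(reads$flag, 1L) != 0L
    rnext <- ifelse(paired, "=", "*")
    pnext <- integer(nrow(reads))
    if (any(paired)) { # mate position by fragment name
      key <- paste(reads$qname, reads$chrom)
      mate_pos <- stats::ave(reads$pos, key, FUN = function(p) {
        if (length(p) == 2L) rev(p) else p
      })
      pnext[paired] <- mate_pos[paired] + 1L
    }
    body <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
      reads$qname, reads$flag, reads$chrom, reads$pos + 1L, reads$mapq,
      reads$cigar, rnext, pnext, reads$seq
    )
  } else {
    body <- character()
  }
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                          indexDestination = FALSE)
  dest <- sub("\\.bam$", "", path)
  sorted <- Rsamtools::sortBam(bam, paste0(dest, ".tmp_sorted"))
  file.rename(sorted, path)
  Rsamtools::indexBam(path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Optional export for running the simulation through a real aligner.
#' Reverse-strand reads (flag 0x10) are written reverse-complemented, i.e.
#' in sequencing orientation. Paired reads are interleaved.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- reads$seq
  rev <- bitwAnd(reads$flag, 16L) != 0L
  if (any(rev)) {
    seqs[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev]))
    )
  }
  mate <- dplyr::case_when(
    bitwAnd(reads$flag, 64L) != 0L ~ "/1",
    bitwAnd(reads$flag, 128L) != 0L ~ "/2",
    .default = ""
  )
  rec <- sprintf("@%s%s\n%s\n+\n%s", reads$qname, mate, seqs,
                 strrep("I", nchar(seqs)))
  writeLines(rec, path)
  invisible(path)
}

#' Add PCR stutter reads to a simulation
#'
#' Fixture utility for exercising the stutter filter: builds, for every
#' haplotype, a companion genome in which each locus has lost one motif unit,
#' and simulates additional reads from it at `stutter_rate` times the main
#' depth. Combined with the parent reads this yields loci whose minor
#' one-motif-shorter haplotype mimics PCR slippage.
#'
#' @param genomes `tr_genomes` from [build_truth_genomes()].
#' @param genotypes The genotype tibble the genomes were built from.
#' @param mode,mean_depth,error_rate,seed As in [simulate_reads()].
#' @param stutter_rate Stutter read depth as a fraction of `mean_depth`.
#' @return A read tibble with an `origin` column (`"allele"` or
#'   `"stutter"`).
#' @export
simulate_stutter_reads <- function(genomes, genotypes, mode = "pe250",
                                   mean_depth, stutter_rate = 0.1,
                                   error_rate = 0, seed = 1L) {
  stopifnot(stutter_rate > 0, stutter_rate < 1)
  main <- simulate_reads(genomes, mode, mean_depth, error_rate, seed = seed)
  stut_geno <- mutate(genotypes, delta = .data$delta - 1L, snp_off = NA_integer_)
  stut_genomes <- build_truth_genomes(genomes$reference, genomes$loci, stut_geno)
  stut <- simulate_reads(stut_genomes, mode, mean_depth * stutter_rate,
                         error_rate, seed = seed + 1L)
  if (nrow(stut) > 0L) stut$qname <- paste0("stut_", stut$qname)
  bind_rows(
    mutate(main, origin = "allele"),
    mutate(stut, origin = "stutter")
  )
}

#' Score called alleles against a truth set
#'
#' Computes the two sensitivity ratios: allele recall (correctly called
#' alleles over expected alleles, where the expected alleles of a locus are
#' its distinct true allele sequences pooled over donors) and locus-level
#' accuracy (a locus is correct when its called set equals its expected set
#' exactly). Precision is the fraction of called alleles present in the
#' truth.
#'
#' @param calls A `tr_calls` object from [call_targets()].
#' @param truth Truth tibble from [build_truth_genomes()].
#' @return One-row tibble: `n_loci`, `expected_alleles`, `called_alleles`,
#'   `correct_alleles`, `allele_recall`, `allele_precision`,
#'   `allele_dropout`, `locus_recall`, `locus_dropout`.
#' @export
score_calls <- function(calls, truth) {
  stopifnot(inherits(calls, "tr_calls"))
  exp_tab <- dplyr::distinct(truth, .data$locus, .data$allele_seq)
  got <- called_alleles(calls)
  loci_names <- unique(truth$locus)
  per_locus <- purrr::map(loci_names, function(ln) {
    expect <- exp_tab$allele_seq[exp_tab$locus == ln]
    seen <- got$sequence[got$locus == ln]
    tibble(
      locus = ln,
      n_expected = length(expect),
      n_called = length(seen),
      n_correct = length(intersect(seen, expect)),
      exact = setequal(seen, expect)
    )
  })
  pl <- bind_rows(per_locus)
  n_exp <- sum(pl$n_expected)
  n_called <- sum(pl$n_called)
  n_corr <- sum(pl$n_correct)
  tibble(
    n_loci = nrow(pl),
    expected_alleles = n_exp,
    called_alleles = n_called,
    correct_alleles = n_corr,
    allele_recall = n_corr / n_exp,
    allele_precision = if (n_called > 0L) n_corr / n_called else NA_real_,
    allele_dropout = 1 - n_corr / n_exp,
    locus_recall = mean(pl$exact),
    locus_dropout = 1 - mean(pl$exact)
  )
}

#' Depth/read-length sensitivity experiment
#'
#' Reproduces the simulation-based sensitivity design: for every replicate a
#' fresh diploid genotype is drawn over the panel, reads are simulated for
#' each (mode, depth) combination, alleles are called with the default
#' configuration and scored against the truth set. Allele recall is the
#' number of correctly called alleles divided by the number of expected
#' alleles; locus dropout is the fraction of loci whose called set does not
#' equal the truth.
#'
#' @param loci Target tibble; when `NULL` a default [simulate_panel()] is
#'   built (and returned as an attribute `panel`).
#' @param reference Named contig sequences matching `loci`; required when
#'   `loci` is given.
#' @param truth_spec Optional fixed genotype tibble; when `NULL` a new
#'   genotype is drawn per replicate.
#' @param modes Character vector of read modes.
#' @param depths Numeric vector of mean depths.
#' @param replicates Simulation rounds per (mode, depth).
#' @param seed Master seed; every replicate derives its own sub-seeds.
#' @param config [caller_config()] used for calling.
#' @param error_rate Optional error-rate override passed to
#'   [simulate_reads()].
#' @return A tibble of class `tr_sensitivity`: one row per
#'   (mode, depth, replicate) with the scores of [score_calls()].
#' @export
sensitivity_experiment <- function(loci = NULL, reference = NULL,
                                   truth_spec = NULL,
                                   modes = c("pe150", "pe250", "long_ccs"),
                                   depths = c(5, 10, 15, 20, 25, 30, 40, 50,
                                              60, 70, 80, 90, 100),
                                   replicates = 10L, seed = 1L,
                                   config = caller_config(),
                                   error_rate = NULL) {
  stopifnot(replicates >= 1L)
  if (is.null(loci)) {
    panel <- simulate_panel(seed = seed)
    loci <- panel$loci
    reference <- panel$reference
  }
  stopifnot(!is.null(reference))
  rows <- vector("list", 0L)
  for (r in seq_len(replicates)) {
    geno <- if (is.null(truth_spec)) {
      simulate_genotypes(loci, seed = seed + 7919L * r)
    } else {
      truth_spec
    }
    genomes <- build_truth_genomes(reference, loci, geno)
    for (mi in seq_along(modes)) {
      for (di in seq_along(depths)) {
        sim_seed <- seed + 104729L * r + 1009L * mi + 31L * di
        reads <- simulate_reads(genomes, modes[mi], depths[di],
                                error_rate = error_rate, seed = sim_seed)
        calls <- call_targets(reads, loci, config)
        sc <- score_calls(calls, genomes$truth)
        rows[[length(rows) + 1L]] <- mutate(
          sc, mode = modes[mi], depth = depths[di], replicate = r,
          .before = 1L
        )
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("tr_sensitivity", class(out))
  out
}
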