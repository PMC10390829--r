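test_that("motif validation is exact-substring and case-insensitive", {
  expect_true(validate_motif("ATCGATCGggATCGA", "ATCG"))
  expect_false(validate_motif("TTTTT", "ATCG"))
  expect_true(validate_motif("atcgatcg", "ATCG"))
  expect_equal(validate_motif(c("ACGTACGT", NA, ""), "ACGT"),
               c(TRUE, FALSE, FALSE))
})

test_that("haplotype classification counts identical sequences", {
  obs <- classify_haplotypes(c("AAC", "AAC", "AACAAC"), "L")
  expect_equal(obs$sequence, c("AAC", "AACAAC"))
  expect_equal(obs$read_count, c(2L, 1L))
  expect_equal(obs$proportion, c(2 / 3, 1 / 3))

  one <- classify_haplotypes(rep("ACGTACGT", 100), "L")
  expect_equal(nrow(one), 1L)
  expect_equal(one$proportion, 1)

  counts <- classify_haplotypes(
    rep(c("AAAC", "AAACC", "AAACCC"), times = c(50, 30, 20)), "L"
  )
  expect_equal(counts$proportion, c(0.5, 0.3, 0.2))
  expect_equal(sum(counts$proportion), 1)

  empty <- classify_haplotypes(character(), "L")
  expect_equal(nrow(empty), 0L)
})

test_that("the allele cap is ploidy times donors", {
  expect_equal(max_alleles(2, 1), 2L)
  expect_equal(max_alleles(2, 2), 4L)
  expect_equal(max_alleles(1, 1), 1L)
  expect_error(max_alleles(0, 1), "positive")
  expect_error(max_alleles(2, 0), "positive")
})

test_that("the stutter filter flags one-motif-shorter minor haplotypes", {
  obs <- tibble::tibble(
    locus = "L",
    sequence = c(strrep("ACGT", 10), strrep("ACGT", 9)),
    read_count = c(100L, 20L),
    proportion = c(100, 20) / 120
  )
  st <- stutter_filter(obs, 4L, 0.25, mixture_mode = FALSE)
  expect_equal(st$is_stutter, c(FALSE, TRUE)) # 20 < 0.25 * 100

  # in mixture mode nothing is filtered
  st_mix <- stutter_filter(obs, 4L, 0.25, mixture_mode = TRUE)
  expect_equal(st_mix$is_stutter, c(FALSE, FALSE))

  # at or above the ratio the candidate is kept
  obs$read_count[2] <- 30L
  st2 <- stutter_filter(obs, 4L, 0.25, mixture_mode = FALSE)
  expect_equal(st2$is_stutter, c(FALSE, FALSE)) # 30 >= 25

  # ratio 0 disables the filter entirely
  obs$read_count[2] <- 1L
  st3 <- stutter_filter(obs, 4L, 0, mixture_mode = FALSE)
  expect_equal(st3$is_stutter, c(FALSE, FALSE))
})

test_that("a filtered stutter cannot shelter a further stutter", {
  obs <- tibble::tibble(
    locus = "L",
    sequence = c(strrep("ACGT", 10), strrep("ACGT", 9), strrep("ACGT", 8)),
    read_count = c(100L, 20L, 4L),
    proportion = c(100, 20, 4) / 124
  )
  st <- stutter_filter(obs, 4L, 0.25, mixture_mode = FALSE)
  # 20 < 25 -> stutter of the 40-mer; the 32-mer's only one-motif parent is
  # itself a stutter, so it survives this filter
  expect_equal(st$is_stutter, c(FALSE, TRUE, FALSE))
})

test_that("filters apply in order with first-failure status attribution", {
  locus <- make_locus(start = 100, end = 140, motif = "ACGT")
  mk_obs <- function(counts, base = 10) {
    seqs <- vapply(seq_along(counts), function(i) strrep("ACGT", base + i),
                   character(1))
    tibble::tibble(
      locus = "LOC", sequence = seqs, read_count = as.integer(counts),
      proportion = counts / sum(counts)
    )
  }
  cfg <- caller_config()

  out <- apply_filters(mk_obs(c(50, 45, 1)), locus, cfg)
  expect_equal(sort(out$status),
               sort(c("called", "called", "filtered_coverage")))
  # the singleton is below coverage AND proportion: coverage wins (first)
  expect_equal(out$status[out$read_count == 1L], "filtered_coverage")

  out2 <- apply_filters(mk_obs(c(50, 48, 47)), locus, cfg)
  expect_equal(out2$status, c("called", "called", "filtered_cap"))

  out3 <- apply_filters(mk_obs(c(50, 48, 47, 40)), locus,
                        caller_config(donors = 2L))
  expect_equal(out3$status, rep("called", 4L))

  # proportion failure when coverage passes
  out4 <- apply_filters(mk_obs(c(80, 5)), locus, cfg)
  expect_equal(out4$status, c("called", "filtered_proportion"))
})

test_that("cap ties break by count, then shorter allele, then sequence", {
  locus <- make_locus(start = 100, end = 140, motif = "ACGT", ploidy = 1L)
  obs <- tibble::tibble(
    locus = "LOC",
    sequence = c(strrep("ACGT", 11), strrep("ACGT", 10)),
    read_count = c(30L, 30L),
    proportion = c(0.5, 0.5)
  )
  out <- apply_filters(obs, locus, caller_config(default_stutter_ratio = 0))
  expect_equal(out$sequence[out$status == "called"], strrep("ACGT", 10))
})

test_that("length-based designation follows the floor/remainder conversion", {
  expect_equal(to_length_allele(15, 2, 4), "3.1")
  expect_equal(to_length_allele(16, 0, 4), "4")
  expect_equal(to_length_allele(127, 43, 4), "21")
  expect_equal(to_length_allele(c(15, 16), c(2, 0), 4), c("3.1", "4"))
  expect_error(to_length_allele(2, 2, 4), "exceed")
  # label reconstruction: I * motif_length + F + internal_offset == length
  expect_equal(from_length_allele("3.1", 2, 4), 15L)
  expect_equal(from_length_allele("21", 43, 4), 127L)
})

test_that("a homozygous locus with concordant reads yields one clean call", {
  locus <- make_locus(start = 120, end = 160, motif = "ACGT")
  tract <- strrep("ACGT", 10)
  seq <- paste0(random_seq(40), tract, random_seq(40))
  reads <- dplyr::bind_rows(lapply(1:30, function(i) {
    r <- make_read("120M", pos = 80, qname = sprintf("r%02d", i), seq = seq)
    r
  }))
  res <- call_locus(reads, locus)
  called <- dplyr::filter(res$calls, status == "called")
  expect_equal(nrow(called), 1L)
  expect_equal(called$read_count, 30L)
  expect_equal(called$sequence, tract)
  expect_equal(called$allele_label, "10")
  expect_equal(res$qc$fetched, 30L)
  expect_equal(res$qc$classified, 30L)
})

test_that("read tallies are conserved through the locus pipeline", {
  w <- demo_world(seed = 31L, mode = "pe150", depth = 40,
                  error_rate = 0.002)
  res <- call_targets(w$reads, w$panel$loci)
  expect_equal(
    res$qc$fetched,
    res$qc$skipped_incomplete + res$qc$motif_invalid + res$qc$classified
  )
  counts <- dplyr::summarise(
    dplyr::group_by(res$calls, locus), n = sum(read_count)
  )
  qc <- dplyr::left_join(res$qc, counts, by = "locus")
  qc$n[is.na(qc$n)] <- 0L
  expect_equal(qc$n, qc$classified)
  # proportions sum to one wherever haplotypes were observed
  props <- dplyr::summarise(
    dplyr::group_by(res$calls, locus), p = sum(proportion)
  )
  expect_true(all(abs(props$p - 1) < 1e-9))
})

test_that("called alleles never exceed the cap and labels reconstruct", {
  w <- demo_world(seed = 32L, n_donors = 2L, depth = 80)
  cfg <- caller_config(donors = 2L)
  res <- call_targets(w$reads, w$panel$loci, cfg)
  called <- called_alleles(res)
  per_locus <- table(called$locus)
  expect_true(all(per_locus <= max_alleles(2L, 2L)))
  loci <- w$panel$loci
  for (i in seq_len(nrow(called))) {
    loc <- loci[loci$name == called$locus[i], ]
    expect_equal(
      from_length_allele(called$allele_label[i], loc$internal_offset,
                         loc$motif_length),
      called$allele_length[i]
    )
  }
})

test_that("raising thresholds never enlarges the called set", {
  w <- demo_world(seed = 33L, mode = "pe150", depth = 25, error_rate = 0.002)
  key <- function(res) {
    c <- called_alleles(res)
    paste(c$locus, c$sequence)
  }
  base <- key(call_targets(w$reads, w$panel$loci, caller_config()))
  higher_cov <- key(call_targets(w$reads, w$panel$loci,
                                 caller_config(min_coverage = 5L)))
  higher_prop <- key(call_targets(w$reads, w$panel$loci,
                                  caller_config(min_proportion = 0.3)))
  expect_true(all(higher_cov %in% base))
  expect_true(all(higher_prop %in% base))
})

test_that("heterozygous and mixed-donor truth genotypes are recovered", {
  # heterozygous 10/12-repeat locus at 50x
  panel <- simulate_panel(n_loci = 1L, seed = 41L)
  geno <- tibble::tibble(
    name = panel$loci$name, donor = 1L, hap = 1:2,
    delta = c(0L, 2L), snp_off = NA_integer_, snp_base = NA_character_,
    weight = 1
  )
  genomes <- build_truth_genomes(panel$reference, panel$loci, geno)
  reads <- simulate_reads(genomes, "pe250", 50, error_rate = 0, seed = 42L)
  res <- call_locus(reads, panel$loci)
  called <- dplyr::filter(res$calls, status == "called")
  expect_equal(nrow(called), 2L)
  expect_setequal(called$sequence, genomes$truth$allele_seq)
  expect_setequal(called$allele_label, genomes$truth$allele_label)

  # two donors, four distinct haplotypes, d = 2: all four called
  geno2 <- tibble::tibble(
    name = panel$loci$name, donor = c(1L, 1L, 2L, 2L), hap = c(1:2, 1:2),
    delta = c(-2L, 0L, 1L, 3L), snp_off = NA_integer_,
    snp_base = NA_character_, weight = 0.5
  )
  genomes2 <- build_truth_genomes(panel$reference, panel$loci, geno2)
  reads2 <- simulate_reads(genomes2, "pe250", 100, error_rate = 0, seed = 43L)
  res2 <- call_locus(reads2, panel$loci, caller_config(donors = 2L))
  called2 <- dplyr::filter(res2$calls, status == "called")
  expect_equal(nrow(called2), 4L)
  expect_setequal(called2$sequence, genomes2$truth$allele_seq)
})

test_that("calling is deterministic on identical inputs", {
  w <- demo_world(seed = 34L, n_loci = 3L, depth = 30, error_rate = 0.001)
  a <- call_targets(w$reads, w$panel$loci)
  b <- call_targets(w$reads, w$panel$loci)
  expect_identical(a$calls, b$calls)
  expect_identical(a$qc, b$qc)
})

test_that("a locus on an unknown contig yields a warned no-call", {
  w <- demo_world(seed = 35L, n_loci = 2L, depth = 20)
  ghost <- make_locus(chrom = "ctgZZ", start = 100, end = 140, name = "GHOST")
  bam <- withr::local_tempfile(fileext = ".bam")
  write_reads_bam(w$reads, nchar(w$panel$reference), bam)
  expect_warning(res <- call_locus(bam, ghost), "ctgZZ")
  expect_equal(res$qc$fetched, 0L)
  expect_equal(res$qc$called, 0L)
})
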