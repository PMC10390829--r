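#' Read a target-locus BED file
#'
#' Parses the extended BED dialect that defines target tandem-repeat loci.
#' Each data line is tab-separated with columns, in order: `chrom`, `start`,
#' `end`, `name`, `motif`, `motif_length`, `internal_offset` and the optional
#' `stutter_ratio` and `ploidy`. Coordinates are 0-based half-open and denote
#' the repeat tract itself (flanking bases are not part of the interval).
#' Lines starting with `#` and blank lines are ignored. A literal `.` in an
#' optional column leaves it unset.
#'
#' The `internal_offset` is the number of bases inside the interval excluded
#' when converting a sequence allele to its length-based designation (see
#' [to_length_allele()]); `stutter_ratio`, when present, overrides the
#' run-level default used by the PCR-stutter filter at that locus.
#'
#' @param path Path to the BED file.
#' @param strict If `TRUE` (default) any malformed line aborts with an error
#'   naming the line; if `FALSE` malformed lines are skipped with a warning.
#' @return A tibble with one row per locus, in file order, with columns
#'   `chrom` (character), `start`, `end` (0-based half-open integers), `name`,
#'   `motif` (uppercase), `motif_length`, `internal_offset` (integers),
#'   `stutter_ratio` (double, `NA` when unset) and `ploidy` (integer,
#'   defaulting to 2).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("ctg1\t100\t140\tLOC1\tTCTA\t4\t0\t0.25\t2", bed)
#' read_targets(bed)
#' @seealso [write_targets()]
#' @export
read_targets <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("target BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_targets())
  }

  parse_line <- function(line, lineno) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    problem <- validate_target_fields(f)
    if (!is.null(problem)) {
      msg <- sprintf("line %d: %s", lineno, problem)
      if (strict) stop("malformed target record at ", msg, call. = FALSE)
      warning("skipping malformed target record at ", msg, call. = FALSE)
      return(NULL)
    }
    tibble(
      chrom = f[1],
      start = as.integer(f[2]),
      end = as.integer(f[3]),
      name = f[4],
      motif = toupper(f[5]),
      motif_length = as.integer(f[6]),
      internal_offset = as.integer(f[7]),
      stutter_ratio = if (length(f) >= 8L && f[8] != ".") as.numeric(f[8]) else NA_real_,
      ploidy = if (length(f) >= 9L && f[9] != ".") as.integer(f[9]) else 2L
    )
  }

  rows <- purrr::map2(lines[idx], idx, parse_line)
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(empty_targets())
  }
  if (strict && anyDuplicated(out$name)) {
    dup <- unique(out$name[duplicated(out$name)])
    stop("duplicate locus name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  out
}

empty_targets <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), motif = character(), motif_length = integer(),
    internal_offset = integer(), stutter_ratio = double(), ploidy = integer()
  )
}

# Returns NULL when the fields form a valid record, else a diagnostic string.
validate_target_fields <- function(f) {
  if (length(f) < 7L) {
    return(sprintf("expected >= 7 tab-separated fields, found %d", length(f)))
  }
  start <- suppressWarnings(as.integer(f[2]))
  end <- suppressWarnings(as.integer(f[3]))
  if (is.na(start) || is.na(end)) return("non-integer start/end coordinate")
  if (start < 0L) return("negative start coordinate")
  if (end <= start) return(sprintf("end (%d) must exceed start (%d)", end, start))
  motif <- toupper(f[5])
  if (!grepl("^[ACGT]+$", motif)) return(sprintf("motif '%s' is not a DNA string over ACGT", f[5]))
  mlen <- suppressWarnings(as.integer(f[6]))
  if (is.na(mlen) || mlen < 1L) return("motif_length must be a positive integer")
  if (mlen != nchar(motif)) {
    return(sprintf("motif_length %d does not match motif '%s' (%d bp)", mlen, motif, nchar(motif)))
  }
  off <- suppressWarnings(as.integer(f[7]))
  if (is.na(off) || off < 0L) return("internal_offset must be a non-negative integer")
  if (off >= end - start) {
    return(sprintf("internal_offset %d must be smaller than the locus width %d", off, end - start))
  }
  if (length(f) >= 8L && f[8] != ".") {
    sr <- suppressWarnings(as.numeric(f[8]))
    if (is.na(sr) || sr < 0 || sr > 1) return("stutter_ratio must lie in [0, 1]")
  }
  if (length(f) >= 9L && f[9] != ".") {
    pl <- suppressWarnings(as.integer(f[9]))
    if (is.na(pl) || pl < 1L) return("ploidy must be a positive integer")
  }
  NULL
}

#' Write target loci to a BED file
#'
#' Inverse of [read_targets()]: writes one tab-separated line per locus in the
#' extended BED dialect, preserving row order. Unset `stutter_ratio` values
#' are written as `.` so that a read/write round trip reproduces the input.
#'
#' @param loci A target tibble as returned by [read_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(loci, path) {
  stopifnot(is.data.frame(loci))
  if (nrow(loci) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%d",
    loci$chrom, loci$start, loci$end, loci$name, loci$motif,
    loci$motif_length, loci$internal_offset,
    ifelse(is.na(loci$stutter_ratio), ".", format(loci$stutter_ratio, trim = TRUE)),
    loci$ploidy
  )
  writeLines(lines, path)
  invisible(path)
}
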