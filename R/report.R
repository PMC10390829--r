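report_header <- function(x, input = NULL) {
  cfg <- x$config
  c(
    "## tandemcall tandem-repeat allele report",
    sprintf("## version=%s", as.character(packageVersion("tandemcall"))),
    sprintf("## timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(input)) sprintf("## input=%s", input),
    sprintf("## min_coverage=%d", cfg$min_coverage),
    sprintf("## min_proportion=%s", format(cfg$min_proportion)),
    sprintf("## donors=%d", cfg$donors),
    sprintf("## default_stutter_ratio=%s", format(cfg$default_stutter_ratio)),
    sprintf("## flank=%d", cfg$flank),
    sprintf("## min_mapq=%d", cfg$min_mapq),
    sprintf("## mixture_mode=%s", cfg$mixture_mode)
  )
}

qc_lines <- function(qc) {
  c(
    paste(c("#QC", names(qc)), collapse = "\t"),
    sprintf(
      "#QC\t%s\t%d\t%d\t%d\t%d\t%d",
      qc$locus, qc$fetched, qc$skipped_incomplete, qc$motif_invalid,
      qc$classified, qc$called
    )
  )
}

allele_lines <- function(calls, with_status = FALSE) {
  cols <- c("locus", "allele_label", "allele_length", "sequence",
            "read_count", "proportion", if (with_status) "status")
  header <- paste(cols, collapse = "\t")
  if (nrow(calls) == 0L) return(header)
  body <- sprintf(
    "%s\t%s\t%d\t%s\t%d\t%.10g%s",
    calls$locus, calls$allele_label, calls$allele_length, calls$sequence,
    calls$read_count, calls$proportion,
    if (with_status) paste0("\t", calls$status) else ""
  )
  c(header, body)
}

#' Write the called-allele report
#'
#' Writes one row per called allele (loci in panel order, alleles by
#' decreasing read count) preceded by `##` metadata lines echoing every
#' threshold in force plus the tool version, and `#QC` lines carrying the
#' per-locus read tallies. Every configured locus appears in the QC section,
#' including no-call loci with zero allele rows.
#'
#' @param x A `tr_calls` object from [call_targets()].
#' @param path Output TSV path.
#' @param input Optional identifier of the alignment input, echoed in the
#'   header.
#' @return `path`, invisibly.
#' @seealso [write_raw_alleles()], [read_called_report()]
#' @export
write_called_report <- function(x, path, input = NULL) {
  stopifnot(inherits(x, "tr_calls"))
  called <- called_alleles(x)
  called <- arrange(
    called,
    match(.data$locus, x$loci$name), desc(.data$read_count), .data$sequence
  )
  writeLines(
    c(report_header(x, input), qc_lines(x$qc), allele_lines(called)),
    path
  )
  invisible(path)
}

#' Write the unfiltered haplotype report
#'
#' Companion file to [write_called_report()]: every observed haplotype at
#' every locus with its filter status (`called`, `filtered_coverage`,
#' `filtered_proportion`, `filtered_stutter`, `filtered_cap`), a superset of
#' the called report, for the user's further consideration.
#'
#' @inheritParams write_called_report
#' @return `path`, invisibly.
#' @export
write_raw_alleles <- function(x, path, input = NULL) {
  stopifnot(inherits(x, "tr_calls"))
  raw <- arrange(
    x$calls,
    match(.data$locus, x$loci$name), desc(.data$read_count), .data$sequence
  )
  writeLines(
    c(report_header(x, input), qc_lines(x$qc), allele_lines(raw, with_status = TRUE)),
    path
  )
  invisible(path)
}

#' Re-read a called-allele or raw-allele report
#'
#' Parses a file written by [write_called_report()] or
#' [write_raw_alleles()] back into its components.
#'
#' @param path Report path.
#' @return A list with `calls` (allele tibble; a `status` column is added as
#'   `"called"` for called-only reports), `qc` (per-locus tallies) and
#'   `meta` (named character vector of the `##` header fields).
#' @export
read_called_report <- function(path) {
  lines <- readLines(path)
  meta_l <- grep("^## ?[a-zA-Z_]+=", lines, value = TRUE)
  kv <- stringr::str_match(meta_l, "^## ?([a-zA-Z_]+)=(.*)$")
  meta <- setNames(kv[, 3], kv[, 2])
  qc_l <- lines[startsWith(lines, "#QC\t")]
  qc <- NULL
  if (length(qc_l) > 1L) {
    qc <- readr::read_tsv(I(sub("^#QC\t", "", qc_l)), show_col_types = FALSE)
    qc <- mutate(qc, across(-"locus", as.integer))
  }
  tab_l <- lines[!startsWith(lines, "#") & nzchar(lines)]
  calls <- readr::read_tsv(
    I(tab_l), show_col_types = FALSE,
    col_types = readr::cols(
      locus = "c", allele_label = "c", allele_length = "i",
      sequence = "c", read_count = "i", proportion = "d",
      .default = "c"
    )
  )
  if (!"status" %in% names(calls)) calls$status <- rep("called", nrow(calls))
  list(calls = as_tibble(calls), qc = qc, meta = meta)
}

#' Write the JSON sidecar of a run
#'
#' Serialises the full result -- configuration echo, per-locus QC tallies
#' and every haplotype row with its status -- as a single JSON object.
#'
#' @inheritParams write_called_report
#' @return `path`, invisibly.
#' @export
write_run_json <- function(x, path, input = NULL) {
  stopifnot(inherits(x, "tr_calls"))
  obj <- list(
    tool = "tandemcall",
    version = as.character(packageVersion("tandemcall")),
    input = input,
    config = unclass(x$config),
    qc = x$qc,
    alleles = x$calls
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
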