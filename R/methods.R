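#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.tr_calls <- function(x, ...) {
  called <- called_alleles(x)
  cat(sprintf(
    "<tr_calls> %d loci, %d called alleles (%d haplotypes observed)\n",
    nrow(x$loci), nrow(called), nrow(x$calls)
  ))
  if (nrow(called) > 0L) print(called, ...)
  invisible(x)
}

#' @export
print.tr_locus_result <- function(x, ...) {
  cat(sprintf("<tr_locus_result> locus %s\n", x$qc$locus))
  print(x$calls, ...)
  invisible(x)
}

#' Tidy an allele-call result
#'
#' @param x A `tr_calls` object.
#' @param ... Unused.
#' @return The full haplotype tibble (one row per observed haplotype with
#'   its filter status).
#' @method tidy tr_calls
#' @export
tidy.tr_calls <- function(x, ...) {
  x$calls
}

#' One-row summary of an allele-call run
#'
#' @param x A `tr_calls` object.
#' @param ... Unused.
#' @return A tibble with locus/allele counts and mean supporting coverage.
#' @method glance tr_calls
#' @export
glance.tr_calls <- function(x, ...) {
  called <- called_alleles(x)
  tibble(
    n_loci = nrow(x$loci),
    n_called_loci = sum(x$qc$called > 0L),
    n_no_call_loci = sum(x$qc$called == 0L),
    n_alleles = nrow(called),
    mean_allele_coverage = if (nrow(called)) mean(called$read_count) else NA_real_,
    reads_classified = sum(x$qc$classified)
  )
}

#' Plot called and filtered haplotypes per locus
#'
#' One panel per locus; bars show read support per haplotype (labelled by
#' length-based designation) coloured by filter status.
#'
#' @param object A `tr_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_calls
#' @export
autoplot.tr_calls <- function(object, ...) {
  df <- object$calls
  if (nrow(df) == 0L) stop("no haplotypes to plot", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$allele_label, y = .data$read_count, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~locus, scales = "free_x") +
    ggplot2::labs(
      x = "length-based allele", y = "supporting reads", fill = "status"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity curves over the depth grid
#'
#' Mean allele recall against mean depth, one line per read mode --
#' the standard depth-titration view of a sensitivity experiment.
#'
#' @param object A `tr_sensitivity` tibble from [sensitivity_experiment()].
#' @param metric Column to plot (default `allele_recall`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_sensitivity
#' @export
autoplot.tr_sensitivity <- function(object, metric = "allele_recall", ...) {
  df <- as_tibble(object) |>
    group_by(.data$mode, .data$depth) |>
    summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$depth, y = .data$value, colour = .data$mode
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean depth (x)", y = gsub("_", " ", metric),
                  colour = "read mode") +
    ggplot2::theme_minimal()
}
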