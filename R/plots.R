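#' Plot enrichment results
#'
#' Draws the most significant classes as a horizontal bar chart of
#' fold enrichment (overrepresentation results) or class size
#' (value-based enrichment results), colored by direction, with the
#' adjusted p-value mapped to bar transparency.
#'
#' @param object A result tibble from [run_overrepresentation()] or
#'   [run_enrichment()].
#' @param top How many classes to show (by adjusted p-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.overrep_result <- function(object, top = 20, ...) {
  d <- utils::head(dplyr::arrange(object, .data$p_adjusted), top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$fold_enrichment,
    y = stats::reorder(paste(.data$term_id, .data$name), -.data$p_adjusted),
    fill = .data$direction, alpha = -log10(.data$p_adjusted + 1e-300))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  alpha = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.overrep_result
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- utils::head(dplyr::arrange(object, .data$p_adjusted), top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = -log10(.data$p_adjusted + 1e-300),
    y = stats::reorder(paste(.data$term_id, .data$name), -.data$p_adjusted),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot family QC flag counts
#'
#' Summarizes a batch of [qc_family()] reports as the number of
#' families fired by each boundary criterion (a family can appear under
#' several criteria).
#'
#' @param reports A tibble of rows from [qc_family()].
#' @return A ggplot object.
#' @export
plot_qc_flags <- function(reports) {
  d <- reports |>
    tidyr::pivot_longer(dplyr::all_of(c("e1_noncore_members", "e2_short_core",
                                        "p1_sparse_members",
                                        "p2_disjoint_subtrees")),
                        names_to = "criterion", values_to = "fired") |>
    dplyr::filter(.data$fired) |>
    dplyr::count(.data$criterion)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$criterion, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "families flagged") +
    ggplot2::theme_minimal()
}
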