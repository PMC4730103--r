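new_ewce_result <- function(df, correction = "none", p_method = "plus_one") {
  attr(df, "correction") <- correction
  attr(df, "p_method") <- p_method
  class(df) <- c("ewce_result", class(df))
  df
}

#' @export
print.ewce_result <- function(x, ...) {
  cat(sprintf(
    "<EWCE enrichment result> %d test(s); correction: %s\n",
    nrow(x), attr(x, "correction") %||% "none"
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EWCE result
#'
#' Returns the per-group test table as a plain tibble (one row per group,
#' or per direction x group in transcriptome mode).
#'
#' @param x An `ewce_result`.
#' @param ... Unused.
#' @method tidy ewce_result
#' @export
tidy.ewce_result <- function(x, ...) {
  out <- x
  attr(out, "correction") <- NULL
  attr(out, "p_method") <- NULL
  attr(out, "genes_used") <- NULL
  attr(out, "genes_excluded") <- NULL
  attr(out, "null") <- NULL
  class(out) <- setdiff(class(out), "ewce_result")
  tibble::as_tibble(out)
}

#' One-row summary of an EWCE result
#'
#' @param x An `ewce_result`.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param ... Unused.
#' @method glance ewce_result
#' @return A tibble with the number of tests, the number significant after
#'   correction, and the top group (smallest adjusted p, ties broken by
#'   z-score).
#' @export
glance.ewce_result <- function(x, alpha = 0.05, ...) {
  ord <- order(x$p_adj, -ifelse(is.na(x$z), -Inf, x$z))
  top <- x[ord[1], ]
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p_adj < alpha),
    top_group = top$group,
    top_p_adj = top$p_adj,
    top_fold = top$fold,
    top_z = top$z,
    n_reps = top$n_reps,
    correction = attr(x, "correction") %||% "none"
  )
}

#' Plot an EWCE result
#'
#' Bar chart of bootstrap z-scores per group (faceted by direction when
#' present), with asterisks marking groups significant after
#' multiple-testing correction.
#'
#' @param object An `ewce_result`.
#' @param alpha Significance threshold on adjusted p-values.
#' @param ... Unused.
#' @method autoplot ewce_result
#' @return A ggplot object.
#' @export
autoplot.ewce_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_adj < alpha
  df$label <- ifelse(df$significant, "*", "")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$z,
                                        fill = .data$significant)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.2, size = 6, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "z-score (s.d. from bootstrap mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("direction" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~direction)
  }
  p
}

#' Heatmap of a specificity matrix
#'
#' Tile plot of gene-by-group specificity, genes ordered by their most
#' specific group. Intended for small selections of genes (e.g. a target
#' list).
#'
#' @param spec Specificity tibble.
#' @param genes Optional subset of genes to show.
#' @return A ggplot object.
#' @export
plot_specificity <- function(spec, genes = NULL) {
  df <- tidy_specificity(spec)
  if (!is.null(genes)) df <- dplyr::filter(df, .data$gene %in% genes)
  ord <- df |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$specificity, n = 1, with_ties = FALSE) |>
    dplyr::arrange(.data$group, -.data$specificity)
  df$gene <- factor(df$gene, levels = ord$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$gene,
                                   fill = .data$specificity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "specificity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Long-format view of a specificity matrix
#'
#' @param spec Specificity tibble (wide, one column per group).
#' @return Tibble with columns `gene`, `group`, `specificity`.
#' @export
tidy_specificity <- function(spec) {
  tidyr::pivot_longer(tibble::as_tibble(as.data.frame(spec)),
                      -"gene", names_to = "group", values_to = "specificity")
}

#' @importFrom rlang .data
NULL
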