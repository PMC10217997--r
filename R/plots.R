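# ggplot2 graphics for the main result types.

#' Plot a selection scan: foreground vs background dN/dS per gene
#'
#' Paired points per gene on a log scale, coloured by LRT significance.
#'
#' @param object A `selection_scan` tibble from [run_selection_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    select(object, "gene", "omega_fg", "omega_bg", "significant"),
    cols = c("omega_fg", "omega_bg"),
    names_to = "branch_set", values_to = "omega")
  df$branch_set <- ifelse(df$branch_set == "omega_fg", "foreground", "background")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$omega,
                                   shape = .data$branch_set,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene), colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "dN/dS", shape = NULL,
                  colour = "LRT significant") +
    ggplot2::theme_minimal()
}

#' Plot BEB site posteriors along the gene
#'
#' @param object A `beb_posteriors` tibble from [beb_site_posteriors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beb_posteriors <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.95
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site, y = .data$posterior)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$flagged), width = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "codon site", y = "P(positive selection)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-expression results
#'
#' @param object A `deg_result` tibble from [call_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_result <- function(object, ...) {
  df <- filter(object, is.finite(.data$log2_fc), .data$padj > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$padj),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
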