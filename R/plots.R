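#' Volcano plot of a differential-result table
#'
#' log2 fold change against -log10 raw p-value, genes passing the strict
#' significance filter highlighted.
#'
#' @param object A `ribote_deres` tibble.
#' @param alpha,lfc_min Thresholds for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribote_deres
#' @export
autoplot.ribote_deres <- function(object, alpha = 0.05, lfc_min = 1, ...) {
  df <- tidy(object) %>%
    filter(!is.na(.data$pvalue)) %>%
    mutate(significant = .data$padj < alpha & abs(.data$log2fc) > lfc_min)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc,
                                   -log10(pmax(.data$pvalue, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  colour = paste0("padj < ", alpha, ", |lfc| > ", lfc_min),
                  title = unique(df$contrast)[1]) +
    ggplot2::theme_minimal()
}

#' Heatmap of footprint-length profiles
#'
#' Percentage of reads per footprint length for every included profile,
#' rows ordered by the hierarchical clustering when one is supplied —
#' a ggplot rendition of the clustered footprint-length heatmap used to
#' compare sRNAs with coding and noncoding references.
#'
#' @param object A `ribote_profiles` tibble.
#' @param clustering Optional [cluster_profiles()] result used for row
#'   order.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribote_profiles
#' @export
autoplot.ribote_profiles <- function(object, clustering = NULL, ...) {
  meta_cols <- c("gene_id", "reference_class", "ref_type", "total_reads",
                 "excluded")
  df <- as_tibble(object) %>%
    filter(!.data$excluded) %>%
    tidyr::pivot_longer(-all_of(meta_cols), names_to = "length",
                        values_to = "pct") %>%
    mutate(length = as.integer(.data$length))
  ord <- if (!is.null(clustering)) {
    clustering$hclust$labels[clustering$hclust$order]
  } else {
    unique(df$gene_id)
  }
  df$gene_id <- factor(df$gene_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$length, .data$gene_id,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$reference_class),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "footprint length (nt)", y = NULL,
                  fill = "% of reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Bar chart of target-overlap summaries
#'
#' Differentially translated vs unaffected predicted targets per sRNA.
#'
#' @param object A `ribote_overlap` tibble from [target_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribote_overlap
#' @export
autoplot.ribote_overlap <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(unaffected = .data$n_targets - .data$n_differential) %>%
    tidyr::pivot_longer(c("n_differential", "unaffected"),
                        names_to = "status", values_to = "n") %>%
    mutate(status = if_else(.data$status == "n_differential",
                            "differential", "unaffected"))
  ggplot2::ggplot(df, ggplot2::aes(.data$srna_id, .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(differential = "purple4",
                                          unaffected = "grey70")) +
    ggplot2::labs(x = NULL, y = "predicted high-confidence targets",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
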