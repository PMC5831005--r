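#' Volcano plot of a differential test
#'
#' @param object a `docseq_diff` object.
#' @param fdr_max,min_abs_log2fc thresholds drawn and used to colour calls.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.docseq_diff <- function(object, fdr_max = 0.05,
                                 min_abs_log2fc = 0.5, ...) {
  r <- object$results |>
    filter(!is.na(.data$pvalue)) |>
    mutate(call = dplyr::case_when(
      .data$fdr < fdr_max & .data$log2fc >= min_abs_log2fc ~ "up in A",
      .data$fdr < fdr_max & .data$log2fc <= -min_abs_log2fc ~ "up in B",
      TRUE ~ "ns"))
  ggplot2::ggplot(r, ggplot2::aes(.data$log2fc, -log10(.data$pvalue),
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-min_abs_log2fc, min_abs_log2fc),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("up in A" = "#c0392b",
                                            "up in B" = "#2980b9",
                                            "ns" = "grey70")) +
    ggplot2::labs(x = "log2 fold change (A vs B)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of grouped region-set enrichment
#'
#' @param grouped tibble from [aggregate_group_enrichment()].
#' @return A ggplot (mean log2FE by annotation, coloured by group, filled
#'   when significant).
#' @export
plot_group_enrichment <- function(grouped) {
  ggplot2::ggplot(grouped,
                  ggplot2::aes(.data$mean_log2fe, .data$annotation_label,
                               colour = .data$group,
                               alpha = .data$significant)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "mean log2 fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of directional log2FE ratios
#'
#' @param ratios tibble from [log2fe_ratio()].
#' @return A ggplot; positive bars favour the first query set.
#' @export
plot_log2fe_ratio <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(.data$log2fe_ratio,
                                       .data$annotation_label)) +
    ggplot2::geom_col(fill = "#7f8c8d") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "log2FE ratio (first vs second query)", y = NULL) +
    ggplot2::theme_minimal()
}

#' PCA scatter of samples
#'
#' @param pca result of [pca_embedding()].
#' @param samples optional sample sheet for colouring by group.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_pca <- function(pca, samples = NULL) {
  s <- pca$scores
  if (!is.null(samples)) {
    s <- left_join(s, as_tibble(samples), by = "sample_id")
  }
  vf <- pca$variance_fraction
  g <- ggplot2::ggplot(s, ggplot2::aes(.data$PC1, .data$PC2))
  g <- if (!is.null(samples)) {
    g + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else g + ggplot2::geom_point(size = 2)
  g + ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * vf[1]),
                    y = sprintf("PC2 (%.0f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}
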