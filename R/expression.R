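#' Stage-wise differential expression
#'
#' Runs the NB Wald pipeline ([estimate_size_factors()],
#' [estimate_dispersion()], [nb_wald_test()], [bh_fdr()]) on gene counts for
#' the samples of one developmental stage, and splits significant genes by
#' direction. DE calling uses the FDR threshold only (no fold-change floor)
#' unless `min_abs_log2fc > 0`.
#'
#' @param counts integer matrix (genes x samples).
#' @param samples sample sheet with `sample_id`, `group` and (optionally)
#'   `stage`.
#' @param stage stage label to select (ignored when the sheet has no stage
#'   column).
#' @param fdr_max significance threshold.
#' @param min_abs_log2fc optional fold-change floor (default 0).
#' @param group_a positive-direction group.
#' @return A list of class `docseq_stage_de`: `stage`, `fit`
#'   (docseq_diff), `up_in_a`, `up_in_b` (gene id vectors), `tested`
#'   (the gene universe actually tested).
#' @export
stage_differential_expression <- function(counts, samples, stage = NULL,
                                          fdr_max = 0.05,
                                          min_abs_log2fc = 0,
                                          group_a = NULL) {
  samples <- as_tibble(samples)
  if (!is.null(stage) && "stage" %in% names(samples)) {
    samples <- samples[samples$stage == stage, ]
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  fit <- nb_wald_test(counts, samples, group_a = group_a)
  r <- fit$results
  sig <- !is.na(r$fdr) & r$fdr < fdr_max & abs(r$log2fc) >= min_abs_log2fc
  structure(list(stage = stage %||% NA_character_, fit = fit,
                 up_in_a = r$feature_id[sig & r$log2fc > 0],
                 up_in_b = r$feature_id[sig & r$log2fc < 0],
                 tested = r$feature_id[!is.na(r$pvalue)]),
            class = "docseq_stage_de")
}

#' @export
print.docseq_stage_de <- function(x, ...) {
  cat(sprintf("stage %s: %d genes up in %s, %d up in the other group (of %d tested)\n",
              x$stage, length(x$up_in_a), x$fit$group_a, length(x$up_in_b),
              length(x$tested)))
  invisible(x)
}

#' Hypergeometric integration of stage DE with DOCS-associated genes
#'
#' For every stage, tests whether genes up in group A are enriched among
#' Bi-DOCS-associated genes and genes up in group B among
#' Fi-DOCS-associated genes (upper-tail hypergeometric on the tested-gene
#' universe), BH-adjusting across all stage x direction tests.
#'
#' @param stage_results list of `docseq_stage_de` objects.
#' @param docs_genes list with `bi` and `fi` character vectors of
#'   DOCS-associated gene ids (from [map_regions_to_genes()]).
#' @param universe gene universe; defaults to the union of tested genes.
#' @return Tibble: stage, direction, overlap/fold/p columns from
#'   [hypergeometric_gene_test()], and `fdr`.
#' @export
docs_expression_enrichment <- function(stage_results, docs_genes,
                                       universe = NULL) {
  if (inherits(stage_results, "docseq_stage_de")) {
    stage_results <- list(stage_results)
  }
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(stage_results, `[[`, "tested")))
  }
  if (!length(universe)) abort("empty gene universe")
  rows <- purrr::map(stage_results, function(sr) {
    bind_rows(
      dplyr::bind_cols(tibble(stage = sr$stage, direction = "up_in_A"),
                       hypergeometric_gene_test(docs_genes$bi, sr$up_in_a,
                                                universe)),
      dplyr::bind_cols(tibble(stage = sr$stage, direction = "up_in_B"),
                       hypergeometric_gene_test(docs_genes$fi, sr$up_in_b,
                                                universe)))
  }) |> bind_rows()
  rows$fdr <- bh_fdr(rows$hypergeom_p)
  rows
}

#' Enrichment of an up-regulated gene set in a target list
#'
#' Same contract as [hypergeometric_gene_test()] with an arbitrary
#' user-supplied target set (e.g. transcription-factor target genes).
#'
#' @param up_genes,target_genes,universe character vectors of gene ids.
#' @return One-row tibble from [hypergeometric_gene_test()].
#' @export
target_set_enrichment <- function(up_genes, target_genes, universe) {
  hypergeometric_gene_test(target_genes, up_genes, universe)
}
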