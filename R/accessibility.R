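#' Count fragments in atlas peaks by the midpoint rule
#'
#' A fragment is assigned to the single peak (if any) containing its
#' midpoint, `floor((start + end) / 2)`, under half-open convention, so each
#' fragment is counted at most once.
#'
#' @param fragments named list of region tibbles, one per sample.
#' @param atlas region tibble of disjoint peaks (error if overlapping); a
#'   `name` column provides the feature ids, otherwise coordinates are used.
#' @return Integer matrix (peaks x samples).
#' @export
count_fragments_in_peaks <- function(fragments, atlas) {
  validate_regions(atlas, what = "atlas")
  at <- arrange(atlas, .data$chrom, .data$start)
  same <- at$chrom[-1] == at$chrom[-nrow(at)]
  if (nrow(at) > 1 && any(at$start[-1][same] < at$end[-nrow(at)][same])) {
    abort("atlas must be merged (disjoint peaks)")
  }
  ids <- col_or(at, "name") %||% paste0(at$chrom, ":", format_coord(at$start), "-",
                             format_coord(at$end))
  counts <- matrix(0L, nrow(at), length(fragments),
                   dimnames = list(ids, names(fragments)))
  for (j in seq_along(fragments)) {
    fr <- fragments[[j]]
    mid <- floor((fr$start + fr$end) / 2)
    for (ch in unique(fr$chrom)) {
      ai <- which(at$chrom == ch)
      if (!length(ai)) next
      mi <- mid[fr$chrom == ch]
      k <- findInterval(mi, at$start[ai])
      inpk <- k >= 1 & mi < at$end[ai][pmax(k, 1)]
      tab <- tabulate(k[inpk], nbins = length(ai))
      counts[ai, j] <- counts[ai, j] + tab
    }
  }
  counts
}

#' Log2 counts-per-million normalization
#'
#' `log2(k / colsum * 1e6 + pseudocount)`; monotone in `k` within a column
#' and invariant to rescaling a column's counts.
#'
#' @param counts non-negative matrix (features x samples).
#' @param pseudocount added on the CPM scale (default 1, so a zero count
#'   maps to 0).
#' @return Numeric matrix of the same shape.
#' @export
normalize_log_cpm <- function(counts, pseudocount = 1) {
  cs <- colSums(counts)
  if (any(cs == 0)) {
    abort(paste("zero total counts for sample(s):",
                paste(colnames(counts)[cs == 0], collapse = ", ")))
  }
  log2(sweep(counts, 2, cs, "/") * 1e6 + pseudocount)
}

#' Sample-sample Spearman correlation with group summaries
#'
#' @param norm normalized matrix (features x samples).
#' @param samples optional sample sheet tibble with `sample_id` and `group`;
#'   when given, the summary includes the median between-group correlation
#'   (the iPSC-subtype similarity statistic).
#' @param method "spearman" (default) or "pearson".
#' @return A list: `cor` (samples x samples), `summary` tibble with
#'   median_rho (all off-diagonal), and median between-/within-group rho
#'   when groups are known. Constant columns yield NA correlations, which
#'   are excluded from summaries with a warning.
#' @export
correlation_matrix <- function(norm, samples = NULL, method = "spearman") {
  if (ncol(norm) < 2) abort("need at least 2 samples")
  cc <- suppressWarnings(cor(norm, method = method))
  diag(cc) <- 1
  off <- cc[lower.tri(cc)]
  if (anyNA(off)) warn("constant sample(s): undefined correlations excluded")
  summ <- tibble(median_rho = median(off, na.rm = TRUE))
  if (!is.null(samples)) {
    grp <- samples$group[match(colnames(norm), samples$sample_id)]
    between <- outer(grp, grp, "!=")[lower.tri(cc)]
    summ$median_between_rho <- median(off[between], na.rm = TRUE)
    summ$median_within_rho <- median(off[!between], na.rm = TRUE)
  }
  list(cor = cc, summary = summ)
}

#' PCA embedding of samples over top-variance features
#'
#' Features are ranked by variance across samples, the matrix is centered
#' per feature (no scaling), and samples are projected onto the principal
#' axes.
#'
#' @param norm normalized matrix (features x samples).
#' @param n_top_features number of top-variance features (all if fewer
#'   available).
#' @param n_components number of components to return.
#' @return A list: `scores` tibble (sample_id, PC1..), `variance_fraction`
#'   (non-increasing, sums to <= 1).
#' @export
pca_embedding <- function(norm, n_top_features = 5000, n_components = 10) {
  if (ncol(norm) < 2) abort("need at least 2 samples")
  v <- apply(norm, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_features, nrow(norm)))]
  x <- t(norm[keep, , drop = FALSE])
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- as_tibble(p$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(norm)), scores)
  vf <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(scores = scores, variance_fraction = vf)
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Distance is `1 - Spearman rho`; linkage is average. Samples are ordered
#' lexicographically before clustering so ties break deterministically.
#'
#' @param norm normalized matrix (features x samples).
#' @return A list: `hclust` (stats::hclust object) and `newick` (the tree
#'   as a Newick string, via ape when available).
#' @export
hierarchical_clustering <- function(norm) {
  norm <- norm[, order(colnames(norm)), drop = FALSE]
  cc <- correlation_matrix(norm)$cor
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  nwk <- if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc))
  } else NA_character_
  list(hclust = hc, newick = nwk)
}
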