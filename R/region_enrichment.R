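#' Width- and chromosome-matched random regions
#'
#' For each query interval, draws one random interval of identical width on
#' the same chromosome, start uniform on `[0, L - w]`. Sampled regions may
#' overlap each other. Regions overlapping `exclude` are resampled (bounded
#' retries).
#'
#' @param query region tibble.
#' @param genome a [genome()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param exclude optional region tibble the null must avoid.
#' @param max_tries resample budget per interval.
#' @return A region tibble with the same widths per chromosome as `query`.
#' @export
sample_matched_random_regions <- function(query, genome, seed = NULL,
                                          exclude = NULL, max_tries = 100L) {
  validate_regions(query, genome, what = "query")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  glen <- setNames(genome$length, genome$chrom)
  w <- query$end - query$start
  L <- glen[query$chrom]
  if (any(w > L)) abort("query interval wider than its chromosome")
  start <- floor(runif(nrow(query), 0, L - w + 1))
  out <- tibble(chrom = query$chrom, start = start, end = start + w)
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- merge_regions(exclude)
    for (t in seq_len(max_tries)) {
      bad <- overlaps_any(out, ex)
      if (!any(bad)) break
      ns <- floor(runif(sum(bad), 0, L[bad] - w[bad] + 1))
      out$start[bad] <- ns
      out$end[bad] <- ns + w[bad]
    }
    if (any(overlaps_any(out, ex))) {
      i <- which(overlaps_any(out, ex))[1]
      abort(sprintf("could not avoid excluded regions for interval %d", i))
    }
  }
  out
}

#' Permutation enrichment of a query region set in an annotation
#'
#' Compares the observed overlap count with a null distribution obtained by
#' redrawing the query `n_perm` times as width/chromosome-matched random
#' regions. `log2FE = log2((obs + pc) / (mean(null) + pc))`; the empirical
#' p (one-sided, enrichment) is `(1 + #{null >= obs}) / (1 + n_perm)`.
#'
#' @param query region tibble.
#' @param annotation region tibble (merged internally).
#' @param genome a [genome()].
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param pseudocount added to both numerator and denominator of the fold
#'   enrichment so it stays finite.
#' @param query_label,annotation_label,cell_type optional labels carried
#'   into the result row.
#' @return A one-row tibble: query_label, annotation_label, cell_type,
#'   n_query, observed, null_mean, null_sd, n_perm, log2fe, empirical_p.
#' @export
permutation_enrichment <- function(query, annotation, genome,
                                   n_perm = 1000, seed = 1, pseudocount = 1,
                                   query_label = "query",
                                   annotation_label = "annotation",
                                   cell_type = NA_character_) {
  if (n_perm < 10) abort("n_perm must be >= 10")
  validate_regions(query, genome, what = "query")
  ann <- merge_regions(annotation)
  idx <- split(ann[c("start", "end")], ann$chrom)
  count_fast <- function(chrom, start, end) {
    total <- 0L
    for (ch in unique(chrom)) {
      a <- idx[[ch]]
      if (is.null(a)) next
      qi <- chrom == ch
      s <- start[qi]; e <- end[qi]
      k <- findInterval(e - 1, a$start)
      total <- total + sum(k >= 1 & a$end[pmax(k, 1)] > s)
    }
    total
  }
  observed <- count_fast(query$chrom, query$start, query$end)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  glen <- setNames(genome$length, genome$chrom)
  w <- query$end - query$start
  L <- glen[query$chrom]
  if (any(w > L)) abort("query interval wider than its chromosome")
  # all permutations drawn at once, one block per chromosome
  null <- numeric(n_perm)
  for (ch in unique(query$chrom)) {
    qi <- query$chrom == ch
    n_ch <- sum(qi)
    s <- floor(matrix(runif(n_ch * n_perm), n_ch, n_perm) *
                 (L[qi] - w[qi] + 1))
    a <- idx[[ch]]
    if (is.null(a)) next
    e <- s + w[qi]
    k <- findInterval(e - 1, a$start)
    hit <- k >= 1 & a$end[pmax(k, 1)] > s
    null <- null + colSums(matrix(hit, n_ch, n_perm))
  }
  tibble(query_label = query_label, annotation_label = annotation_label,
         cell_type = cell_type, n_query = nrow(query),
         observed = observed, null_mean = mean(null), null_sd = sd(null),
         n_perm = n_perm,
         log2fe = log2((observed + pseudocount) /
                         (mean(null) + pseudocount)),
         empirical_p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Batch enrichment over an annotation grid with batch-wide FDR
#'
#' Runs [permutation_enrichment()] for one query against every
#' (annotation_label, cell_type) in a segmentation table and BH-adjusts the
#' empirical p values across the whole batch.
#'
#' @param query region tibble.
#' @param states segmentation tibble (cell_type, state, chrom, start, end),
#'   as from [simulate_state_annotations()].
#' @param genome a [genome()].
#' @param n_perm,pseudocount see [permutation_enrichment()].
#' @param seed batch seed; each cell of the grid gets a distinct derived
#'   seed so results do not depend on grid order.
#' @param query_label label carried into the rows.
#' @return Tibble of enrichment rows with an `fdr` column.
#' @export
enrichment_batch <- function(query, states, genome, n_perm = 1000,
                             seed = 1, pseudocount = 1,
                             query_label = "query") {
  grid <- distinct(states[, c("cell_type", "state")]) |>
    arrange(.data$cell_type, .data$state)
  res <- purrr::pmap(grid, function(cell_type, state) {
    ann <- state_regions(states, cell_type, state)
    permutation_enrichment(
      query, ann, genome, n_perm = n_perm,
      seed = stage_seed(seed, paste(query_label, cell_type, state)),
      pseudocount = pseudocount, query_label = query_label,
      annotation_label = state, cell_type = cell_type)
  }) |> bind_rows()
  res$fdr <- bh_fdr(res$empirical_p)
  res
}

#' Aggregate enrichment across cell types within groups
#'
#' Averages log2FE and FDR over the member cell types of each
#' (annotation, group) and applies the compound significance rule:
#' mean FDR < `fdr_max` and mean log2FE > 0.
#'
#' @param results enrichment tibble with `fdr` (e.g. [enrichment_batch()]).
#' @param cell_type_groups tibble (cell_type, group) assigning every cell
#'   type to exactly one group.
#' @param fdr_max significance threshold on the mean FDR.
#' @return Tibble: annotation_label, group, mean_log2fe, mean_fdr,
#'   n_cell_types, significant.
#' @export
aggregate_group_enrichment <- function(results, cell_type_groups,
                                       fdr_max = 0.05) {
  if (!"fdr" %in% names(results)) abort("results must carry batch FDR")
  un <- setdiff(unique(results$cell_type), cell_type_groups$cell_type)
  if (length(un)) {
    abort(paste("cell type(s) without a group:", paste(un, collapse = ", ")))
  }
  results |>
    left_join(cell_type_groups, by = "cell_type") |>
    group_by(.data$annotation_label, .data$group) |>
    summarise(mean_log2fe = mean(.data$log2fe),
              mean_fdr = mean(.data$fdr),
              n_cell_types = dplyr::n_distinct(.data$cell_type),
              .groups = "drop") |>
    mutate(significant = .data$mean_fdr < fdr_max & .data$mean_log2fe > 0)
}

#' Directional log2FE ratio between two query sets
#'
#' Per annotation (optionally within groups), the difference of
#' cell-type-mean log2FE between query A and query B — the log2 of the
#' fold-enrichment ratio. Positive values favour query A; swapping the
#' queries negates every ratio.
#'
#' @param res_a,res_b enrichment tibbles for the two queries, evaluated on
#'   an identical (annotation_label, cell_type) grid.
#' @param by grouping columns for the mean (default annotation only).
#' @return Tibble with `log2fe_ratio` per annotation (and extra `by`
#'   columns).
#' @export
log2fe_ratio <- function(res_a, res_b, by = "annotation_label") {
  key <- function(r) paste(r$annotation_label, r$cell_type)
  missing_a <- setdiff(key(res_b), key(res_a))
  missing_b <- setdiff(key(res_a), key(res_b))
  if (length(missing_a) || length(missing_b)) {
    abort(paste0("annotation/cell-type grids differ; missing cells: ",
                 paste(c(missing_a, missing_b), collapse = "; ")))
  }
  ma <- res_a |> group_by(across(all_of(by))) |>
    summarise(mean_a = mean(.data$log2fe), .groups = "drop")
  mb <- res_b |> group_by(across(all_of(by))) |>
    summarise(mean_b = mean(.data$log2fe), .groups = "drop")
  left_join(ma, mb, by = by) |>
    mutate(log2fe_ratio = .data$mean_a - .data$mean_b) |>
    select(all_of(by), "log2fe_ratio")
}
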