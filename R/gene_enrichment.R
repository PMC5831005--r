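#' Assign regulatory domains to genes (basal plus extension)
#'
#' Each gene gets a basal window around its TSS (`basal_up` bp upstream,
#' `basal_down` bp downstream, oriented by strand) which is then extended
#' outward to the nearest neighbouring basal domain, capped at
#' `extension_max` and clipped to the chromosome. Domains of different
#' genes may overlap (a region can regulate several genes).
#'
#' @param genes tibble with gene_id, chrom, tss, strand.
#' @param genome a [genome()].
#' @param basal_up,basal_down,extension_max rule parameters in bp (defaults
#'   5 kb / 1 kb / 1 Mb).
#' @return Tibble: gene_id, chrom, start, end (the domain),
#'   basal_start, basal_end.
#' @export
assign_regulatory_domains <- function(genes, genome, basal_up = 5000,
                                      basal_down = 1000,
                                      extension_max = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  glen <- setNames(genome$length, genome$chrom)
  if (any(!genes$chrom %in% genome$chrom) ||
      any(genes$tss < 0 | genes$tss >= glen[genes$chrom])) {
    abort("gene TSS outside the genome")
  }
  plus <- genes$strand != "-"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(0, basal_start)
  basal_end <- pmin(glen[genes$chrom], basal_end)

  d <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
              tss = genes$tss,
              basal_start = basal_start, basal_end = basal_end) |>
    arrange(.data$chrom, .data$basal_start, .data$basal_end)
  d2 <- d |>
    group_by(.data$chrom) |>
    mutate(
      left_bound = dplyr::lag(cummax(.data$basal_end), default = -Inf),
      right_bound = rev(cummin(rev(dplyr::lead(.data$basal_start,
                                               default = Inf)))),
      start = pmax(0, .data$tss - extension_max,
                   pmin(.data$basal_start, .data$left_bound)),
      end = pmin(glen[.data$chrom[1]], .data$tss + extension_max,
                 pmax(.data$basal_end, .data$right_bound))) |>
    ungroup()
  d2 |>
    mutate(start = unname(pmin(.data$start, .data$basal_start)),
           end = unname(pmax(.data$end, .data$basal_end)),
           basal_start = unname(.data$basal_start),
           basal_end = unname(.data$basal_end)) |>
    select("gene_id", "chrom", "start", "end", "basal_start", "basal_end")
}

#' Associate regions with genes by the midpoint rule
#'
#' A region maps to gene g iff its midpoint lies inside g's regulatory
#' domain; one region may map to several genes.
#'
#' @param regions region tibble (a `name` column provides region ids).
#' @param domains domain tibble from [assign_regulatory_domains()].
#' @return Tibble of (region_id, gene_id) pairs; the attribute
#'   `associated_genes` lists genes with >= 1 region.
#' @export
map_regions_to_genes <- function(regions, domains) {
  validate_regions(regions, what = "regions")
  rid <- col_or(regions, "name") %||% paste0(regions$chrom, ":",
                                  format_coord(regions$start), "-",
                                  format_coord(regions$end))
  mid <- floor((regions$start + regions$end) / 2)
  out <- purrr::map(unique(regions$chrom), function(ch) {
    ri <- which(regions$chrom == ch)
    dd <- domains[domains$chrom == ch, ]
    if (!nrow(dd)) return(NULL)
    hits <- purrr::map(ri, function(i) {
      g <- dd$gene_id[dd$start <= mid[i] & mid[i] < dd$end]
      if (length(g)) tibble(region_id = rid[i], gene_id = g)
    })
    bind_rows(hits)
  }) |> bind_rows()
  if (!nrow(out)) out <- tibble(region_id = character(),
                                gene_id = character())
  attr(out, "associated_genes") <- unique(out$gene_id)
  out
}

#' Binomial region test for one term
#'
#' With n regions total and the term's merged domain union covering genome
#' fraction pi, the number of region midpoints falling in the union is
#' Binomial(n, pi) under the null; p is the upper tail `P(X >= k)` and the
#' fold enrichment `k / (n * pi)`.
#'
#' @param term_genes character vector of the term's gene ids.
#' @param regions region tibble (all tested regions).
#' @param domains domain tibble.
#' @param genome a [genome()].
#' @return One-row tibble: n_regions, k_regions, pi_term, region_fold,
#'   binomial_p.
#' @export
binomial_region_test <- function(term_genes, regions, domains, genome) {
  dd <- domains[domains$gene_id %in% term_genes, ]
  n <- nrow(regions)
  if (!nrow(dd)) {
    return(tibble(n_regions = n, k_regions = 0L, pi_term = 0,
                  region_fold = NA_real_, binomial_p = 1))
  }
  un <- merge_regions(dd[, c("chrom", "start", "end")])
  pi_term <- coverage_fraction(un, genome)
  mid <- floor((regions$start + regions$end) / 2)
  pts <- tibble(chrom = regions$chrom, start = mid, end = mid + 1)
  k <- count_overlaps(pts, un)
  if (pi_term == 0 && k > 0) abort("internal: hits in zero-coverage term")
  tibble(n_regions = n, k_regions = k, pi_term = pi_term,
         region_fold = if (pi_term > 0) k / (n * pi_term) else NA_real_,
         binomial_p = pbinom(k - 1, n, pi_term, lower.tail = FALSE))
}

#' Hypergeometric gene-set test
#'
#' With a universe of N genes, K in the term and n hit genes, the overlap
#' k is hypergeometric under the null; p is the upper tail `P(X >= k)` and
#' the fold enrichment `(k * N) / (K * n)`.
#'
#' @param term_genes,hit_genes,universe character vectors of gene ids
#'   (term and hits are intersected with the universe).
#' @return One-row tibble: universe_n, term_k, hits_n, overlap_k,
#'   gene_fold, hypergeom_p.
#' @export
hypergeometric_gene_test <- function(term_genes, hit_genes, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (!N) abort("empty gene universe")
  K <- length(intersect(term_genes, universe))
  hits <- intersect(hit_genes, universe)
  n <- length(hits)
  k <- length(intersect(term_genes, hits))
  tibble(universe_n = N, term_k = K, hits_n = n, overlap_k = k,
         gene_fold = if (K > 0 && n > 0) (k * N) / (K * n) else NA_real_,
         hypergeom_p = if (K == 0 || n == 0) 1 else
           phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Term enrichment with the compound significance rule
#'
#' Runs the binomial region test and the hypergeometric gene test for every
#' term, BH-adjusts each test family separately across terms, and flags
#' terms significant when both FDRs are below `fdr_max` and both fold
#' enrichments exceed `min_fold`.
#'
#' @param terms tibble (term_id, gene_id).
#' @param regions region tibble of the query (e.g. Bi-DOCS).
#' @param domains domain tibble from [assign_regulatory_domains()].
#' @param genome a [genome()].
#' @param universe gene universe for the hypergeometric test.
#' @param fdr_max,min_fold compound thresholds (defaults 0.05 and 2).
#' @return Tibble, one row per term, sorted by binomial FDR, with columns
#'   from both tests plus binomial_fdr, hypergeom_fdr, significant.
#' @export
call_enriched_terms <- function(terms, regions, domains, genome, universe,
                                fdr_max = 0.05, min_fold = 2) {
  assoc <- map_regions_to_genes(regions, domains)
  hit_genes <- attr(assoc, "associated_genes")
  ids <- unique(terms$term_id)
  res <- purrr::map(ids, function(t) {
    tg <- terms$gene_id[terms$term_id == t]
    dplyr::bind_cols(
      tibble(term_id = t),
      binomial_region_test(tg, regions, domains, genome),
      hypergeometric_gene_test(tg, hit_genes, universe))
  }) |> bind_rows()
  res$binomial_fdr <- bh_fdr(res$binomial_p)
  res$hypergeom_fdr <- bh_fdr(res$hypergeom_p)
  res |>
    mutate(significant = .data$binomial_fdr < fdr_max &
             .data$hypergeom_fdr < fdr_max &
             !is.na(.data$region_fold) & .data$region_fold > min_fold &
             !is.na(.data$gene_fold) & .data$gene_fold > min_fold) |>
    arrange(.data$binomial_fdr)
}

#' Fisher exact test on a 2x2 overlap table
#'
#' Two-sided p by the point-probability method (all tables with probability
#' at most the observed one); the odds ratio reported is the sample OR
#' `(a d) / (b c)` (Inf or 0 when an off-diagonal cell is 0). When a
#' margin is zero the table carries no information: p = 1 and the OR is NA.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: a, b, c, d, odds_ratio, fisher_p.
#' @export
fisher_overlap_test <- function(table) {
  m <- matrix(as.numeric(table), 2, 2)
  if (any(m < 0) || any(m != floor(m))) {
    abort("2x2 table must hold non-negative integers")
  }
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  margin_zero <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  or <- if (margin_zero) NA_real_ else (a * d) / (b * c)
  p <- if (margin_zero) 1 else fisher.test(m)$p.value
  tibble(a = a, b = b, c = c, d = d, odds_ratio = or, fisher_p = p)
}

#' Fraction of a gene set contained in a reference set
#' @param set_a,reference character vectors of gene ids.
#' @return `|A intersect ref| / |A|`.
#' @export
gene_set_overlap_fraction <- function(set_a, reference) {
  set_a <- unique(set_a)
  if (!length(set_a)) abort("empty gene set")
  length(intersect(set_a, reference)) / length(set_a)
}
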