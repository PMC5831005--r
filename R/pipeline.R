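#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Exactly one
#' input source must be present: a `simulation` block (arguments for
#' [sim_config()]) or an `inputs` block with paths to real data
#' (`counts`, `samples`, and optionally `peaks`, `chrom_sizes`).
#'
#' @param x a YAML file path or a named list.
#' @return A validated list of class `docseq_pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    seed = 1L,
    out_dir = "docseq_out",
    simulation = NULL,
    inputs = NULL,
    thresholds = list())
  cfg <- modifyList(defaults, cfg)
  thr_defaults <- list(fdr = 0.05, min_lfc = 0.5, n_perm = 200,
                       basal_up = 5000, basal_down = 1000,
                       extension_max = 1e6, min_fold = 2)
  cfg$thresholds <- modifyList(thr_defaults, cfg$thresholds)
  if (is.null(cfg$simulation) && is.null(cfg$inputs)) {
    abort("config must contain a `simulation` block or an `inputs` block",
          class = "docseq_config_error")
  }
  with(cfg$thresholds, {
    if (fdr <= 0 || min_lfc < 0 || n_perm < 10) {
      abort("invalid thresholds", class = "docseq_config_error")
    }
  })
  structure(cfg, class = "docseq_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data simulation (or loading), QC
#' (correlation + PCA), NB differential testing and DOCS calling,
#' permutation region-set enrichment with grouped aggregation and the
#' Bi-vs-Fi log2FE ratio, regulatory-domain term enrichment, and stage-wise
#' expression integration. Every output file is recorded in a manifest with
#' its MD5 hash; rerunning with the same config reproduces identical
#' hashes.
#'
#' @param config a [pipeline_config()], a list, or a YAML path.
#' @param out_dir output directory (overrides the config when given).
#' @return A list: `manifest` tibble (file, md5), `log` character vector,
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "docseq_pipeline_config")) config else
    pipeline_config(config)
  out <- out_dir %||% cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  thr <- cfg$thresholds
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[docseq] ", msg)
  }
  t0 <- Sys.time()
  stage_time <- function(name) {
    say("%s (%.1fs elapsed)", name, as.numeric(Sys.time() - t0, "secs"))
  }

  results <- list()
  if (!is.null(cfg$simulation)) {
    stage_time("simulate")
    scfg <- do.call(sim_config, modifyList(list(seed = cfg$seed),
                                           cfg$simulation))
    sim <- simulate_study(scfg)
    results$sim <- sim
    counts <- sim$atac$counts
    samples <- sim$atac$samples
    atlas <- sim$atlas
    gnm <- sim$genome
    write_bed(atlas, file.path(out, "peaks.bed"))
    readr::write_tsv(counts_to_tsv(counts), file.path(out, "counts_atac.tsv"))
    readr::write_tsv(samples, file.path(out, "sample_sheet.tsv"))
    jsonlite::write_json(
      list(peaks = sim$truth$peaks,
           size_factors = sim$truth$size_factors,
           expression = sim$truth$expression,
           enriched = sim$truth$enriched,
           coupled_term = sim$truth$coupled_term),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    stage_time("load inputs")
    counts_df <- readr::read_tsv(cfg$inputs$counts, col_types =
                                   readr::cols(), progress = FALSE)
    counts <- as.matrix(counts_df[, -1])
    rownames(counts) <- counts_df[[1]]
    samples <- readr::read_tsv(cfg$inputs$samples,
                               col_types = readr::cols(), progress = FALSE)
    atlas <- if (!is.null(cfg$inputs$peaks)) read_bed(cfg$inputs$peaks)
    gnm <- if (!is.null(cfg$inputs$chrom_sizes))
      read_chrom_sizes(cfg$inputs$chrom_sizes)
  }

  stage_time("qc")
  norm <- normalize_log_cpm(counts)
  cc <- correlation_matrix(norm, samples)
  readr::write_tsv(as_tibble(cc$cor, rownames = "sample_id"),
                   file.path(out, "correlation.tsv"))
  readr::write_tsv(cc$summary, file.path(out, "correlation_summary.tsv"))
  pca <- pca_embedding(norm)
  readr::write_tsv(pca$scores, file.path(out, "pca_scores.tsv"))
  results$qc <- list(correlation = cc, pca = pca)

  stage_time("differential")
  fit <- nb_wald_test(counts, samples)
  docs <- call_docs(fit, coords = if (!is.null(atlas)) atlas,
                    fdr_max = thr$fdr, min_abs_log2fc = thr$min_lfc)
  readr::write_tsv(tidy(fit), file.path(out, "differential.tsv"))
  docs_tbl <- tidy(docs)
  if (all(c("chrom", "start", "end") %in% names(docs_tbl)) &&
      nrow(docs_tbl)) {
    write_bed(tibble(chrom = docs_tbl$chrom, start = docs_tbl$start,
                     end = docs_tbl$end, name = docs_tbl$direction,
                     score = round(-log10(pmax(docs_tbl$fdr, 1e-300)), 3)),
              file.path(out, "docs.bed"))
  }
  results$fit <- fit; results$docs <- docs
  say("DOCS: %d (%d Bi / %d Fi)", docs$n_docs, docs$n_bi, docs$n_fi)

  if (!is.null(cfg$simulation)) {
    sim <- results$sim
    stage_time("region enrichment")
    bi_rs <- docs$bi[, c("chrom", "start", "end")]
    fi_rs <- docs$fi[, c("chrom", "start", "end")]
    if (nrow(bi_rs) >= 10 && nrow(fi_rs) >= 10) {
      res_bi <- enrichment_batch(bi_rs, sim$annotations$states, gnm,
                                 n_perm = thr$n_perm, seed = cfg$seed,
                                 query_label = "Bi-DOCS")
      res_fi <- enrichment_batch(fi_rs, sim$annotations$states, gnm,
                                 n_perm = thr$n_perm, seed = cfg$seed,
                                 query_label = "Fi-DOCS")
      grouped <- aggregate_group_enrichment(res_bi,
                                            sim$annotations$groups,
                                            fdr_max = thr$fdr)
      ratio <- log2fe_ratio(res_bi, res_fi)
      readr::write_tsv(bind_rows(res_bi, res_fi),
                       file.path(out, "enrich.tsv"))
      readr::write_tsv(grouped, file.path(out, "enrich_grouped.tsv"))
      readr::write_tsv(ratio, file.path(out, "enrich_ratio.tsv"))
      results$enrichment <- list(bi = res_bi, fi = res_fi,
                                 grouped = grouped, ratio = ratio)
    } else {
      say("too few DOCS for region enrichment; stage skipped")
    }

    stage_time("term enrichment")
    domains <- assign_regulatory_domains(sim$genes, gnm,
                                         basal_up = thr$basal_up,
                                         basal_down = thr$basal_down,
                                         extension_max = thr$extension_max)
    terms_res <- call_enriched_terms(sim$terms, bi_rs, domains, gnm,
                                     universe = sim$genes$gene_id,
                                     fdr_max = thr$fdr,
                                     min_fold = thr$min_fold)
    readr::write_tsv(terms_res, file.path(out, "terms.tsv"))
    results$terms <- terms_res

    stage_time("expression integration")
    assoc_bi <- map_regions_to_genes(docs$bi, domains)
    assoc_fi <- map_regions_to_genes(docs$fi, domains)
    docs_genes <- list(bi = attr(assoc_bi, "associated_genes"),
                       fi = attr(assoc_fi, "associated_genes"))
    de <- lapply(names(sim$rna$stages), function(stg) {
      s <- sim$rna$stages[[stg]]
      stage_differential_expression(s$counts, s$samples, stage = stg,
                                    fdr_max = thr$fdr)
    })
    integ <- docs_expression_enrichment(de, docs_genes)
    readr::write_tsv(integ, file.path(out, "de_integration.tsv"))
    de_report <- bind_rows(lapply(de, function(d) {
      mutate(tidy(d$fit), stage = d$stage)
    }))
    readr::write_tsv(de_report, file.path(out, "de_report.tsv"))
    results$expression <- list(stages = de, integration = integ)
  }

  stage_time("manifest")
  files <- sort(list.files(out, full.names = TRUE))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  writeLines(log, file.path(out, "run.log"))
  list(manifest = manifest, log = log, results = results)
}

counts_to_tsv <- function(counts) {
  dplyr::bind_cols(tibble(feature_id = rownames(counts)),
                   as_tibble(counts))
}
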