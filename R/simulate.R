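#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator: a desk-scale stand-in
#' for a two-group iPSC ATAC-seq study (group "A" emulating beta-cell-derived
#' lines, "B" fibroblast-derived) with chromatin-state segmentations, a gene
#' model with term sets, and stage-wise RNA counts coupled to the planted
#' accessibility effects. All downstream acceptance testing is done against
#' the serialized truth this generator emits.
#'
#' @param seed integer master seed. Every stage derives its own child stream
#'   from `seed` and the stage name, so adding a stage never perturbs
#'   earlier stages.
#' @param n_chroms,chrom_length_bp genome shape ("chr1".."chrN", equal
#'   lengths).
#' @param n_peaks number of non-overlapping atlas peaks.
#' @param peak_width length-2 (min, max) uniform peak width in bp (>= 50).
#' @param n_samples_per_group length-2 integer: ATAC samples in groups A, B.
#' @param frac_differential fraction of peaks with a planted group effect.
#' @param effect_log2fc planted |log2FC| magnitude for differential peaks.
#' @param prop_up_in_a fraction of differential peaks more open in group A
#'   (positive log2FC).
#' @param base_mean_meanlog,base_mean_sdlog lognormal parameters of per-peak
#'   expected counts (depth).
#' @param dispersion per-peak NB dispersion alpha: a single number for a
#'   constant alpha, or `c(shape =, mean =)` for Gamma-distributed alpha.
#' @param size_factor_sdlog lognormal sd of per-sample library size factors
#'   (geometric mean forced to 1).
#' @param n_cell_types,n_states chromatin-state segmentation shape.
#' @param state_coverage numeric vector (recycled to `n_states`) of per-state
#'   genome fractions; must sum to <= 1.
#' @param state_segment_bp mean length of a state segment.
#' @param enrichment_rho relative placement rate of differential peaks inside
#'   the designated enriched state (state "S1" of the first cell type):
#'   a differential peak falls inside it with probability
#'   `min(1, rho * coverage)`, otherwise in its complement; non-differential
#'   peaks are placed uniformly.
#' @param n_genes,n_terms,term_size gene model and term-set shape
#'   (`term_size` = (min, max) genes per term).
#' @param n_rna_samples_per_group RNA samples per group at each stage.
#' @param stages stage labels for the expression arm.
#' @param coupling probability that a gene whose TSS was planted next to a
#'   differential peak is differentially expressed in the matching direction.
#' @param de_log2fc planted expression |log2FC| for coupled genes.
#' @param frac_de_background fraction of background genes DE irrespective of
#'   any peak.
#' @param rna_base_mean_meanlog,rna_base_mean_sdlog,rna_dispersion RNA count
#'   model parameters (same NB parameterization as ATAC).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length_bp = 1e7,
                       n_peaks = 10000L, peak_width = c(200L, 800L),
                       n_samples_per_group = c(5L, 5L),
                       frac_differential = 0.1,
                       effect_log2fc = 1.5,
                       prop_up_in_a = 0.58,
                       base_mean_meanlog = log(50), base_mean_sdlog = 1,
                       dispersion = c(shape = 4, mean = 0.15),
                       size_factor_sdlog = 0.2,
                       n_cell_types = 4L, n_states = 5L,
                       state_coverage = c(0.10, 0.08, 0.08, 0.06, 0.05),
                       state_segment_bp = 20000,
                       enrichment_rho = 4,
                       n_genes = 2000L, n_terms = 50L,
                       term_size = c(20L, 40L),
                       n_rna_samples_per_group = c(4L, 4L),
                       stages = c("DE", "PP"),
                       coupling = 0.8,
                       de_log2fc = 1.0,
                       frac_de_background = 0.02,
                       rna_base_mean_meanlog = log(100),
                       rna_base_mean_sdlog = 1,
                       rna_dispersion = 0.1) {
  cfg <- as.list(environment())
  cfg$state_coverage <- rep_len(state_coverage, n_states)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_chroms < 1) abort("n_chroms must be >= 1")
    if (chrom_length_bp <= 0) abort("chrom_length_bp must be positive")
    if (n_peaks < 1) abort("n_peaks must be >= 1")
    if (peak_width[1] < 50) abort("peak widths must be >= 50 bp")
    if (peak_width[2] < peak_width[1]) abort("peak_width must be (min, max)")
    for (f in c(frac_differential, prop_up_in_a, coupling,
                frac_de_background)) {
      if (f < 0 || f > 1) abort("fractions must lie in [0, 1]")
    }
    if (any(state_coverage < 0) || sum(state_coverage) > 1) {
      abort("state coverages must be non-negative and sum to <= 1")
    }
    if (any(unlist(dispersion) <= 0)) abort("dispersion must be > 0")
    if (enrichment_rho <= 0) abort("enrichment_rho must be > 0")
  })
  invisible(cfg)
}

# Deterministic child seed per stage: polynomial rolling hash of the stage
# name folded into the master seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 31 + h) %% 2147483629 + 1)
}

with_stage_seed <- function(cfg, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stage_seed(cfg$seed, stage))
  expr
}

#' Simulate a genome
#' @param cfg a [sim_config()].
#' @return A [genome()] with chromosomes "chr1".."chrN".
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  genome(setNames(rep(cfg$chrom_length_bp, cfg$n_chroms),
                  paste0("chr", seq_len(cfg$n_chroms))))
}

#' Simulate chromatin-state segmentations
#'
#' Per cell type, each chromosome is cut into segments of approximately
#' `state_segment_bp`; segments are assigned to states so that state k tiles
#' about `state_coverage[k]` of the genome (the remainder is unannotated).
#' Cell types are assigned to groups emulating pluripotency / germ-layer
#' panels: "pluripotent" (first cell type), then "endoderm", "mesoderm",
#' "ectoderm", "other" cycling.
#'
#' @param cfg a [sim_config()].
#' @param genome a [genome()].
#' @return A list with `states`: tibble (cell_type, state, chrom, start,
#'   end); `groups`: tibble (cell_type, group); `enriched`: the designated
#'   enriched annotation (cell_type, state).
#' @export
simulate_state_annotations <- function(cfg, genome) {
  validate_sim_config(cfg)
  cell_types <- paste0("CT", seq_len(cfg$n_cell_types))
  states <- paste0("S", seq_len(cfg$n_states))
  grp <- c("pluripotent", "endoderm", "mesoderm", "ectoderm", "other")
  groups <- tibble(cell_type = cell_types,
                   group = grp[(seq_along(cell_types) - 1) %% 5 + 1])
  seg <- with_stage_seed(cfg, "states", {
    purrr::map(cell_types, function(ct) {
      purrr::map(seq_len(nrow(genome)), function(ci) {
        L <- genome$length[ci]
        n_seg <- max(2L, ceiling(L / cfg$state_segment_bp))
        cuts <- sort(runif(n_seg - 1, 0, L))
        start <- floor(c(0, cuts))
        end <- floor(c(cuts, L))
        keep <- end > start
        start <- start[keep]; end <- end[keep]
        # state label per segment, probability = target coverage
        p <- c(cfg$state_coverage, 1 - sum(cfg$state_coverage))
        lab <- sample(c(states, NA), length(start), replace = TRUE, prob = p)
        tibble(cell_type = ct, state = lab, chrom = genome$chrom[ci],
               start = start, end = end)
      }) |> bind_rows()
    }) |> bind_rows() |> filter(!is.na(.data$state))
  })
  list(states = seg, groups = groups,
       enriched = list(cell_type = cell_types[1], state = "S1"))
}

#' Extract one annotation's region set from a segmentation table
#' @param states the `states` tibble from [simulate_state_annotations()].
#' @param cell_type,state labels selecting the annotation.
#' @return A region tibble.
#' @export
state_regions <- function(states, cell_type, state) {
  ct <- cell_type; st <- state
  states |>
    filter(.data$cell_type == ct, .data$state == st) |>
    select("chrom", "start", "end")
}

#' Simulate a peak atlas with planted differential peaks
#'
#' Places `n_peaks` non-overlapping peaks. A fraction `frac_differential` is
#' flagged differential and assigned a true log2FC of magnitude
#' `effect_log2fc`, with a `prop_up_in_a` share positive (more open in group
#' A). When `enriched_regions` is supplied, each differential peak is placed
#' fully inside that annotation with probability
#' `min(1, enrichment_rho * coverage)` and fully outside otherwise;
#' non-differential peaks are placed uniformly.
#'
#' @param cfg a [sim_config()].
#' @param genome a [genome()].
#' @param enriched_regions optional region tibble of the designated enriched
#'   annotation.
#' @return A list with `atlas` (region tibble with `name` = peak id) and
#'   `truth` (tibble: peak_id, differential, log2fc, in_enriched).
#' @export
simulate_peak_atlas <- function(cfg, genome, enriched_regions = NULL) {
  validate_sim_config(cfg)
  with_stage_seed(cfg, "atlas", {
    n <- cfg$n_peaks
    widths <- floor(runif(n, cfg$peak_width[1], cfg$peak_width[2] + 1))
    n_diff <- round(cfg$frac_differential * n)
    differential <- c(rep(TRUE, n_diff), rep(FALSE, n - n_diff))
    sign <- rep(0, n)
    if (n_diff > 0) {
      n_up <- round(cfg$prop_up_in_a * n_diff)
      sign[seq_len(n_diff)] <- sample(c(rep(1, n_up), rep(-1, n_diff - n_up)))
    }
    log2fc <- sign * cfg$effect_log2fc

    enr <- if (!is.null(enriched_regions)) merge_regions(enriched_regions)
    cov <- if (is.null(enr)) 0 else
      sum(enr$end - enr$start) / effective_size(genome)
    p_in <- min(1, cfg$enrichment_rho * cov)
    # differential peaks follow the in/out rule; others are uniform
    mode <- rep("uniform", n)
    if (!is.null(enr)) {
      mode[differential] <- ifelse(runif(sum(differential)) < p_in,
                                   "in", "out")
    }
    want_in <- mode == "in"

    placed <- place_nonoverlapping(widths, mode, genome, enr)
    atlas <- tibble(chrom = placed$chrom, start = placed$start,
                    end = placed$end,
                    name = sprintf("peak_%05d", seq_len(n)))
    truth <- tibble(peak_id = atlas$name, differential = differential,
                    log2fc = log2fc, in_enriched = want_in)
    list(atlas = atlas, truth = truth)
  })
}

# Rejection placement of non-overlapping intervals; `mode` per peak is
# "uniform" (anywhere), "in" (inside the enriched annotation) or "out"
# (inside its complement).
place_nonoverlapping <- function(widths, mode, genome, enr,
                                 max_tries = 500L) {
  n <- length(widths)
  chrom <- character(n); start <- numeric(n)
  placed <- list() # per chrom sorted matrix of placed intervals
  for (ch in genome$chrom) placed[[ch]] <- matrix(numeric(0), ncol = 2)
  glen <- setNames(genome$length, genome$chrom)

  enr_out <- NULL
  if (!is.null(enr)) {
    enr_out <- complement_regions(enr, genome)
  }
  whole <- tibble(chrom = genome$chrom, start = 0, end = unname(glen))
  for (i in seq_len(n)) {
    w <- widths[i]
    segs <- switch(mode[i], uniform = whole, `in` = enr, out = enr_out)
    segs_ok <- segs[segs$end - segs$start >= w, ]
    if (!nrow(segs_ok)) abort("no segment can host a peak of this width")
    seg_w <- segs_ok$end - segs_ok$start - w + 1
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      j <- sample.int(nrow(segs_ok), 1, prob = seg_w)
      s <- floor(runif(1, segs_ok$start[j], segs_ok$end[j] - w + 1))
      ch <- segs_ok$chrom[j]
      pm <- placed[[ch]]
      if (!nrow(pm)) clash <- FALSE else {
        k <- findInterval(s + w - 1, pm[, 1])
        clash <- k >= 1 && pm[k, 2] > s
      }
      if (!clash) {
        chrom[i] <- ch; start[i] <- s
        ins <- findInterval(s, pm[, 1])
        placed[[ch]] <- rbind(pm[seq_len(ins), , drop = FALSE], c(s, s + w),
                              if (ins < nrow(pm))
                                pm[(ins + 1):nrow(pm), , drop = FALSE])
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste("could not place peak without overlap after bounded",
                  "retries; use fewer or narrower peaks"))
    }
  }
  tibble(chrom = chrom, start = start, end = start + widths)
}

complement_regions <- function(rs, genome) {
  m <- merge_regions(rs)
  purrr::map(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]; L <- genome$length[ci]
    mm <- m[m$chrom == ch, ]
    bounds <- c(0, rbind(mm$start, mm$end), L)
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e > s
    tibble(chrom = ch, start = s[keep], end = e[keep])
  }) |> bind_rows()
}

#' Simulate the peak-by-sample ATAC count matrix
#'
#' Counts follow `K_ij ~ NB(mean = s_j * q_i * 2^(x_j * beta_i), dispersion
#' alpha_i)` with `x_j = 1` for group A samples, `beta_i` the planted log2FC
#' (0 for non-differential peaks), `s_j` the true size factor and `q_i` the
#' per-peak base mean.
#'
#' @param cfg a [sim_config()].
#' @param atlas_truth result of [simulate_peak_atlas()].
#' @return A list: `counts` (integer matrix peaks x samples), `samples`
#'   (sample sheet tibble: sample_id, group, donor), `size_factors`,
#'   `base_mean`, `alpha` (the true per-peak dispersions).
#' @export
simulate_count_matrix <- function(cfg, atlas_truth) {
  validate_sim_config(cfg)
  truth <- atlas_truth$truth
  with_stage_seed(cfg, "atac_counts", {
    nA <- cfg$n_samples_per_group[1]; nB <- cfg$n_samples_per_group[2]
    ns <- nA + nB
    np <- nrow(truth)
    samples <- tibble(
      sample_id = c(sprintf("A%02d", seq_len(nA)),
                    sprintf("B%02d", seq_len(nB))),
      group = rep(c("A", "B"), c(nA, nB)),
      donor = paste0("D", c(rep_len(1:3, nA), rep_len(4:5, nB))))
    sf <- rlnorm(ns, 0, cfg$size_factor_sdlog)
    sf <- sf / exp(mean(log(sf)))
    q <- rlnorm(np, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
    alpha <- draw_alpha(cfg$dispersion, np)
    x <- as.numeric(samples$group == "A")
    mu <- (q * 2^(outer(truth$log2fc, x))) %*% diag(sf)
    counts <- matrix(rnbinom(np * ns, mu = mu, size = 1 / alpha),
                     nrow = np, ncol = ns,
                     dimnames = list(truth$peak_id, samples$sample_id))
    list(counts = counts, samples = samples, size_factors = sf,
         base_mean = q, alpha = alpha)
  })
}

draw_alpha <- function(dispersion, n) {
  d <- dispersion
  if (length(d) == 1 && is.null(names(d))) return(rep(as.numeric(d), n))
  shape <- d[["shape"]]
  rgamma(n, shape = shape, rate = shape / d[["mean"]])
}

#' Simulate a gene model and term sets
#'
#' Genes get uniform TSS positions and random strands, except the members of
#' one designated "coupled" term, whose TSSs are planted a short distance
#' from randomly chosen differential peaks (on the basal-upstream side, so
#' the peak midpoint falls inside the gene's regulatory domain).
#'
#' @param cfg a [sim_config()].
#' @param genome a [genome()].
#' @param atlas_truth result of [simulate_peak_atlas()]; may be NULL for a
#'   fully decoupled model.
#' @param couple_direction which planted direction the coupled term tracks:
#'   "up_in_A" (default) uses peaks more open in group A.
#' @return A list: `genes` (tibble gene_id, chrom, tss, strand), `terms`
#'   (tibble term_id, gene_id), `coupled_term` (the term id, or NA when no
#'   atlas/differential peaks are available).
#' @export
simulate_gene_model_and_terms <- function(cfg, genome, atlas_truth = NULL,
                                          couple_direction = "up_in_A") {
  validate_sim_config(cfg)
  with_stage_seed(cfg, "genes_terms", {
    ng <- cfg$n_genes
    glen <- setNames(genome$length, genome$chrom)
    chrom <- sample(genome$chrom, ng, replace = TRUE,
                    prob = genome$length / sum(genome$length))
    tss <- floor(runif(ng, 0, glen[chrom]))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    genes <- tibble(gene_id = sprintf("gene_%04d", seq_len(ng)),
                    chrom = chrom, tss = tss, strand = strand)

    sizes <- floor(runif(cfg$n_terms, cfg$term_size[1],
                         cfg$term_size[2] + 1))
    terms <- purrr::map2(seq_len(cfg$n_terms), sizes, function(t, k) {
      tibble(term_id = sprintf("term_%02d", t),
             gene_id = sample(genes$gene_id, k))
    }) |> bind_rows()

    coupled_term <- NA_character_
    if (!is.null(atlas_truth) && cfg$coupling > 0) {
      tr <- atlas_truth$truth
      sel <- if (couple_direction == "up_in_A") {
        tr$differential & tr$log2fc > 0
      } else tr$differential & tr$log2fc < 0
      if (any(sel)) {
        coupled_term <- "term_01"
        cg <- terms$gene_id[terms$term_id == coupled_term]
        at <- atlas_truth$atlas
        pick <- sample(which(sel), length(cg), replace = sum(sel) < length(cg))
        mid <- floor((at$start[pick] + at$end[pick]) / 2)
        off <- floor(runif(length(cg), 1000, 4000))
        idx <- match(cg, genes$gene_id)
        genes$chrom[idx] <- at$chrom[pick]
        # put the TSS so the peak midpoint sits in the basal-upstream window
        genes$strand[idx] <- "+"
        genes$tss[idx] <- pmin(pmax(mid + off, 0), glen[at$chrom[pick]] - 1)
      }
    }
    list(genes = genes, terms = terms, coupled_term = coupled_term)
  })
}

#' Simulate stage-wise RNA counts coupled to planted accessibility effects
#'
#' Genes planted next to a differential peak (by
#' [simulate_gene_model_and_terms()]'s coupled term, plus any gene whose TSS
#' lies within 5 kb of a differential peak) become differentially expressed
#' in the matching direction with probability `coupling`; a background
#' fraction of other genes is DE at random. Counts are NB per stage with the
#' same parameterization as the ATAC matrix.
#'
#' @param cfg a [sim_config()].
#' @param genes gene tibble.
#' @param atlas_truth result of [simulate_peak_atlas()].
#' @return A list: per stage `counts` (genes x samples), `samples` (with
#'   `stage` column), and `truth` (gene_id, de, log2fc, coupled).
#' @export
simulate_expression_counts <- function(cfg, genes, atlas_truth) {
  validate_sim_config(cfg)
  with_stage_seed(cfg, "rna_counts", {
    tr <- atlas_truth$truth
    at <- atlas_truth$atlas
    diffpk <- at[tr$differential, ]
    difffc <- tr$log2fc[tr$differential]
    # nearest differential peak midpoint within 5 kb couples a gene
    coupled <- rep(FALSE, nrow(genes))
    dir <- rep(0, nrow(genes))
    if (nrow(diffpk)) {
      mid <- floor((diffpk$start + diffpk$end) / 2)
      for (ci in unique(genes$chrom)) {
        gi <- which(genes$chrom == ci)
        pm <- mid[diffpk$chrom == ci]
        fc <- difffc[diffpk$chrom == ci]
        if (!length(pm)) next
        o <- order(pm); pm <- pm[o]; fc <- fc[o]
        k <- findInterval(genes$tss[gi], pm)
        dlo <- abs(genes$tss[gi] - pm[pmax(k, 1)])
        dhi <- abs(pm[pmin(k + 1, length(pm))] - genes$tss[gi])
        nearest <- ifelse(dlo <= dhi, pmax(k, 1), pmin(k + 1, length(pm)))
        dmin <- pmin(dlo, dhi)
        hit <- dmin <= 5000
        coupled[gi[hit]] <- TRUE
        dir[gi[hit]] <- sign(fc[nearest[hit]])
      }
    }
    ng <- nrow(genes)
    de <- (coupled & runif(ng) < cfg$coupling)
    # background DE is drawn from all not-yet-DE genes, so with coupling = 0
    # DE status is independent of peak proximity
    bg <- (!de) & runif(ng) < cfg$frac_de_background
    log2fc <- numeric(ng)
    log2fc[de] <- dir[de] * cfg$de_log2fc
    log2fc[bg] <- sample(c(-1, 1), sum(bg), TRUE) * cfg$de_log2fc
    de <- de | bg
    truth <- tibble(gene_id = genes$gene_id, de = de, log2fc = log2fc,
                    coupled = coupled)

    nA <- cfg$n_rna_samples_per_group[1]
    nB <- cfg$n_rna_samples_per_group[2]
    q <- rlnorm(ng, cfg$rna_base_mean_meanlog, cfg$rna_base_mean_sdlog)
    out <- purrr::map(cfg$stages, function(stg) {
      samples <- tibble(
        sample_id = paste0(stg, "_", c(sprintf("A%02d", seq_len(nA)),
                                       sprintf("B%02d", seq_len(nB)))),
        group = rep(c("A", "B"), c(nA, nB)),
        donor = paste0("D", c(rep_len(1:3, nA), rep_len(4:5, nB))),
        stage = stg)
      sf <- rlnorm(nA + nB, 0, cfg$size_factor_sdlog)
      sf <- sf / exp(mean(log(sf)))
      x <- as.numeric(samples$group == "A")
      mu <- (q * 2^(outer(log2fc, x))) %*% diag(sf)
      counts <- matrix(rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$rna_dispersion),
                       nrow = ng, dimnames = list(genes$gene_id,
                                                  samples$sample_id))
      list(counts = counts, samples = samples, size_factors = sf)
    })
    names(out) <- cfg$stages
    list(stages = out, truth = truth)
  })
}

#' Run the whole generator
#'
#' Convenience wrapper running genome, states, atlas, ATAC counts, gene
#' model/terms and RNA counts in dependency order under one master seed.
#'
#' @param cfg a [sim_config()].
#' @return A named list with all generator outputs plus the assembled
#'   `truth` list.
#' @export
simulate_study <- function(cfg = sim_config()) {
  g <- simulate_genome(cfg)
  ann <- simulate_state_annotations(cfg, g)
  enr <- state_regions(ann$states, ann$enriched$cell_type,
                       ann$enriched$state)
  at <- simulate_peak_atlas(cfg, g, enriched_regions = enr)
  atac <- simulate_count_matrix(cfg, at)
  gt <- simulate_gene_model_and_terms(cfg, g, at)
  rna <- simulate_expression_counts(cfg, gt$genes, at)
  list(config = cfg, genome = g, annotations = ann, atlas = at$atlas,
       atac = atac, genes = gt$genes, terms = gt$terms,
       coupled_term = gt$coupled_term, rna = rna,
       truth = list(peaks = at$truth, size_factors = atac$size_factors,
                    expression = rna$truth,
                    enriched = ann$enriched,
                    coupled_term = gt$coupled_term))
}
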