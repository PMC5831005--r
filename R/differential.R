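#' Median-of-ratios size factors
#'
#' DESeq-style: per sample, the median ratio of counts to the per-feature
#' geometric mean, over features whose counts are positive in every sample;
#' factors are rescaled to geometric mean 1. If fewer than 100 usable
#' features exist, falls back to column-sum ratios.
#'
#' @param counts non-negative integer matrix (features x samples).
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  if (all(counts == 0)) abort("all-zero count matrix")
  cs <- colSums(counts)
  if (any(cs == 0)) abort("sample with zero total counts")
  logc <- log(counts)
  lgm <- rowMeans(logc)
  usable <- is.finite(lgm)
  if (sum(usable) >= 100) {
    sf <- apply(counts[usable, , drop = FALSE], 2, function(k) {
      exp(median(log(k) - lgm[usable]))
    })
  } else {
    sf <- cs / exp(mean(log(cs)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' NB dispersion estimation
#'
#' On size-factor-scaled counts, with `m` the per-feature scaled mean and
#' `s2` its scaled variance — the pooled within-group (residual) variance
#' when `group` is supplied, so real group effects do not inflate the
#' dispersion — three estimators are available:
#'
#' * `"trended"` (default): a mean-dispersion trend. For each feature, the
#'   moment-ratio `sum(s2 - m) / sum(m^2)` is taken over the window of the
#'   `2 * window_half + 1` nearest features by mean. Because
#'   `E[s2] = m + alpha m^2`, the windowed ratio is an approximately
#'   unbiased, low-noise estimate of the local dispersion, under which the
#'   downstream Wald test is well calibrated.
#' * `"mom"`: the raw per-feature method of moments
#'   `max(alpha_min, (s2 - m) / m^2)`. Unbiased in expectation but noisy at
#'   small sample sizes.
#' * `"eb"`: empirical-Bayes compromise; per-feature log MoM estimates are
#'   shrunk toward the log trend with weights from the delta-method
#'   sampling variance of each log dispersion against the observed
#'   between-feature spread. Appropriate when true dispersions vary
#'   feature-to-feature beyond the mean trend.
#'
#' @param counts integer matrix (features x samples).
#' @param size_factors per-sample factors (from [estimate_size_factors()]).
#' @param group optional per-sample grouping vector; strongly recommended
#'   for designs with real effects.
#' @param method one of "trended", "mom", "eb".
#' @param window_half half-width of the mean-ordered window for the trend.
#' @param alpha_min dispersion floor.
#' @return Numeric vector of per-feature dispersions >= `alpha_min`.
#' @export
estimate_dispersion <- function(counts, size_factors, group = NULL,
                                method = c("trended", "mom", "eb"),
                                window_half = 50, alpha_min = 1e-4) {
  method <- match.arg(method)
  if (ncol(counts) < 3) abort("need at least 3 samples")
  sc <- sweep(counts, 2, size_factors, "/")
  m <- rowMeans(sc)
  if (is.null(group)) {
    s2 <- apply(sc, 1, var)
    df_res <- ncol(counts) - 1
  } else {
    group <- as.character(group)
    parts <- lapply(unique(group), function(g) sc[, group == g, drop = FALSE])
    ss <- Reduce(`+`, lapply(parts, function(p) {
      rowSums((p - rowMeans(p))^2)
    }))
    df_res <- ncol(counts) - length(unique(group))
    s2 <- ss / df_res
  }
  mom <- pmax(alpha_min, (s2 - m) / m^2)
  mom[!is.finite(mom)] <- alpha_min
  if (method == "mom") return(mom)

  # windowed moment-ratio trend over features ordered by mean
  o <- order(m)
  n <- length(m)
  half <- min(window_half, n - 1)
  num <- (s2 - m)[o]
  den <- (m^2)[o]
  cn <- c(0, cumsum(num)); cd <- c(0, cumsum(den))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  trend <- numeric(n)
  trend[o] <- (cn[hi + 1] - cn[lo]) / (cd[hi + 1] - cd[lo])
  trend <- pmax(alpha_min, trend)
  trend[!is.finite(trend)] <- alpha_min
  if (method == "trended") return(trend)

  # eb: shrink log MoM toward log trend, weighting by the delta-method
  # sampling variance of log alpha-hat at the trend dispersion
  la <- log(mom)
  lt <- log(trend)
  v <- (2 / df_res) * ((1 + trend * m) / (trend * m))^2
  resid <- la - lt
  s2_prior <- max(stats::mad(resid)^2 - median(v), 1e-8)
  w <- v / (v + s2_prior)
  pmax(alpha_min, exp(w * lt + (1 - w) * la))
}

#' Negative-binomial Wald test for a two-group design
#'
#' Fits, per feature, the NB log-link model
#' `mu_ij = s_j * exp(b0_i + b_i * x_j)` with `x_j = 1` for group-A samples
#' and fixed per-feature dispersion, by Newton iteration vectorised across
#' features. `log2FC = b / ln 2` (positive = higher in group A); the Wald
#' statistic is `b / SE` with SE from the expected information, and the
#' two-sided p comes from the normal tail. Features with all-zero counts
#' are excluded (reported with NA statistics); one-group-all-zero features
#' are handled by a 0.5-count continuity floor on the group means.
#'
#' @param counts integer matrix (features x samples).
#' @param samples sample sheet tibble with `sample_id` and `group` columns
#'   (exactly two groups, >= 2 samples each).
#' @param group_a which group label maps to the positive log2FC direction
#'   (default: "A" if present, else the first level).
#' @param size_factors,dispersions optional; estimated from the data when
#'   missing ([estimate_size_factors()], [estimate_dispersion()] with the
#'   group design).
#' @param min_mean_count optional mean-count filter applied before testing
#'   (0 = off, the default); filtered features are reported with NA
#'   statistics and excluded from FDR adjustment.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `docseq_diff`: use [tidy()] for the
#'   per-feature table (feature_id, base_mean, log2fc, se, stat, pvalue,
#'   fdr, status) and [glance()] for the fit summary.
#' @export
nb_wald_test <- function(counts, samples, group_a = NULL,
                         size_factors = NULL, dispersions = NULL,
                         min_mean_count = 0, max_iter = 50, tol = 1e-8) {
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (!is.null(colnames(counts))) {
    samples <- samples[match(colnames(counts), samples$sample_id), ]
    if (anyNA(samples$sample_id)) abort("sample sheet does not cover counts")
  }
  grp <- as.character(samples$group)
  levels <- unique(grp)
  if (length(levels) != 2) abort("exactly two groups required")
  if (any(table(grp) < 2)) abort("need >= 2 samples per group")
  if (is.null(group_a)) group_a <- if ("A" %in% levels) "A" else levels[1]
  if (!group_a %in% levels) abort("group_a not a group label")
  x <- as.numeric(grp == group_a)

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, size_factors, group = grp)
  }
  s <- as.numeric(size_factors)
  np <- nrow(counts)
  feature_id <- rownames(counts) %||% sprintf("f%05d", seq_len(np))

  sc <- sweep(counts, 2, s, "/")
  base_mean <- rowMeans(sc)
  status <- rep("ok", np)
  status[base_mean == 0] <- "all_zero"
  if (min_mean_count > 0) {
    status[status == "ok" & base_mean < min_mean_count] <- "filtered"
  }

  mA <- rowMeans(sc[, x == 1, drop = FALSE])
  mB <- rowMeans(sc[, x == 0, drop = FALSE])
  sep <- status == "ok" & (mA == 0 | mB == 0)
  status[sep] <- "separated"
  test <- status %in% c("ok", "separated")
  # continuity floor keeps separated features estimable
  mAf <- pmax(mA, 0.5); mBf <- pmax(mB, 0.5)

  b0 <- log(mBf[test]); b1 <- log(mAf[test] / mBf[test])
  K <- counts[test, , drop = FALSE]
  a <- dispersions[test]
  newton_free <- !(sep[test]) # separated features keep their floored fit
  active <- newton_free
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    mu <- exp(outer(b0[active], rep(1, length(x))) +
                outer(b1[active], x)) * rep(s, each = sum(active))
    w <- mu / (1 + a[active] * mu)
    r <- (K[active, , drop = FALSE] - mu) / (1 + a[active] * mu)
    u0 <- rowSums(r); u1 <- rowSums(r * rep(x, each = sum(active)))
    i00 <- rowSums(w)
    i01 <- rowSums(w * rep(x, each = sum(active)))
    i11 <- i01 # x is 0/1 so x^2 = x
    det <- i00 * i11 - i01^2
    det[det <= 0] <- NA
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    d0[is.na(d0)] <- 0; d1[is.na(d1)] <- 0
    # damp huge steps
    stepmax <- pmax(abs(d0), abs(d1))
    damp <- ifelse(stepmax > 5, 5 / stepmax, 1)
    b0[active] <- b0[active] + damp * d0
    b1[active] <- b1[active] + damp * d1
    conv <- stepmax < tol
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  nonconv <- newton_free & active
  # expected information at the final fit
  mu <- exp(outer(b0, rep(1, length(x))) + outer(b1, x)) *
    rep(s, each = length(b0))
  w <- mu / (1 + a * mu)
  i00 <- rowSums(w); i01 <- rowSums(w * rep(x, each = length(b0)))
  det <- i00 * i01 - i01^2 # i11 == i01
  se_b1 <- sqrt(i00 / det)

  log2fc <- rep(NA_real_, np); se <- rep(NA_real_, np)
  stat <- rep(NA_real_, np); pvalue <- rep(NA_real_, np)
  log2fc[test] <- b1 / log(2)
  se[test] <- se_b1 / log(2)
  stat[test] <- b1 / se_b1
  pvalue[test] <- 2 * pnorm(-abs(b1 / se_b1))
  if (any(nonconv)) {
    ti <- which(test)[nonconv]
    status[ti] <- "not_converged"
    pvalue[ti] <- NA_real_
    warn(sprintf("%d feature(s) did not converge; p set to NA", length(ti)))
  }
  fdr <- rep(NA_real_, np)
  ok <- !is.na(pvalue)
  fdr[ok] <- bh_fdr(pvalue[ok])

  results <- tibble(feature_id = feature_id, base_mean = base_mean,
                    log2fc = log2fc, se = se, stat = stat,
                    pvalue = pvalue, fdr = fdr, status = status)
  structure(list(results = results, group_a = group_a,
                 groups = levels, n_samples = table(grp),
                 size_factors = setNames(s, samples$sample_id),
                 dispersions = dispersions,
                 min_mean_count = min_mean_count),
            class = "docseq_diff")
}

#' @export
print.docseq_diff <- function(x, ...) {
  cat("NB Wald differential test:", nrow(x$results), "features;",
      sprintf("positive log2FC = higher in group %s\n", x$group_a))
  print(head(x$results))
  invisible(x)
}

#' @rdname nb_wald_test
#' @param x a `docseq_diff` object.
#' @param ... unused.
#' @export
tidy.docseq_diff <- function(x, ...) x$results

#' @rdname nb_wald_test
#' @export
glance.docseq_diff <- function(x, ...) {
  r <- x$results
  tibble(n_features = nrow(r),
         n_tested = sum(!is.na(r$pvalue)),
         n_excluded = sum(is.na(r$pvalue)),
         group_a = x$group_a,
         median_dispersion = median(x$dispersions))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up BH with monotonicity, NA passed through.
#'
#' @param pvals numeric in \[0, 1\] (NA allowed).
#' @return Adjusted values, same length/order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Call differential open chromatin sites (DOCS)
#'
#' Compound thresholds: `fdr < fdr_max` and `|log2FC| >= min_abs_log2fc`.
#' Bi-DOCS are the positive-log2FC calls (more open in group A), Fi-DOCS
#' the negative ones.
#'
#' @param fit a `docseq_diff` object or its [tidy()] tibble.
#' @param coords optional region tibble with a `name` column matching
#'   feature ids; when given, the calls carry coordinates.
#' @param fdr_max,min_abs_log2fc thresholds (defaults 0.05 and 0.5).
#' @return An object of class `docseq_docs` with `bi`, `fi` (tibbles),
#'   thresholds, and counts. [tidy()] returns one row per DOCS with its
#'   direction.
#' @export
call_docs <- function(fit, coords = NULL, fdr_max = 0.05,
                      min_abs_log2fc = 0.5) {
  res <- if (inherits(fit, "docseq_diff")) fit$results else as_tibble(fit)
  sig <- !is.na(res$fdr) & res$fdr < fdr_max &
    abs(res$log2fc) >= min_abs_log2fc
  bi <- res[sig & res$log2fc > 0, ]
  fi <- res[sig & res$log2fc < 0, ]
  if (!is.null(coords)) {
    key <- coords$name
    add_coords <- function(d) {
      j <- match(d$feature_id, key)
      dplyr::bind_cols(coords[j, c("chrom", "start", "end")], d)
    }
    bi <- add_coords(bi); fi <- add_coords(fi)
  }
  structure(list(bi = bi, fi = fi,
                 fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                 n_bi = nrow(bi), n_fi = nrow(fi),
                 n_docs = nrow(bi) + nrow(fi),
                 frac_bi = if (nrow(bi) + nrow(fi) > 0)
                   nrow(bi) / (nrow(bi) + nrow(fi)) else NA_real_),
            class = "docseq_docs")
}

#' @export
print.docseq_docs <- function(x, ...) {
  cat(sprintf("DOCS call (FDR < %g, |log2FC| >= %g): %d sites (%d Bi / %d Fi, %.0f%% Bi)\n",
              x$fdr_max, x$min_abs_log2fc, x$n_docs, x$n_bi, x$n_fi,
              100 * (x$frac_bi %||% NA)))
  invisible(x)
}

#' @rdname call_docs
#' @param x a `docseq_docs` object.
#' @param ... unused.
#' @export
tidy.docseq_docs <- function(x, ...) {
  bind_rows(mutate(x$bi, direction = "bi"),
            mutate(x$fi, direction = "fi"))
}

#' Sample-label permutation null for the DOCS count
#'
#' Re-runs the full test + call pipeline under permuted group labels
#' (preserving group sizes; the identity assignment and its mirror are
#' excluded) and compares the permuted DOCS counts with the observed one.
#' This is the in-silico validation that donor- or line-specific structure,
#' rather than the group contrast, is not driving the calls.
#'
#' @param counts integer matrix (features x samples).
#' @param samples sample sheet (`sample_id`, `group`).
#' @param n_perm number of permutations (default 100); if fewer distinct
#'   assignments exist, all are used with a warning.
#' @param seed integer seed for drawing permutations.
#' @param fdr_max,min_abs_log2fc thresholds passed to [call_docs()].
#' @param group_a positive-direction group label.
#' @return A list: `observed` DOCS count, `permuted` integer vector,
#'   `mean_permuted`, and `p_value` = (1 + #\{perm >= obs\}) / (1 + n).
#' @export
label_permutation_null <- function(counts, samples, n_perm = 100, seed = 1,
                                   fdr_max = 0.05, min_abs_log2fc = 0.5,
                                   group_a = NULL) {
  samples <- as_tibble(samples)
  grp <- as.character(samples$group)
  levels <- unique(grp)
  if (length(levels) != 2) abort("exactly two groups required")
  nA <- sum(grp == levels[1])
  n <- length(grp)
  n_distinct <- choose(n, nA) - 2
  sf <- estimate_size_factors(counts)

  run_once <- function(g) {
    ss <- mutate(samples, group = g)
    fit <- nb_wald_test(counts, ss, group_a = levels[1], size_factors = sf)
    call_docs(fit, fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc)$n_docs
  }
  observed <- run_once(grp)

  perms <- list()
  if (n_distinct <= n_perm) {
    warn(sprintf("only %d distinct non-trivial assignments; using all",
                 n_distinct))
    idx <- utils::combn(n, nA, simplify = FALSE)
    for (ii in idx) {
      g <- rep(levels[2], n); g[ii] <- levels[1]
      if (all(g == grp) || all(g != grp)) next
      perms[[length(perms) + 1]] <- g
    }
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    seen <- character()
    while (length(perms) < n_perm) {
      ii <- sample.int(n, nA)
      g <- rep(levels[2], n); g[sort(ii)] <- levels[1]
      key <- paste(g, collapse = "")
      if (all(g == grp) || all(g != grp) || key %in% seen) next
      seen <- c(seen, key)
      perms[[length(perms) + 1]] <- g
    }
  }
  permuted <- vapply(perms, run_once, numeric(1))
  list(observed = observed, permuted = permuted,
       mean_permuted = mean(permuted),
       p_value = (1 + sum(permuted >= observed)) / (1 + length(permuted)))
}

#' Subset re-analysis: drop samples and compare DOCS calls
#'
#' Re-runs the pipeline without the dropped samples and reports the overlap
#' of the two DOCS sets and the Pearson correlation of log2FC over shared
#' DOCS (the karyotype-robustness check).
#'
#' @param counts integer matrix (features x samples).
#' @param samples sample sheet.
#' @param drop_samples character vector of sample ids to remove.
#' @param fdr_max,min_abs_log2fc thresholds.
#' @param group_a positive-direction group label.
#' @return A list: `full`, `subset` (docseq_docs), `n_overlap`,
#'   `overlap_fraction` (of the full calls), `jaccard`, `log2fc_cor`.
#' @export
subset_reanalysis <- function(counts, samples, drop_samples,
                              fdr_max = 0.05, min_abs_log2fc = 0.5,
                              group_a = NULL) {
  samples <- as_tibble(samples)
  keep <- !(samples$sample_id %in% drop_samples)
  ss <- samples[keep, ]
  if (length(unique(ss$group)) != 2 || any(table(ss$group) < 2)) {
    abort("dropping these samples leaves a degenerate design")
  }
  fit_full <- nb_wald_test(counts, samples, group_a = group_a)
  fit_sub <- nb_wald_test(counts[, samples$sample_id[keep], drop = FALSE],
                          ss, group_a = group_a)
  d_full <- call_docs(fit_full, fdr_max = fdr_max,
                      min_abs_log2fc = min_abs_log2fc)
  d_sub <- call_docs(fit_sub, fdr_max = fdr_max,
                     min_abs_log2fc = min_abs_log2fc)
  ids_full <- tidy(d_full)$feature_id
  ids_sub <- tidy(d_sub)$feature_id
  shared <- intersect(ids_full, ids_sub)
  lf <- tidy(fit_full); ls <- tidy(fit_sub)
  r <- if (length(shared) >= 3) {
    cor(lf$log2fc[match(shared, lf$feature_id)],
        ls$log2fc[match(shared, ls$feature_id)])
  } else NA_real_
  list(full = d_full, subset = d_sub,
       n_overlap = length(shared),
       overlap_fraction = if (length(ids_full))
         length(shared) / length(ids_full) else NA_real_,
       jaccard = if (length(union(ids_full, ids_sub)))
         length(shared) / length(union(ids_full, ids_sub)) else NA_real_,
       log2fc_cor = r)
}
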