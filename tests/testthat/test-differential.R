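test_that("size factors: identical and scaled columns, known-factor recovery", {
  k <- matrix(rpois(3000, 50), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  k[, 2] <- k[, 1]; k[, 3] <- k[, 1]
  expect_equal(unname(estimate_size_factors(k)), rep(1, 3))
  k2 <- cbind(a = k[, 1], b = 2 * k[, 1], c = k[, 1])
  sf <- estimate_size_factors(k2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # planted factors 0.5 / 1 / 2 recovered within 5% at 10k features
  set.seed(2)
  q <- rlnorm(10000, log(60), 1)
  truef <- c(0.5, 1, 2)
  k3 <- sapply(truef, function(s) rnbinom(10000, mu = q * s, size = 10))
  colnames(k3) <- c("a", "b", "c")
  sf3 <- estimate_size_factors(k3)
  expect_equal(unname(sf3 / exp(mean(log(sf3)))),
               truef / exp(mean(log(truef))), tolerance = 0.05)
  expect_error(estimate_size_factors(matrix(0, 5, 3)), "all-zero")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  mk <- make_counts(n_feat = 2000, mu = 40, alpha = 0.2,
                    sf = c(0.7, 1, 1.4, 1, 0.9, 1.2, 1, 1), seed = 29)
  mine <- estimate_size_factors(mk$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(mk$counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("method-of-moments dispersion follows the stated formula", {
  # scaled mean 10, sample variance 30 -> alpha = (30 - 10) / 100 = 0.2
  s <- sqrt(30)
  k <- rbind(c(10 - s, 10, 10 + s), c(10, 10, 10))
  a <- estimate_dispersion(k, size_factors = rep(1, 3), method = "mom")
  expect_equal(a[1], 0.2)
  expect_equal(a[2], 1e-4) # variance <= mean floors at alpha_min
})

test_that("dispersion estimators recover a planted constant alpha", {
  set.seed(4)
  k <- matrix(rnbinom(1000 * 20, mu = 50, size = 10), ncol = 20)
  colnames(k) <- paste0("s", 1:20)
  sf <- rep(1, 20)
  mom <- estimate_dispersion(k, sf, method = "mom")
  expect_gt(median(mom), 0.07)
  expect_lt(median(mom), 0.13)
  tr <- estimate_dispersion(k, sf, method = "trended")
  expect_equal(median(tr), 0.1, tolerance = 0.15)
  expect_lt(sd(tr), sd(mom)) # the trend is the low-noise estimator
  eb <- estimate_dispersion(k, sf, method = "eb")
  expect_equal(median(eb), 0.1, tolerance = 0.2)
  # group effects do not inflate the within-group estimate
  grp <- rep(c("A", "B"), each = 10)
  k2 <- k; k2[1:200, grp == "A"] <- k2[1:200, grp == "A"] * 4L
  within <- estimate_dispersion(k2, sf, group = grp, method = "mom")
  pooled <- estimate_dispersion(k2, sf, method = "mom")
  expect_lt(median(within[1:200]), 0.5 * median(pooled[1:200]))
})

test_that("NB Wald fit matches a per-feature GLM oracle at fixed dispersion", {
  skip_if_not_installed("MASS")
  mk <- make_counts(n_feat = 40, nA = 5, nB = 5, mu = 60, alpha = 0.15,
                    log2fc = rep(c(0, 1), each = 20),
                    sf = c(0.8, 1, 1.2, 1, 1, 0.9, 1.1, 1, 1, 1), seed = 7)
  alpha <- rep(0.15, 40)
  fit <- nb_wald_test(mk$counts, mk$samples, size_factors = mk$sf,
                      dispersions = alpha)
  r <- tidy(fit)
  x <- as.numeric(mk$samples$group == "A")
  for (i in c(1, 7, 21, 33)) {
    m <- glm(mk$counts[i, ] ~ x + offset(log(mk$sf)),
             family = MASS::negative.binomial(theta = 1 / alpha[i]))
    co <- summary(m, dispersion = 1)$coefficients
    expect_equal(r$log2fc[i], unname(co["x", "Estimate"]) / log(2),
                 tolerance = 1e-5)
    expect_equal(r$se[i], unname(co["x", "Std. Error"]) / log(2),
                 tolerance = 1e-4)
  }
})

test_that("identical groups give log2FC exactly 0 and p near 1", {
  k <- matrix(10, nrow = 3, ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  ss <- tibble::tibble(sample_id = colnames(k),
                       group = rep(c("A", "B"), each = 3))
  fit <- nb_wald_test(k, ss, size_factors = rep(1, 6),
                      dispersions = rep(0.01, 3))
  r <- tidy(fit)
  expect_equal(r$log2fc, rep(0, 3))
  expect_equal(r$pvalue, rep(1, 3))
})

test_that("relabelling the groups negates log2FC and swaps the DOCS sets", {
  mk <- make_counts(n_feat = 400, mu = 50, alpha = 0.1,
                    log2fc = sample(c(-1.5, 0, 1.5), 400, TRUE,
                                    prob = c(.1, .8, .1)), seed = 11)
  fit_a <- nb_wald_test(mk$counts, mk$samples, group_a = "A")
  fit_b <- nb_wald_test(mk$counts, mk$samples, group_a = "B")
  expect_equal(tidy(fit_b)$log2fc, -tidy(fit_a)$log2fc, tolerance = 1e-9)
  expect_equal(tidy(fit_b)$pvalue, tidy(fit_a)$pvalue, tolerance = 1e-9)
  d_a <- call_docs(fit_a); d_b <- call_docs(fit_b)
  expect_setequal(d_a$bi$feature_id, d_b$fi$feature_id)
  expect_setequal(d_a$fi$feature_id, d_b$bi$feature_id)
})

test_that("all-zero and one-group-zero features are handled", {
  k <- rbind(c(0, 0, 0, 0, 0, 0),
             c(0, 0, 0, 40, 45, 50),
             c(20, 25, 30, 22, 24, 28))
  colnames(k) <- paste0("s", 1:6)
  rownames(k) <- c("zero", "sep", "ok")
  ss <- tibble::tibble(sample_id = colnames(k),
                       group = rep(c("A", "B"), each = 3))
  fit <- nb_wald_test(k, ss, size_factors = rep(1, 6),
                      dispersions = rep(0.1, 3))
  r <- tidy(fit)
  expect_equal(r$status, c("all_zero", "separated", "ok"))
  expect_true(is.na(r$pvalue[1]))
  expect_lt(r$log2fc[2], -5) # strong depletion in A, finite via 0.5 floor
  expect_true(is.finite(r$log2fc[2]))
})

test_that("BH adjustment reproduces step-up arithmetic and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.001, 1, 1, 1)), c(0.004, 1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(50)^2
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # fdr >= p componentwise in a result table
  mk <- make_counts(n_feat = 200, seed = 3)
  r <- tidy(nb_wald_test(mk$counts, mk$samples))
  expect_true(all(r$fdr >= r$pvalue, na.rm = TRUE))
})

test_that("DOCS calling applies the compound thresholds by direction", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    base_mean = 50, se = 0.1, stat = 0, pvalue = 0.01, status = "ok",
    log2fc = c(0.6, 0.4, 2.0, -0.7),
    fdr = c(0.04, 0.04, 0.06, 0.01))
  d <- call_docs(res)
  expect_equal(d$bi$feature_id, "a")   # fdr 0.04, lfc 0.6
  expect_equal(d$fi$feature_id, "d")
  expect_false("b" %in% tidy(d)$feature_id) # |lfc| below 0.5
  expect_false("c" %in% tidy(d)$feature_id) # fdr above 0.05
  # boundary: |log2fc| exactly 0.5 is included (non-strict)
  res$log2fc[2] <- 0.5
  expect_true("b" %in% call_docs(res)$bi$feature_id)
})

test_that("label permutation enumerates distinct assignments for small designs", {
  mk <- make_counts(n_feat = 60, nA = 3, nB = 3, seed = 13)
  expect_warning(
    pn <- label_permutation_null(mk$counts, mk$samples, n_perm = 100,
                                 seed = 1),
    "distinct")
  expect_equal(length(pn$permuted), choose(6, 3) - 2)
  expect_gte(pn$p_value, 1 / (length(pn$permuted) + 1))
})

test_that("null data put the observed DOCS count inside the permuted range", {
  mk <- make_counts(n_feat = 800, nA = 4, nB = 4, mu = 40, alpha = 0.1,
                    seed = 17)
  pn <- label_permutation_null(mk$counts, mk$samples, n_perm = 20, seed = 2)
  expect_gt(pn$p_value, 0.05)
})

test_that("subset re-analysis is the identity when nothing is dropped", {
  mk <- make_counts(n_feat = 500, nA = 6, nB = 5, mu = 50, alpha = 0.1,
                    log2fc = sample(c(0, 2), 500, TRUE, prob = c(.8, .2)),
                    seed = 19)
  sr <- subset_reanalysis(mk$counts, mk$samples, drop_samples = character())
  expect_equal(sr$overlap_fraction, 1)
  expect_equal(sr$jaccard, 1)
  expect_equal(sr$log2fc_cor, 1)
  sr1 <- subset_reanalysis(mk$counts, mk$samples, drop_samples = "A1")
  expect_gt(sr1$overlap_fraction, 0.5)
  expect_gt(sr1$log2fc_cor, 0.9)
  expect_error(
    subset_reanalysis(mk$counts, mk$samples,
                      drop_samples = paste0("A", 1:6)),
    "degenerate")
})
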