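test_that("regulatory domains follow basal-plus-extension with caps and clips", {
  g <- genome(c(chr1 = 1e6))
  one <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000,
                        strand = "+")
  d <- assign_regulatory_domains(one, g)
  expect_equal(d$basal_start, 5000)
  expect_equal(d$basal_end, 11000)
  expect_equal(d$start, 0)     # capped at 1 Mb upstream, clipped to chrom
  expect_equal(d$end, 1e6)
  # minus strand mirrors the basal window
  neg <- tibble::tibble(gene_id = "g2", chrom = "chr1", tss = 10000,
                        strand = "-")
  dn <- assign_regulatory_domains(neg, g)
  expect_equal(dn$basal_start, 9000)
  expect_equal(dn$basal_end, 15000)
  # two genes 100 kb apart: extensions meet at the neighbour's basal edge
  two <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        tss = c(100000, 200000), strand = "+")
  d2 <- assign_regulatory_domains(two, g)
  expect_equal(d2$end[d2$gene_id == "a"],
               d2$basal_start[d2$gene_id == "b"])
  expect_equal(d2$start[d2$gene_id == "b"],
               d2$basal_end[d2$gene_id == "a"])
  # extension cap respected when neighbours are far
  far <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        tss = c(100, 999000), strand = "+")
  df <- assign_regulatory_domains(far, g, extension_max = 5e4)
  expect_equal(df$end[1], 100 + 5e4)
  expect_error(assign_regulatory_domains(
    tibble::tibble(gene_id = "x", chrom = "chr9", tss = 1, strand = "+"), g),
    "outside")
})

test_that("region-gene association uses the midpoint rule", {
  domains <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                            start = c(0, 400), end = c(500, 900),
                            basal_start = c(0, 400), basal_end = c(500, 900))
  # overlapping domains: midpoint in both
  dom_ov <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                           start = c(0, 100), end = c(300, 500),
                           basal_start = c(0, 100), basal_end = c(300, 500))
  r <- region_set("chr1", 150, 250, name = "r1") # midpoint 200
  m <- map_regions_to_genes(r, dom_ov)
  expect_setequal(m$gene_id, c("g1", "g2"))
  # midpoint outside all domains -> no association
  r2 <- region_set("chr1", 880, 1000, name = "r2") # midpoint 940
  expect_equal(nrow(map_regions_to_genes(r2, domains)), 0)
  # region end overlaps a domain but midpoint does not
  r3 <- region_set("chr1", 850, 1050, name = "r3") # midpoint 950, end in g2
  expect_equal(nrow(map_regions_to_genes(r3, domains)), 0)
  expect_equal(attr(m, "associated_genes"), c("g1", "g2"))
})

test_that("binomial region test reproduces closed forms and the oracle", {
  g <- genome(c(chr1 = 1000))
  domains <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
                            end = 500, basal_start = 0, basal_end = 500)
  # all 10 region midpoints inside a half-genome domain: p = 2^-10, fold 2
  regions <- region_set(rep("chr1", 10), seq(0, 9) * 50, seq(0, 9) * 50 + 10)
  b <- binomial_region_test("g1", regions, domains, g)
  expect_equal(b$k_regions, 10)
  expect_equal(b$pi_term, 0.5)
  expect_equal(b$region_fold, 2)
  expect_equal(b$binomial_p, 2^-10)
  # k = n * pi exactly -> fold 1
  reg2 <- region_set(rep("chr1", 10), c(seq(0, 4) * 90, seq(5, 9) * 90 + 60),
                     c(seq(0, 4) * 90, seq(5, 9) * 90 + 60) + 8)
  b2 <- binomial_region_test("g1", reg2, domains, g)
  expect_equal(b2$region_fold, b2$k_regions / (10 * 0.5))
  expect_equal(b2$binomial_p,
               oracle_binom_upper(b2$k_regions, 10, 0.5), tolerance = 1e-12)
})

test_that("binomial and hypergeometric tails match summation oracles", {
  expect_equal(pbinom(6 - 1, 40, 0.05, lower.tail = FALSE),
               oracle_binom_upper(6, 40, 0.05), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:100) {
    n <- sample(5:500, 1); p <- runif(1, 0.01, 0.99)
    k <- sample(0:n, 1)
    expect_equal(pbinom(k - 1, n, p, lower.tail = FALSE),
                 oracle_binom_upper(k, n, p), tolerance = 1e-12)
    N <- sample(10:500, 1); K <- sample(1:N, 1)
    nn <- sample(1:N, 1); kk <- sample(0:min(K, nn), 1)
    expect_equal(phyper(kk - 1, K, N - K, nn, lower.tail = FALSE),
                 oracle_hyper_upper(kk, N, K, nn), tolerance = 1e-12)
  }
})

test_that("hypergeometric gene test: closed form, degenerate and oracle", {
  u <- sprintf("g%02d", 1:10)
  h <- hypergeometric_gene_test(u[1:5], u[1:5], u)
  expect_equal(h$overlap_k, 5)
  expect_equal(h$gene_fold, 2)
  expect_equal(h$hypergeom_p, 1 / choose(10, 5))
  # empty term
  h0 <- hypergeometric_gene_test(character(), u[1:5], u)
  expect_equal(h0$overlap_k, 0)
  expect_equal(h0$hypergeom_p, 1)
  # N=100, K=20, n=30, k=12 vs oracle
  u2 <- sprintf("g%03d", 1:100)
  term <- u2[1:20]; hits <- c(u2[1:12], u2[50:67])
  h2 <- hypergeometric_gene_test(term, hits, u2)
  expect_equal(h2$overlap_k, 12)
  expect_equal(h2$hypergeom_p, oracle_hyper_upper(12, 100, 20, 30),
               tolerance = 1e-12)
  expect_error(hypergeometric_gene_test(term, hits, character()), "empty")
})

test_that("Fisher overlap test: symmetry, extremes, oracle, transpose", {
  f <- fisher_overlap_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$fisher_p, 1)
  f2 <- fisher_overlap_test(matrix(c(5, 0, 0, 5), 2))
  expect_equal(f2$odds_ratio, Inf)
  expect_equal(f2$fisher_p, 2 / choose(10, 5), tolerance = 1e-12)
  f3 <- fisher_overlap_test(matrix(c(12, 7, 5, 16), 2))
  expect_equal(f3$fisher_p, oracle_fisher_two_sided(12, 5, 7, 16),
               tolerance = 1e-12)
  expect_equal(f3$odds_ratio, (12 * 16) / (5 * 7))
  # transpose invariance on random tables; margin zero -> p = 1, OR NA
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(sample(0:30, 4, TRUE), 2)
    expect_equal(fisher_overlap_test(m)$fisher_p,
                 fisher_overlap_test(t(m))$fisher_p, tolerance = 1e-12)
    expect_equal(fisher_overlap_test(m)$fisher_p,
                 oracle_fisher_two_sided(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
  }
  fz <- fisher_overlap_test(matrix(c(0, 0, 3, 5), 2))
  expect_equal(fz$fisher_p, 1)
  expect_true(is.na(fz$odds_ratio))
  expect_error(fisher_overlap_test(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("term calling applies the compound Table-style rule end to end", {
  # craft a tiny world where one term's domains capture all regions
  g <- genome(c(chr1 = 1e5))
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          tss = seq(2500, 97500, length.out = 20),
                          strand = "+")
  domains <- assign_regulatory_domains(genes, g, extension_max = 2000)
  terms <- tibble::tibble(
    term_id = rep(c("hit_term", "null_term"), each = 4),
    gene_id = c(genes$gene_id[1:4], genes$gene_id[11:14]))
  # regions at the basal windows of the hit term's genes
  tss_hit <- genes$tss[1:4]
  regions <- region_set(rep("chr1", 8),
                        c(tss_hit - 100, tss_hit - 100),
                        c(tss_hit + 100, tss_hit + 100),
                        name = sprintf("r%d", 1:8))
  res <- call_enriched_terms(terms, regions, domains, g,
                             universe = genes$gene_id)
  expect_true(res$significant[res$term_id == "hit_term"])
  expect_false(res$significant[res$term_id == "null_term"])
  expect_gt(res$region_fold[res$term_id == "hit_term"], 2)
  expect_equal(res$term_id[1], "hit_term") # sorted by binomial FDR
})

test_that("gene-set overlap fraction mirrors its definition", {
  expect_equal(gene_set_overlap_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(gene_set_overlap_fraction(c("a", "b"), c("x")), 0)
  expect_equal(gene_set_overlap_fraction(sprintf("g%03d", 1:200),
                                         sprintf("g%03d", 3:200)), 0.99)
  expect_error(gene_set_overlap_fraction(character(), "a"), "empty")
})
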