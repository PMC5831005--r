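# Independent tail/enumeration oracles, written directly from the
# definitions (log-space summation of binomial coefficients), used to check
# the tests the package routes through stats::.

oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

oracle_hyper_upper <- function(k, N, K, n) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Two-sided Fisher p by full enumeration over tables with fixed margins,
# point-probability rule (tables at most as probable as the observed one;
# the conventional 1 + 1e-7 relative tolerance guards ties).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  lp <- function(x) {
    lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  }
  probs <- exp(vapply(lo:hi, lp, numeric(1)))
  obs <- exp(lp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# tiny deterministic two-group NB count matrix
make_counts <- function(n_feat = 200, nA = 4, nB = 4, mu = 50, alpha = 0.1,
                        log2fc = rep(0, n_feat), sf = NULL, seed = 1) {
  set.seed(seed)
  ns <- nA + nB
  if (is.null(sf)) sf <- rep(1, ns)
  x <- rep(c(1, 0), c(nA, nB))
  q <- rep(mu, n_feat)
  m <- (q * 2^(outer(log2fc, x))) %*% diag(sf)
  counts <- matrix(rnbinom(n_feat * ns, mu = m, size = 1 / alpha),
                   nrow = n_feat,
                   dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                                   c(sprintf("A%d", seq_len(nA)),
                                     sprintf("B%d", seq_len(nB)))))
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    group = rep(c("A", "B"), c(nA, nB)),
    donor = paste0("D", seq_len(ns)))
  list(counts = counts, samples = samples, sf = sf)
}
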