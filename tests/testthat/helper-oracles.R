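# independent brute-force oracles used to freeze expected values

# Hardy-Weinberg exact test by full enumeration with exact choose() weights:
# P(h hets | n genotypes, n_a copies of A) over all attainable h
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  # multiplicity of a genotype configuration with h hets
  w <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (2 * n - n_a - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# upper-tail hypergeometric by direct enumeration of the pmf
hyper_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

hyper_oracle_pmf <- function(n, K, N) {
  j <- 0:min(n, K)
  choose(K, j) * choose(N - K, n - j) / choose(N, n)
}

# Mendelian transmission oracle: child must receive one allele from each
# parent's unordered pair
mendel_oracle <- function(f, m, c) {
  for (fa in f) for (ma in m) {
    if (setequal_multiset(c(fa, ma), c)) return(TRUE)
  }
  FALSE
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# minimal trio_calls row builder for filter tests
one_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     f = c(0L, 0L), m = c(0L, 0L), ch = c(0L, 1L),
                     gq = c(99L, 99L, 99L), dp = c(30L, 30L, 30L)) {
  trio_calls(chrom = chrom, pos = pos, ref = ref, alt = alt,
             f_a1 = f[1], f_a2 = f[2], m_a1 = m[1], m_a2 = m[2],
             c_a1 = ch[1], c_a2 = ch[2],
             f_gq = gq[1], m_gq = gq[2], c_gq = gq[3],
             f_dp = dp[1], m_dp = dp[2], c_dp = dp[3])
}
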