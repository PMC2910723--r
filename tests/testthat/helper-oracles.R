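# Independent brute-force oracles, computed straight from interval
# coordinates with no reference to the package's matrix representation.

# Dense co-occurrence matrix by an all-pairs double scan.
bf_dense_matrix <- function(profiles, policy = "binary") {
  iv <- do.call(rbind, lapply(profiles, function(p)
    cbind(p$intervals, origin = p$factor)))
  n <- nrow(iv)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (iv$contig[i] == iv$contig[j]) {
        shared <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
        if (shared > 0)
          m[i, j] <- if (policy == "bases") shared else 1
      }
    }
  }
  attr(m, "origin") <- iv$origin
  m
}

# Statistic as an explicit double loop over the two assigned sets.
bf_statistic <- function(dense, setA, setB) {
  s <- 0
  for (i in setA) for (j in setB) s <- s + dense[i, j]
  s
}

# Exact permutation null: enumerate every split of the n-record pool into
# an A-set of size n_a and its complement.
enum_perm_null <- function(dense, n_a) {
  n <- nrow(dense)
  splits <- utils::combn(n, n_a)
  apply(splits, 2L, function(sa)
    bf_statistic(dense, sa, setdiff(seq_len(n), sa)))
}

# Exact independent-resampling null: every ordered pair of draws.
enum_indep_null <- function(dense, n_a, n_b) {
  n <- nrow(dense)
  sa <- utils::combn(n, n_a, simplify = FALSE)
  sb <- utils::combn(n, n_b, simplify = FALSE)
  unlist(lapply(sa, function(a)
    vapply(sb, function(b) bf_statistic(dense, a, b), 0)))
}

# Random binding profiles on a couple of contigs for property tests.
random_profiles <- function(n_per_factor = 8, contigs = c("chr1", "chr2"),
                            span = 2000, max_len = 300) {
  lapply(c("A", "B"), function(f) {
    start <- sample.int(span, n_per_factor)
    len <- sample.int(max_len, n_per_factor)
    binding_profile(data.frame(contig = sample(contigs, n_per_factor,
                                               replace = TRUE),
                               start = start, end = start + len),
                    factor = f)
  })
}

# Three-sigma binomial tolerance around an expected proportion.
mc_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
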