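# Small deterministic fixtures shared across test files.

# random spot matrix on an integer lattice
make_spots <- function(n_genes = 20, n_spots = 400, lattice = 40, seed = 1,
                       lambda = 2) {
  set.seed(seed)
  coords <- unique(data.frame(x = sample(0:(lattice - 1), n_spots, TRUE),
                              y = sample(0:(lattice - 1), n_spots, TRUE)))
  counts <- matrix(rpois(n_genes * nrow(coords), lambda), nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)), NULL))
  spot_matrix(counts, coords)
}

# dense normalized-style expression matrix with named genes/units
make_expr <- function(n_genes = 60, n_units = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_units)), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("u%03d", seq_len(n_units))))
  m
}

# independent term-by-term running-sum oracle for the single-sample
# enrichment statistic (never calls the package implementation)
ssgsea_oracle <- function(v, sig, alpha = 0.25) {
  n <- length(v)
  ord <- order(-v)
  genes <- names(v)[ord]
  inset <- genes %in% sig
  m <- sum(inset)
  wt <- function(j) abs((n - j + 1) - (n + 1) / 2)^alpha
  denom_in <- 0
  for (j in seq_len(n)) if (inset[j]) denom_in <- denom_in + wt(j)
  run_in <- 0; run_out <- 0; total <- 0
  for (j in seq_len(n)) {
    if (inset[j]) run_in <- run_in + wt(j) / denom_in
    else run_out <- run_out + 1 / (n - m)
    total <- total + (run_in - run_out)
  }
  total / n
}

# exact two-sided rank-sum p by full enumeration of group assignments
ranksum_enum_p <- function(x1, x2) {
  n1 <- length(x1)
  pooled <- c(x1, x2)
  r <- rank(pooled)
  combos <- combn(length(pooled), n1)
  w <- colSums(matrix(r[combos], nrow = n1))
  mu <- mean(w)
  w_obs <- sum(r[seq_len(n1)])
  mean(abs(w - mu) >= abs(w_obs - mu) - 1e-12)
}

# hypergeometric enrichment tail by explicit pmf summation
hyper_enrich_oracle <- function(k, m, n, N) {
  ks <- k:min(m, n)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}
hyper_deplete_oracle <- function(k, m, n, N) {
  ks <- max(0, m + n - N):k
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}
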