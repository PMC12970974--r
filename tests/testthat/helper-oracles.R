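# Independent oracles used to cross-check the package implementations.
# These deliberately use different constructions from the package code.

# Gini via the Lorenz-curve trapezoid: cumulative share of mass against
# cumulative share of ranked units; G = 1 - 2 * area under the Lorenz curve.
lorenz_gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (sum(x) == 0) return(NA_real_)
  L <- c(0, cumsum(x) / sum(x))
  area <- sum((L[-1] + L[-(n + 1)]) / 2) / n  # trapezoids, width 1/n
  1 - 2 * area
}

# Kendall tau-b by brute-force pair counting with tie corrections.
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Two-sided Wilcoxon rank-sum p by looping over every label assignment
# (index-set loop, not the package's matrix enumeration).
brute_wilcoxon_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(r), nx, simplify = FALSE)
  ws <- vapply(sets, function(s) sum(r[s]), numeric(1))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Benjamini-Hochberg step-up by hand.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Moments of a discrete pmf by direct summation over its support.
pmf_moments <- function(d, kmax) {
  k <- 0:kmax
  p <- d(k)
  m <- sum(k * p)
  c(mean = m, variance = sum(k^2 * p) - m^2)
}

# A small fully-processed two-condition dataset for pipeline tests.
make_test_dataset <- function(seed = 1, n_genes = 400, n_cells = 120,
                              permissive_qc = TRUE) {
  st <- make_two_condition_study(n_genes, n_cells, 0.05, 4, 0.05, seed = seed)
  ds <- study_to_dataset(st)
  qp <- if (permissive_qc)
    qc_params(min_genes = 10, max_genes = 1e6, min_umis = 10,
              min_cells_per_gene = 5)
  else qc_params()
  ds <- normalize_counts(qc_filter(ds, qp))
  list(study = st, ds = expression_filter(ds))
}
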